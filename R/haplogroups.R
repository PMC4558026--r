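#' Construct a haplogroup frequency table
#'
#' The central genetic data structure: populations by haplogroups. Relative
#' frequencies always sum to one per population; integer counts are kept
#' alongside when available (AMOVA requires them).
#'
#' @param freq numeric matrix of relative frequencies, rownames = population
#'   ids, colnames = haplogroup labels.
#' @param counts optional integer matrix of the same shape; when given,
#'   `freq` must equal the row-normalised counts.
#' @param meta optional population metadata tibble (see
#'   [read_population_meta()]); must contain every population of `freq`.
#' @return an object of class `haplogroup_table`.
#' @export
haplogroup_table <- function(freq, counts = NULL, meta = NULL) {
  if (!is.matrix(freq) || !is.numeric(freq)) stop_input("freq must be a numeric matrix")
  if (is.null(rownames(freq)) || is.null(colnames(freq))) {
    stop_input("freq must carry population rownames and haplogroup colnames")
  }
  if (anyDuplicated(rownames(freq))) stop_input("duplicate population ids")
  if (any(freq < 0) || any(freq > 1 + 1e-9)) stop_input("frequencies outside [0, 1]")
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) {
    bad <- rownames(freq)[which.max(abs(rs - 1))]
    stop_input("frequency rows must sum to 1 (population '%s' sums to %.6f)", bad, rs[[bad]])
  }
  if (!is.null(counts)) {
    if (!identical(dim(counts), dim(freq))) stop_input("counts and freq shapes differ")
    if (!is_whole(counts) || any(counts < 0)) stop_input("counts must be non-negative integers")
    dimnames(counts) <- dimnames(freq)
    if (max(abs(freq - counts / rowSums(counts))) > 1e-9) {
      stop_input("freq is not the row-normalisation of counts")
    }
  }
  if (!is.null(meta)) {
    missing <- setdiff(rownames(freq), meta$population)
    if (length(missing)) {
      stop_input("populations absent from metadata: %s", paste(missing, collapse = ", "))
    }
    meta <- meta[match(rownames(freq), meta$population), , drop = FALSE]
  }
  structure(
    list(freq = freq, counts = counts, meta = meta,
         populations = rownames(freq), haplogroups = colnames(freq)),
    class = "haplogroup_table"
  )
}

#' @export
print.haplogroup_table <- function(x, ...) {
  cat(sprintf("<haplogroup_table> %d populations x %d haplogroups%s%s\n",
              length(x$populations), length(x$haplogroups),
              if (!is.null(x$counts)) ", with counts" else "",
              if (!is.null(x$meta)) ", with metadata" else ""))
  invisible(x)
}

#' Coerce to a haplogroup table
#'
#' @param x a `haplogroup_table`, or a data frame whose first column holds
#'   population ids and remaining numeric columns hold frequencies or counts
#'   (auto-detected: all-integer entries whose rows do not sum to one are
#'   treated as counts).
#' @param meta optional metadata tibble.
#' @return a `haplogroup_table`.
#' @export
as_haplogroup_table <- function(x, meta = NULL) {
  if (inherits(x, "haplogroup_table")) return(x)
  if (!is.data.frame(x)) stop_input("cannot coerce %s to haplogroup_table", class(x)[1])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("haplogroup columns must be numeric")
  rownames(m) <- as.character(x[[1]])
  rs <- rowSums(m)
  if (any(rs == 0)) {
    i <- which(rs == 0)[1]
    stop_input("empty population '%s' (row %d): all haplogroup cells are zero", rownames(m)[i], i)
  }
  counts_given <- is_whole(m) && any(abs(rs - 1) > 1e-9)
  if (counts_given) {
    haplogroup_table(m / rs, counts = m, meta = meta)
  } else {
    haplogroup_table(m / rs, meta = meta)
  }
}

#' @export
as_tibble.haplogroup_table <- function(x, ..., what = c("freq", "counts")) {
  what <- match.arg(what)
  m <- if (what == "counts") x$counts else x$freq
  if (is.null(m)) stop_input("table carries no counts")
  tibble::add_column(tibble::as_tibble(m), population = rownames(m), .before = 1)
}

#' Read population metadata
#'
#' Tab-separated, `#`-comments ignored. Required column: `population`.
#' Recognised columns: `ethnic_group`, `branch`, `language`, `lat`, `lon`,
#' `n`. Coordinates are validated to lie in the usual ranges.
#'
#' @param path file path.
#' @return a tibble of population metadata.
#' @export
read_population_meta <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"population" %in% names(meta)) stop_input("metadata lacks a 'population' column")
  if (anyDuplicated(meta$population)) stop_input("duplicate population ids in metadata")
  if ("lat" %in% names(meta) && any(abs(meta$lat) > 90, na.rm = TRUE)) {
    stop_input("latitude outside [-90, 90]")
  }
  if ("lon" %in% names(meta) && any(abs(meta$lon) > 180, na.rm = TRUE)) {
    stop_input("longitude outside [-180, 180]")
  }
  if ("n" %in% names(meta) && any(meta$n < 1, na.rm = TRUE)) {
    stop_input("sample sizes must be >= 1")
  }
  meta
}

#' Read a haplogroup frequency/count table
#'
#' Tab-separated: header row of haplogroup labels, first column population
#' ids, cells either relative frequencies or integer counts (auto-detected:
#' an all-integer table whose rows do not sum to one is treated as counts and
#' renormalised).
#'
#' @param path haplogroup table TSV.
#' @param meta_path optional metadata TSV; every population in the table must
#'   be present in the metadata.
#' @return a `haplogroup_table`.
#' @export
read_haplogroup_table <- function(path, meta_path = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  meta <- if (!is.null(meta_path)) read_population_meta(meta_path) else NULL
  if (!is.null(meta)) {
    missing <- !(as.character(tbl[[1]]) %in% meta$population)
    if (any(missing)) {
      i <- which(missing)[1]
      stop_input("population '%s' (row %d of '%s') not found in metadata",
                 as.character(tbl[[1]])[i], i, path)
    }
  }
  as_haplogroup_table(tbl, meta = meta)
}

#' Write a haplogroup table to TSV
#'
#' Counts are written when present, frequencies otherwise, so that a
#' write/read round trip reproduces the table.
#'
#' @param x a `haplogroup_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplogroup_table <- function(x, path) {
  x <- as_haplogroup_table(x)
  what <- if (!is.null(x$counts)) "counts" else "freq"
  readr::write_tsv(as_tibble.haplogroup_table(x, what = what), path)
  invisible(path)
}

# counts matrix or informative failure (AMOVA entry point)
require_counts <- function(x) {
  x <- as_haplogroup_table(x)
  if (is.null(x$counts)) stop_input("this analysis needs integer haplogroup counts, not frequencies")
  x$counts
}
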