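#' Construct an IBD segment set
#'
#' Holds per-pair identity-by-descent segments with genetic-map coordinates
#' (half-open `[start_cM, end_cM)`), plus the individual-to-population
#' register needed for group-level statistics.
#'
#' @param segments tibble with columns `id1`, `id2`, `chromosome`,
#'   `start_cM`, `end_cM`.
#' @param individuals tibble with columns `individual_id`, `population_id`;
#'   every id occurring in `segments` must be registered.
#' @return an object of class `ibd_segments`.
#' @export
ibd_segments <- function(segments, individuals) {
  segments <- tibble::as_tibble(segments)
  individuals <- tibble::as_tibble(individuals)
  need <- c("id1", "id2", "chromosome", "start_cM", "end_cM")
  if (!all(need %in% names(segments))) {
    stop_input("segments need columns: %s", paste(need, collapse = ", "))
  }
  if (!all(c("individual_id", "population_id") %in% names(individuals))) {
    stop_input("individuals need columns individual_id, population_id")
  }
  if (anyDuplicated(individuals$individual_id)) stop_input("duplicate individual ids")
  if (any(segments$id1 == segments$id2)) stop_input("segment with identical endpoints (id1 == id2)")
  if (any(segments$end_cM <= segments$start_cM)) {
    stop_input("segment end before (or at) start in genetic-map coordinates")
  }
  unknown <- setdiff(unique(c(segments$id1, segments$id2)), individuals$individual_id)
  if (length(unknown)) {
    stop_input("segment ids not registered in individuals: %s",
               paste(head(unknown, 5), collapse = ", "))
  }
  segments$length_cM <- segments$end_cM - segments$start_cM
  structure(list(segments = segments, individuals = individuals),
            class = "ibd_segments")
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat(sprintf("<ibd_segments> %d segments among %d individuals (%d populations)\n",
              nrow(x$segments), nrow(x$individuals),
              length(unique(x$individuals$population_id))))
  invisible(x)
}

#' Read a genetic map
#'
#' PLINK `.map`-like whitespace-separated file: chromosome, marker name (or
#' index), genetic position in cM in the third column; a fourth bp column is
#' tolerated and ignored. `#` comment lines are skipped.
#'
#' @param path map file path.
#' @return tibble with `chromosome`, `marker`, `position_cM`.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_table(path, comment = "#", col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(map) < 3) stop_input("genetic map needs >= 3 columns (chromosome, marker, cM)")
  out <- tibble::tibble(
    chromosome = as.character(map[[1]]),
    marker = as.character(map[[2]]),
    position_cM = as.numeric(map[[3]])
  )
  if (any(!is.finite(out$position_cM))) stop_input("non-numeric cM positions in genetic map")
  if (anyDuplicated(paste(out$chromosome, out$marker))) {
    stop_input("duplicate (chromosome, marker) entries in genetic map")
  }
  out
}

#' Read fastIBD-style pairwise IBD segments
#'
#' Whitespace-separated columns: `id1`, `id2`, `chromosome`, `start_marker`,
#' `end_marker` and an optional score. Marker names are resolved to cM
#' through the genetic map; segments whose mapped length falls below
#' `min_cM` are dropped (the count is reported via [message()]).
#'
#' @param path segment file path.
#' @param map_path genetic map path (see [read_genetic_map()]).
#' @param individuals_path optional TSV with `individual_id`,
#'   `population_id`; when absent, individuals are inferred from the segment
#'   file with unknown population.
#' @param min_cM minimum retained segment length in cM (default 1).
#' @return an `ibd_segments` object.
#' @export
read_ibd_segments <- function(path, map_path, individuals_path = NULL, min_cM = 1) {
  raw <- readr::read_table(path, comment = "#", col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 5) {
    stop_input("segment file needs >= 5 columns (id1 id2 chromosome start_marker end_marker)")
  }
  seg <- tibble::tibble(
    id1 = as.character(raw[[1]]), id2 = as.character(raw[[2]]),
    chromosome = as.character(raw[[3]]),
    start_marker = as.character(raw[[4]]), end_marker = as.character(raw[[5]])
  )
  map <- read_genetic_map(map_path)
  key <- paste(map$chromosome, map$marker)
  lookup <- function(chrom, marker) {
    pos <- map$position_cM[match(paste(chrom, marker), key)]
    if (anyNA(pos)) {
      bad <- marker[is.na(pos)][1]
      stop_input("marker '%s' absent from the genetic map", bad)
    }
    pos
  }
  seg$start_cM <- lookup(seg$chromosome, seg$start_marker)
  seg$end_cM <- lookup(seg$chromosome, seg$end_marker)
  if (any(seg$end_cM <= seg$start_cM)) {
    i <- which(seg$end_cM <= seg$start_cM)[1]
    stop_input("segment %d ends at or before its start (%s: %.4g -> %.4g cM)",
               i, seg$chromosome[i], seg$start_cM[i], seg$end_cM[i])
  }
  short <- (seg$end_cM - seg$start_cM) < min_cM
  if (any(short)) {
    message(sprintf("dropped %d segment(s) shorter than %g cM", sum(short), min_cM))
    seg <- seg[!short, , drop = FALSE]
  }
  if (!is.null(individuals_path)) {
    ind <- readr::read_tsv(individuals_path, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  } else {
    ind <- tibble::tibble(
      individual_id = unique(c(seg$id1, seg$id2)),
      population_id = NA_character_
    )
  }
  ibd_segments(seg[, c("id1", "id2", "chromosome", "start_cM", "end_cM")], ind)
}

#' Write IBD segments and their individual register
#'
#' @param x an `ibd_segments` object.
#' @param path output TSV for the segment table (cM coordinates).
#' @param individuals_path optional output TSV for the individual register.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(x, path, individuals_path = NULL) {
  stopifnot(inherits(x, "ibd_segments"))
  readr::write_tsv(x$segments, path)
  if (!is.null(individuals_path)) readr::write_tsv(x$individuals, individuals_path)
  invisible(path)
}
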