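#' Construct a wordlist matrix
#'
#' Swadesh-style multistate cognate matrix: per (concept item, lect) a
#' possibly empty set of integer cognate-class ids; several ids in one cell
#' encode synonyms. Cognate ids are comparable across lects within an item
#' only.
#'
#' @param cells a list-matrix (items x lects) of integer vectors; empty
#'   vectors mean missing data. Must carry item rownames and lect colnames.
#' @param weights optional positive per-item stability weights (default 1);
#'   these implement the individual relative index of stability.
#' @return an object of class `wordlist`.
#' @export
wordlist <- function(cells, weights = NULL) {
  if (!is.matrix(cells) || !is.list(cells[1])) {
    if (!is.matrix(cells)) stop_input("cells must be a list-matrix")
  }
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    stop_input("cells must carry item rownames and lect colnames")
  }
  weights <- weights %||% rep(1, nrow(cells))
  if (length(weights) != nrow(cells) || any(weights <= 0)) {
    stop_input("weights must be positive, one per item")
  }
  nonmiss <- apply(cells, 2, function(col) any(lengths(col) > 0))
  if (any(!nonmiss)) {
    stop_input("lect(s) with no non-missing cells: %s",
               paste(colnames(cells)[!nonmiss], collapse = ", "))
  }
  structure(list(cells = cells, items = rownames(cells),
                 lects = colnames(cells), weights = weights),
            class = "wordlist")
}

#' @export
print.wordlist <- function(x, ...) {
  cat(sprintf("<wordlist> %d items x %d lects\n", length(x$items), length(x$lects)))
  invisible(x)
}

#' Read a wordlist matrix from TSV
#'
#' Rows are concept items, columns are lects; each cell holds
#' comma-separated integer cognate-class ids, with an empty cell or `?`
#' meaning missing. `#` comment lines are ignored.
#'
#' @param path wordlist TSV.
#' @param weights_path optional two-column TSV (`item`, `weight`) supplying
#'   per-item stability weights.
#' @return a `wordlist`.
#' @export
read_wordlist <- function(path, weights_path = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  items <- as.character(tbl[[1]])
  lects <- names(tbl)[-1]
  cells <- matrix(vector("list", length(items) * length(lects)),
                  nrow = length(items), dimnames = list(items, lects))
  for (j in seq_along(lects)) {
    raw <- tbl[[j + 1]]
    cells[, j] <- lapply(raw, function(s) {
      if (is.na(s) || s == "" || s == "?") return(integer(0))
      v <- suppressWarnings(as.integer(strsplit(s, ",")[[1]]))
      if (anyNA(v)) stop_input("non-integer cognate id in cell '%s'", s)
      unique(v)
    })
  }
  weights <- NULL
  if (!is.null(weights_path)) {
    w <- readr::read_tsv(weights_path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
    weights <- w[[2]][match(items, as.character(w[[1]]))]
    if (anyNA(weights)) stop_input("weights file misses some items")
  }
  wordlist(cells, weights)
}

#' Write a wordlist matrix to TSV
#'
#' @param x a `wordlist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wordlist <- function(x, path) {
  stopifnot(inherits(x, "wordlist"))
  tbl <- tibble::tibble(item = x$items)
  for (l in x$lects) {
    tbl[[l]] <- vapply(x$cells[, l], function(v) {
      if (!length(v)) "" else paste(v, collapse = ",")
    }, character(1))
  }
  readr::write_tsv(tbl, path, na = "")
  invisible(path)
}

#' Lexicostatistical distances from a cognate matrix
#'
#' For each pair of lects, the compared items are those non-missing in
#' both; an item matches when the two cognate-class sets intersect (the
#' synonym rule). The cognate share is the weight-sum of matched items over
#' the weight-sum of compared items; the distance is one minus the share.
#'
#' @param w a `wordlist`.
#' @return a labelled distance matrix with the share matrix in attribute
#'   `"share"`.
#' @export
lex_distance_matrix <- function(w) {
  stopifnot(inherits(w, "wordlist"))
  L <- length(w$lects)
  if (L < 2) stop_input("need at least 2 lects")
  share <- matrix(1, L, L, dimnames = list(w$lects, w$lects))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      ci <- w$cells[, i]; cj <- w$cells[, j]
      both <- lengths(ci) > 0 & lengths(cj) > 0
      if (!any(both)) {
        stop_input("no items compared for pair %s-%s", w$lects[i], w$lects[j])
      }
      matched <- vapply(which(both), function(k) {
        length(intersect(ci[[k]], cj[[k]])) > 0
      }, logical(1))
      share[i, j] <- share[j, i] <-
        sum(w$weights[which(both)[matched]]) / sum(w$weights[both])
    }
  }
  d <- as_dist_matrix(1 - share)
  attr(d, "share") <- share
  d
}

#' Glottochronological dating from a cognate share
#'
#' Converts a cognate share `c` into a divergence date in years before
#' present. The default is the root-corrected decay law
#' \eqn{t = \sqrt{-\ln c / (2 \lambda c)}} (millennia) with
#' \eqn{\lambda = 0.05} per squared millennium, whose division by `c`
#' compensates for the stability bias of surviving comparisons. The simple
#' square-root law \eqn{t = \sqrt{-\ln c / (2\lambda)}} and the
#' constant-rate law \eqn{t = -\ln c / (2\lambda)} (with `lambda` then a
#' per-millennium replacement rate; the exact inverse of a homogeneous
#' Poisson replacement clock) are available as alternatives.
#'
#' @param c cognate share(s) in (0, 1].
#' @param lambda decay constant; interpretation depends on `law`.
#' @param law `"starostin"` (default), `"sqrt"`, or `"constant"`.
#' @return date(s) in years before present; `c = 1` dates to 0.
#' @export
glotto_date <- function(c, lambda = 0.05, law = c("starostin", "sqrt", "constant")) {
  law <- match.arg(law)
  if (any(c <= 0)) stop_input("cognate share must be positive")
  if (any(c > 1 + 1e-12)) stop_input("cognate share cannot exceed 1")
  c <- pmin(c, 1)
  t_mill <- switch(law,
    starostin = sqrt(-log(c) / (2 * lambda * c)),
    sqrt = sqrt(-log(c) / (2 * lambda)),
    constant = -log(c) / (2 * lambda)
  )
  1000 * t_mill
}
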