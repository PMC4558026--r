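#' Validate and coerce a labelled distance matrix
#'
#' Distance matrices are the common currency of the pipeline: Nei genetic
#' distances, great-circle geographic distances and lexicostatistical
#' distances all travel as labelled, symmetric, zero-diagonal matrices with
#' non-negative entries.
#'
#' @param x a square numeric matrix with identical row and column names, or a
#'   data frame whose first column holds labels.
#' @param tol asymmetries up to `tol` are symmetrised by averaging; anything
#'   larger is an error.
#' @return a validated base matrix with `dimnames`.
#' @export
as_dist_matrix <- function(x, tol = 1e-6) {
  if (is.data.frame(x)) {
    labels <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- labels
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) stop_input("distance matrix must be numeric")
  if (nrow(x) != ncol(x)) stop_input("distance matrix is not square (%d x %d)", nrow(x), ncol(x))
  if (is.null(rownames(x))) stop_input("distance matrix must carry labels")
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!identical(rownames(x), colnames(x))) {
    stop_input("row and column labels differ")
  }
  if (anyDuplicated(rownames(x))) stop_input("duplicate labels in distance matrix")
  if (any(!is.finite(x))) stop_input("non-finite entries in distance matrix")
  if (any(x < -tol)) stop_input("negative entries in distance matrix")
  asym <- max(abs(x - t(x)))
  if (asym > tol) {
    stop_input("asymmetric distance matrix (max |d_ij - d_ji| = %.3g > %.1g)", asym, tol)
  }
  x <- (x + t(x)) / 2
  if (any(abs(diag(x)) > tol)) stop_input("non-zero diagonal in distance matrix")
  diag(x) <- 0
  x[x < 0] <- 0
  x
}

#' Read a square distance matrix from TSV
#'
#' Expects a tab-separated file whose header row and first column carry the
#' same labels in the same order. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @inheritParams as_dist_matrix
#' @return a labelled distance matrix.
#' @export
read_distance_matrix <- function(path, tol = 1e-6) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  labels <- as.character(tbl[[1]])
  header <- names(tbl)[-1]
  if (!identical(header, labels)) {
    stop_input("row labels and column labels disagree in '%s'", path)
  }
  as_dist_matrix(tbl, tol = tol)
}

#' Write a distance matrix to TSV
#'
#' @param d a labelled distance matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_dist_matrix(d)
  tbl <- tibble::as_tibble(d, .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, label = rownames(d), .before = 1)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Distance matrix as a tidy pair table
#'
#' @param d a labelled distance matrix.
#' @return a tibble with one row per unordered pair: `label_a`, `label_b`,
#'   `distance`.
#' @export
dist_pairs <- function(d) {
  d <- as_dist_matrix(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(
    label_a = rownames(d)[idx[, 1]],
    label_b = colnames(d)[idx[, 2]],
    distance = d[idx]
  )
}
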