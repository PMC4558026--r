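#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' Pure evaluation half of non-metric MDS: configuration distances are
#' monotonically regressed on the observed dissimilarities (pool-adjacent-
#' violators, primary treatment of ties) and
#' \eqn{\sqrt{\sum (\hat d_{ij} - \delta_{ij})^2 / \sum \delta_{ij}^2}}
#' is returned, where \eqn{\delta} are the configuration distances and
#' \eqn{\hat d} the disparities.
#'
#' @param d a labelled dissimilarity matrix.
#' @param coordinates a numeric matrix with rownames, or a tibble with a
#'   `label` column followed by coordinate columns; labels must match `d`.
#' @return stress-1, a non-negative scalar.
#' @export
stress1 <- function(d, coordinates) {
  d <- as_dist_matrix(d)
  conf <- coords_matrix(coordinates)
  conf <- conf[match(rownames(d), rownames(conf)), , drop = FALSE]
  if (anyNA(rownames(conf))) stop_input("configuration labels do not match the matrix")
  dv <- upper_vec(d)
  del <- upper_vec(as.matrix(dist(conf)))
  # primary ties: within blocks of tied dissimilarities the configuration
  # distances may order freely, so sort them ascending before PAVA
  o <- order(dv, del)
  dhat <- isoreg(del[o])$yf
  sqrt(sum((del[o] - dhat)^2) / sum(del^2))
}

coords_matrix <- function(coordinates) {
  if (is.data.frame(coordinates)) {
    m <- as.matrix(coordinates[, -1, drop = FALSE])
    rownames(m) <- as.character(coordinates[[1]])
    return(m)
  }
  if (!is.matrix(coordinates) || is.null(rownames(coordinates))) {
    stop_input("coordinates must be a labelled matrix or a label + columns data frame")
  }
  coordinates
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Embeds a distance matrix in `k` dimensions by isotonic-regression MDS.
#' The first restart starts from classical (Torgerson) scaling, subsequent
#' restarts from random Gaussian configurations; the lowest-stress solution
#' wins. The reported stress is [stress1()] of the returned configuration,
#' so result and evaluator agree by construction.
#'
#' @param d a labelled distance matrix.
#' @param k embedding dimension (default 2).
#' @param restarts number of starts (>= 1, default 8).
#' @param seed integer seed making the random restarts reproducible.
#' @return an object of class `mds_result` with `coordinates` (tibble:
#'   `label`, `dim1..dimk`, centred per axis), `stress`, `k`, `n_restarts`,
#'   `converged`.
#' @export
mds_embed <- function(d, k = 2, restarts = 8, seed = NULL) {
  d <- as_dist_matrix(d)
  if (k < 1) stop_input("k must be >= 1")
  if (restarts < 1) stop_input("restarts must be >= 1")
  if (all(d == 0)) stop_input("degenerate distances: all entries are zero")
  n <- nrow(d)
  dd <- stats::as.dist(d)
  if (!is.null(seed)) set.seed(seed)
  torg <- suppressWarnings(cmdscale(dd, k = k))
  if (ncol(torg) < k) { # rank-deficient double centring: pad with zeros
    torg <- cbind(torg, matrix(0, n, k - ncol(torg)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    y0 <- if (r == 1) torg else matrix(rnorm(n * k), n, k)
    fit <- try(vegan::monoMDS(dd, y = y0, k = k, model = "global",
                              maxit = 500, smin = 1e-9, sfgrmin = 1e-11,
                              sratmax = 1 - 1e-9), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop_input("MDS failed on every restart")
  conf <- best$points
  conf <- sweep(conf, 2, colMeans(conf))
  rownames(conf) <- rownames(d)
  colnames(conf) <- paste0("dim", seq_len(k))
  coords <- tibble::add_column(tibble::as_tibble(conf), label = rownames(d), .before = 1)
  structure(
    list(coordinates = coords,
         stress = stress1(d, conf),
         k = k, n_restarts = restarts,
         # icause 1 = iteration cap hit; 2/3 = stress-based stopping rules
         converged = isTRUE(best$icause != 1) || best$stress < 1e-6),
    class = "mds_result"
  )
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> k = %d, stress-1 = %.4f (%d restarts)\n",
              x$k, x$stress, x$n_restarts))
  invisible(x)
}

#' @export
tidy.mds_result <- function(x, ...) x$coordinates

#' @export
glance.mds_result <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k,
                 n_restarts = x$n_restarts, converged = x$converged)
}

#' @export
autoplot.mds_result <- function(object, ...) {
  stopifnot(object$k >= 2)
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2, label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2",
      title = sprintf("non-metric MDS (stress-1 = %.3f)", object$stress)
    )
}
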