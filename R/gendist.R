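#' Nei's standard genetic distance between two frequency vectors
#'
#' For haplogroup frequency vectors `p` and `q`, the normalised identity is
#' \eqn{I = J_{xy} / \sqrt{J_x J_y}} with \eqn{J_{xy} = \sum_i p_i q_i},
#' \eqn{J_x = \sum_i p_i^2}, \eqn{J_y = \sum_i q_i^2}, and the distance is
#' \eqn{D = -\ln I}. The plain plug-in estimator is used (no small-sample
#' bias correction), matching common haplogroup-frequency practice.
#'
#' When the two vectors share no haplogroup (\eqn{J_{xy} = 0}) the distance
#' is infinite; by default a finite cap is returned with a warning so that
#' downstream ordination and matrix tests stay finite. `strict = TRUE` turns
#' this into an error.
#'
#' @param p,q non-negative frequency vectors of equal length, each summing
#'   to one (tolerance 1e-6).
#' @param cap value returned for disjoint support (default 10); any computed
#'   distance exceeding the cap is also truncated to it.
#' @param strict error instead of cap-and-warn on disjoint support.
#' @return a non-negative scalar distance.
#' @export
nei_distance <- function(p, q, cap = 10, strict = FALSE) {
  if (length(p) != length(q)) stop_input("frequency vectors differ in length")
  if (any(p < 0) || any(q < 0)) stop_input("negative frequencies")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_input("frequency vectors must each sum to 1")
  }
  jxy <- sum(p * q)
  if (jxy == 0) {
    if (strict) stop_input("no shared haplogroups between the two populations")
    rlang::warn("no shared haplogroups; returning the configured cap")
    return(cap)
  }
  i <- jxy / sqrt(sum(p^2) * sum(q^2))
  d <- -log(min(i, 1))
  min(max(d, 0), cap)
}

#' Pairwise Nei distance matrix from a haplogroup table
#'
#' @param x a `haplogroup_table` or a coercible data frame (see
#'   [as_haplogroup_table()]).
#' @inheritParams nei_distance
#' @return a labelled symmetric distance matrix.
#' @export
nei_distance_matrix <- function(x, cap = 10, strict = FALSE) {
  x <- as_haplogroup_table(x)
  f <- x$freq
  n <- nrow(f)
  if (n < 2) stop_input("need at least 2 populations")
  jx <- rowSums(f^2)
  jxy <- f %*% t(f)
  zero <- which(jxy == 0 & upper.tri(jxy), arr.ind = TRUE)
  if (nrow(zero)) {
    pairs <- paste0(rownames(f)[zero[, 1]], "-", rownames(f)[zero[, 2]])
    if (strict) stop_input("no shared haplogroups for pair(s): %s", paste(pairs, collapse = ", "))
    rlang::warn(sprintf("no shared haplogroups for pair(s) %s; using cap %g",
                        paste(pairs, collapse = ", "), cap))
  }
  i <- jxy / sqrt(outer(jx, jx))
  d <- -log(pmin(i, 1))
  d[!is.finite(d) | d > cap] <- cap
  diag(d) <- 0
  dimnames(d) <- list(rownames(f), rownames(f))
  as_dist_matrix(d)
}

#' Mean pairwise distance within or between population groups
#'
#' With one group, the mean over its unordered distinct pairs (the study's
#' within-group summary, e.g. the East Slavic mean Nei distance); with two
#' disjoint groups, the mean over all cross pairs (e.g. North Russians
#' against the remaining East Slavs).
#'
#' @param d a labelled distance matrix.
#' @param a character vector of member labels of the (first) group.
#' @param b optional character vector for a second, disjoint group.
#' @param name_a,name_b optional display names for the groups.
#' @return a one-row tibble: `group_a`, `group_b`, `mean_d`, `n_pairs`.
#' @export
mean_group_distance <- function(d, a, b = NULL, name_a = NULL, name_b = NULL) {
  d <- as_dist_matrix(d)
  miss <- setdiff(c(a, b), rownames(d))
  if (length(miss)) stop_input("labels absent from matrix: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(a) || anyDuplicated(b)) stop_input("duplicated labels within a group")
  if (is.null(b)) {
    if (length(a) < 2) stop_input("no within-group pairs: group has a single member")
    sub <- d[a, a, drop = FALSE]
    vals <- upper_vec(sub)
    out_b <- NA_character_
  } else {
    if (length(intersect(a, b)) > 0) {
      stop_input("groups overlap: %s", paste(intersect(a, b), collapse = ", "))
    }
    vals <- as.vector(d[a, b, drop = FALSE])
    out_b <- name_b %||% paste(b, collapse = "+")
  }
  tibble::tibble(
    group_a = name_a %||% paste(a, collapse = "+"),
    group_b = out_b,
    mean_d = mean(vals),
    n_pairs = length(vals)
  )
}

#' Great-circle distance matrix from population coordinates
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param meta tibble with columns `population`, `lat`, `lon` (decimal
#'   degrees).
#' @param radius_km sphere radius in km.
#' @return a labelled distance matrix in km.
#' @export
haversine_matrix <- function(meta, radius_km = 6371) {
  need <- c("population", "lat", "lon")
  if (!all(need %in% names(meta))) stop_input("meta needs columns population, lat, lon")
  if (any(abs(meta$lat) > 90) || any(abs(meta$lon) > 180)) {
    stop_input("coordinates out of range")
  }
  phi <- meta$lat * pi / 180
  lam <- meta$lon * pi / 180
  n <- nrow(meta)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  h[h > 1] <- 1
  d <- 2 * radius_km * asin(sqrt(h))
  dimnames(d) <- list(meta$population, meta$population)
  diag(d) <- 0
  as_dist_matrix(d, tol = 1e-6)
}
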