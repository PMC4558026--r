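#' Default IBD segment length classes
#'
#' Ten classes in cM with half-cM boundaries at the short end and an
#' open-ended last class: `[1,1.5), [1.5,2), [2,2.5), [2.5,3), [3,4),
#' [4,5), [5,6), [6,8), [8,10), [10,Inf)`.
#'
#' @param edges increasing numeric breakpoints; the last may be `Inf`
#'   (appended if missing).
#' @return a validated numeric vector of class edges.
#' @export
ibd_length_bins <- function(edges = c(1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, Inf)) {
  if (is.unsorted(edges, strictly = TRUE)) stop_input("bin edges must be strictly increasing")
  if (edges[1] < 0) stop_input("bin edges must be non-negative")
  if (is.finite(edges[length(edges)])) edges <- c(edges, Inf)
  edges
}

bin_labels <- function(edges) {
  k <- length(edges) - 1
  sprintf("[%g,%s)", edges[seq_len(k)],
          ifelse(is.finite(edges[-1]), sprintf("%g", edges[-1]), "Inf"))
}

group_individuals <- function(x, members) {
  x$individuals$individual_id[x$individuals$population_id %in% members]
}

# per-class segment counts between two individual id sets
cross_class_counts <- function(segments, ids_a, ids_b, edges) {
  in_ab <- (segments$id1 %in% ids_a & segments$id2 %in% ids_b) |
    (segments$id1 %in% ids_b & segments$id2 %in% ids_a)
  len <- segments$length_cM[in_ab]
  len <- len[len >= edges[1]]
  cls <- findInterval(len, edges)
  tabulate(cls, nbins = length(edges) - 1)
}

#' Average IBD segments per cross-group pair, by length class
#'
#' The ibd-statistic: for two disjoint groups of individuals, the number of
#' IBD segments whose cM length falls in each class, over all cross-group
#' pairs, divided by the number of pairs. Pairs sharing no segment count in
#' the denominator.
#'
#' @param x an `ibd_segments` object.
#' @param a,b character vectors of population ids defining the two groups
#'   (must be disjoint at the individual level).
#' @param bins class edges (see [ibd_length_bins()]).
#' @param name_a,name_b optional display names.
#' @return an object of class `ibd_profile`: tibble `per_class`
#'   (`class`, `lower`, `upper`, `avg_segments`), `n_pairs`, `total`.
#' @export
ibd_statistic <- function(x, a, b, bins = ibd_length_bins(),
                          name_a = NULL, name_b = NULL) {
  stopifnot(inherits(x, "ibd_segments"))
  edges <- ibd_length_bins(bins)
  ids_a <- group_individuals(x, a)
  ids_b <- group_individuals(x, b)
  if (!length(ids_a) || !length(ids_b)) stop_input("empty group")
  overlap <- intersect(ids_a, ids_b)
  if (length(overlap)) {
    stop_input("groups overlap at the individual level (%d shared individuals)", length(overlap))
  }
  n_pairs <- length(ids_a) * length(ids_b)
  counts <- cross_class_counts(x$segments, ids_a, ids_b, edges)
  per_class <- tibble::tibble(
    class = bin_labels(edges),
    lower = edges[-length(edges)],
    upper = edges[-1],
    avg_segments = counts / n_pairs
  )
  structure(
    list(per_class = per_class, n_pairs = n_pairs,
         total = sum(counts) / n_pairs,
         group_a = name_a %||% paste(a, collapse = "+"),
         group_b = name_b %||% paste(b, collapse = "+")),
    class = "ibd_profile"
  )
}

#' @export
print.ibd_profile <- function(x, ...) {
  cat(sprintf("<ibd_profile> %s vs %s: %.4g segments/pair over %d pairs\n",
              x$group_a, x$group_b, x$total, x$n_pairs))
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.ibd_profile <- function(x, ...) {
  tibble::add_column(x$per_class, group_a = x$group_a, group_b = x$group_b,
                     .before = 1)
}

#' @export
glance.ibd_profile <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 total = x$total, n_pairs = x$n_pairs)
}

#' @export
autoplot.ibd_profile <- function(object, ...) {
  df <- object$per_class
  df$class <- factor(df$class, levels = df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$avg_segments, group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "IBD segment length class (cM)",
                  y = "average segments per pair",
                  title = sprintf("%s vs %s", object$group_a, object$group_b)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ibd-statistic of one focal group against several comparators
#'
#' @inheritParams ibd_statistic
#' @param groups a named list of character vectors (population ids per
#'   comparator group).
#' @param focal character vector of population ids of the focal group.
#' @param focal_name optional display name of the focal group.
#' @return a tibble: one row per (comparator, length class) with
#'   `avg_segments`, plus `n_pairs` and group names.
#' @export
sharing_profile_table <- function(x, groups, focal, bins = ibd_length_bins(),
                                  focal_name = NULL) {
  if (is.null(names(groups))) stop_input("groups must be a named list")
  purrr::map_dfr(names(groups), function(g) {
    pr <- ibd_statistic(x, focal, groups[[g]], bins = bins,
                        name_a = focal_name %||% "focal", name_b = g)
    out <- tidy(pr)
    out$n_pairs <- pr$n_pairs
    out
  })
}

#' Permutation comparison of IBD sharing between two comparator groups
#'
#' Tests whether a focal group shares more IBD segments per pair with
#' comparator `c1` than with comparator `c2`:
#' `delta = ibd_statistic(focal, c1) - ibd_statistic(focal, c2)`, totalled
#' over the selected length classes. The null reassigns the individuals of
#' `c1` and `c2` at random to two pseudo-groups of the original sizes
#' (individuals, not populations, are the exchangeable units) and the
#' two-sided p-value is `(b + 1) / (m + 1)`.
#'
#' @inheritParams ibd_statistic
#' @param focal,c1,c2 character vectors of population ids; `focal` must be
#'   disjoint from both comparators.
#' @param permutations permutation count (0 = delta only, no p-value).
#' @param seed integer seed.
#' @param classes optional integer indices of the length classes entering
#'   the totalled delta (default: all).
#' @return an object of class `sharing_comparison`: `delta` (total),
#'   `per_class_delta`, `p_value`, `permutations`.
#' @export
compare_sharing <- function(x, focal, c1, c2, bins = ibd_length_bins(),
                            permutations = 999, seed = NULL, classes = NULL) {
  stopifnot(inherits(x, "ibd_segments"))
  edges <- ibd_length_bins(bins)
  k <- length(edges) - 1
  classes <- classes %||% seq_len(k)
  if (any(classes < 1 | classes > k)) stop_input("class index out of range")
  ids_f <- group_individuals(x, focal)
  ids_1 <- group_individuals(x, c1)
  ids_2 <- group_individuals(x, c2)
  if (length(intersect(ids_f, c(ids_1, ids_2)))) {
    stop_input("focal group overlaps a comparator at the individual level")
  }
  if (length(intersect(ids_1, ids_2))) stop_input("comparator groups overlap")
  n_f <- length(ids_f); n_1 <- length(ids_1); n_2 <- length(ids_2)
  if (!n_f || !n_1 || !n_2) stop_input("empty group")
  # per pooled individual: class-count vector of its segments with the focal set
  seg <- x$segments
  pool <- c(ids_1, ids_2)
  with_f <- (seg$id1 %in% ids_f & seg$id2 %in% pool) |
    (seg$id2 %in% ids_f & seg$id1 %in% pool)
  seg <- seg[with_f, , drop = FALSE]
  other <- ifelse(seg$id1 %in% ids_f, seg$id2, seg$id1)
  len <- seg$length_cM
  keep <- len >= edges[1]
  other <- other[keep]; len <- len[keep]
  cls <- findInterval(len, edges)
  in_sel <- cls %in% classes
  S <- matrix(0, nrow = length(pool), ncol = k, dimnames = list(pool, NULL))
  if (length(other)) {
    tab <- table(factor(other, levels = pool), factor(cls, levels = seq_len(k)))
    S[] <- as.numeric(tab)
  }
  sel_counts <- rowSums(S[, classes, drop = FALSE])
  is_1 <- pool %in% ids_1
  delta_of <- function(sel1) {
    sum(sel_counts[sel1]) / (n_f * n_1) - sum(sel_counts[!sel1]) / (n_f * n_2)
  }
  delta <- delta_of(is_1)
  per_class_delta <- colSums(S[is_1, , drop = FALSE]) / (n_f * n_1) -
    colSums(S[!is_1, , drop = FALSE]) / (n_f * n_2)
  p <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (i in seq_len(permutations)) {
      sel <- logical(length(pool))
      sel[sample.int(length(pool), n_1)] <- TRUE
      if (abs(delta_of(sel)) >= abs(delta) - 1e-12) b <- b + 1L
    }
    p <- (b + 1) / (permutations + 1)
  }
  structure(
    list(delta = delta,
         per_class_delta = tibble::tibble(class = bin_labels(edges),
                                          delta = unname(per_class_delta)),
         classes = classes, p_value = p, permutations = permutations,
         focal = paste(focal, collapse = "+"),
         comparator_1 = paste(c1, collapse = "+"),
         comparator_2 = paste(c2, collapse = "+")),
    class = "sharing_comparison"
  )
}

#' @export
print.sharing_comparison <- function(x, ...) {
  cat(sprintf("<sharing_comparison> %s: (%s) - (%s)\n  delta = %.4g, p = %s (%d permutations)\n",
              x$focal, x$comparator_1, x$comparator_2, x$delta,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4),
              x$permutations))
  invisible(x)
}

#' @export
tidy.sharing_comparison <- function(x, ...) x$per_class_delta

#' @export
glance.sharing_comparison <- function(x, ...) {
  tibble::tibble(delta = x$delta, p_value = x$p_value,
                 permutations = x$permutations)
}
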