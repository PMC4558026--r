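# Mantel and partial Mantel permutation tests between distance matrices.
# r is the Pearson correlation over the n(n-1)/2 upper-triangle pairs; the
# null permutes rows and columns of the second matrix simultaneously.

mantel_r <- function(A, B) cor(upper_vec(A), upper_vec(B))

partial_r <- function(r_ab, r_ac, r_bc) {
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

check_mantel_input <- function(A, B) {
  A <- as_dist_matrix(A)
  B <- align_labels(as_dist_matrix(B), rownames(A))
  if (nrow(A) < 4) stop_input("Mantel test needs n >= 4")
  if (stats::sd(upper_vec(A)) == 0) stop_input("constant matrix: first matrix has zero variance")
  if (stats::sd(upper_vec(B)) == 0) stop_input("constant matrix: second matrix has zero variance")
  list(A = A, B = B)
}

mantel_p <- function(r_obs, r_perm, alternative) {
  m <- length(r_perm)
  b <- switch(alternative,
              greater = sum(r_perm >= r_obs),
              less = sum(r_perm <= r_obs),
              two.sided = sum(abs(r_perm) >= abs(r_obs)))
  (b + 1) / (m + 1)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

new_mantel_result <- function(r, p, m, alternative, partial_on = NA_character_,
                              exact = FALSE) {
  structure(
    list(r = r, p_value = p, permutations = m, alternative = alternative,
         partial_on = partial_on, exact = exact),
    class = "mantel_result"
  )
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over unordered pairs, with a permutation null built
#' by simultaneously permuting rows and columns of the second matrix.
#' Matrices are aligned by label before testing. For small matrices
#' (`n <= 7`) with `exact = TRUE` (or when `permutations` reaches `n!`) the
#' full permutation distribution is enumerated and the p-value is exact.
#'
#' @param A,B labelled distance matrices over the same label set.
#' @param permutations number of random permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default; the study reports positive
#'   correlations), `"less"`, or `"two.sided"`.
#' @param exact force (or forbid) exhaustive enumeration; `NULL` chooses
#'   automatically.
#' @return an object of class `mantel_result` with `r`, `p_value`,
#'   `permutations`, `alternative`, `exact`.
#' @export
mantel_test <- function(A, B, permutations = 999, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        exact = NULL) {
  alternative <- match.arg(alternative)
  mats <- check_mantel_input(A, B)
  A <- mats$A; B <- mats$B
  n <- nrow(A)
  r_obs <- mantel_r(A, B)
  use_exact <- isTRUE(exact) || (is.null(exact) && n <= 7 && permutations >= factorial(n))
  if (use_exact && n > 9) stop_input("exact enumeration is limited to n <= 9")
  if (use_exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(o) mantel_r(A, B[o, o]))
    m <- nrow(perms)
    b <- switch(alternative,
                greater = sum(r_perm >= r_obs - 1e-12),
                less = sum(r_perm <= r_obs + 1e-12),
                two.sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12))
    return(new_mantel_result(r_obs, b / m, m, alternative, exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(i) {
    o <- sample.int(n)
    mantel_r(A, B[o, o])
  }, numeric(1))
  new_mantel_result(r_obs, mantel_p(r_obs, r_perm, alternative),
                    permutations, alternative)
}

#' Partial Mantel test controlling for a third matrix
#'
#' The partial correlation
#' \eqn{r_{AB \cdot C} = (r_{AB} - r_{AC} r_{BC}) /
#' \sqrt{(1 - r_{AC}^2)(1 - r_{BC}^2)}} separates the direct association of
#' `A` and `B` from the one induced by `C` (e.g. genetics vs linguistics
#' controlling for geography). The null permutes the raw `B` matrix and
#' recomputes the partial correlation each time (the most common
#' implementation lineage); `method = "residual"` instead permutes the
#' residuals of `B` on `C`.
#'
#' @param A,B,C labelled distance matrices over the same label set; `C` is
#'   the controlled matrix.
#' @inheritParams mantel_test
#' @param method `"raw"` (default) or `"residual"` permutation scheme.
#' @return a `mantel_result` with `partial_on` set.
#' @export
partial_mantel_test <- function(A, B, C, permutations = 999, seed = NULL,
                                alternative = c("greater", "less", "two.sided"),
                                method = c("raw", "residual")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  mats <- check_mantel_input(A, B)
  A <- mats$A; B <- mats$B
  C <- align_labels(as_dist_matrix(C), rownames(A))
  if (stats::sd(upper_vec(C)) == 0) stop_input("constant matrix: control matrix has zero variance")
  n <- nrow(A)
  r_ac <- mantel_r(A, C)
  r_bc <- mantel_r(B, C)
  if (abs(r_ac) >= 1 - 1e-10 || abs(r_bc) >= 1 - 1e-10) {
    stop_input("collinear control matrix (|r| = 1 with A or B)")
  }
  r_obs <- partial_r(mantel_r(A, B), r_ac, r_bc)
  if (!is.null(seed)) set.seed(seed)
  if (method == "raw") {
    r_perm <- vapply(seq_len(permutations), function(i) {
      o <- sample.int(n)
      Bp <- B[o, o]
      partial_r(mantel_r(A, Bp), r_ac, mantel_r(Bp, C))
    }, numeric(1))
  } else {
    a <- upper_vec(A); b <- upper_vec(B); cc <- upper_vec(C)
    res_b <- stats::resid(stats::lm(b ~ cc))
    Rb <- matrix(0, n, n); Rb[upper.tri(Rb)] <- res_b
    Rb <- Rb + t(Rb)
    res_a <- stats::resid(stats::lm(a ~ cc))
    Ra <- matrix(0, n, n); Ra[upper.tri(Ra)] <- res_a
    Ra <- Ra + t(Ra)
    r_perm <- vapply(seq_len(permutations), function(i) {
      o <- sample.int(n)
      cor(upper_vec(Ra), upper_vec(Rb[o, o]))
    }, numeric(1))
  }
  out <- new_mantel_result(r_obs, mantel_p(r_obs, r_perm, alternative),
                           permutations, alternative, partial_on = "C")
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  kind <- if (!is.na(x$partial_on)) "partial Mantel" else "Mantel"
  cat(sprintf("<%s> r = %.4f, p = %.4g (%s, %d permutations%s)\n",
              kind, x$r, x$p_value, x$alternative, x$permutations,
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, permutations = x$permutations,
                 alternative = x$alternative,
                 partial = !is.na(x$partial_on), exact = isTRUE(x$exact))
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)
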