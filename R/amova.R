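# Hierarchical AMOVA on haplogroup counts.
#
# Individuals are expanded as haplogroup-labelled units with the 0/1
# mismatch distance, so Phi_ST is the haplogroup-frequency analogue of F_ST.
# With delta^2 in {0,1}, the sum of squared deviations within any set of
# individuals with haplogroup counts c_h and size n is
#   SS = (1/n) * sum_{i<j} delta_ij^2 = (n - sum_h c_h^2 / n) / 2,
# which lets every permutation replicate run on count tables.

ss_within <- function(counts_vec) {
  n <- sum(counts_vec)
  if (n == 0) return(0)
  (n - sum(counts_vec^2) / n) / 2
}

# decomposition given a pop x haplogroup count matrix and a group factor
amova_decompose <- function(C, group) {
  n_p <- rowSums(C)
  N <- sum(n_p)
  P <- nrow(C)
  groups <- unique(group)
  G <- length(groups)
  ss_total <- ss_within(colSums(C))
  ss_wp <- sum(apply(C, 1, ss_within))
  ss_wg <- vapply(groups, function(g) ss_within(colSums(C[group == g, , drop = FALSE])),
                  numeric(1))
  n_g <- vapply(groups, function(g) sum(n_p[group == g]), numeric(1))
  ss_ap <- sum(ss_wg) - ss_wp          # among populations within groups
  ss_ag <- ss_total - sum(ss_wg)       # among groups
  df_a <- G - 1
  df_b <- P - G
  df_c <- N - P
  sum_np2_over_ng <- sum(vapply(groups, function(g) {
    sum(n_p[group == g]^2) / sum(n_p[group == g])
  }, numeric(1)))
  n1 <- if (df_b > 0) (N - sum_np2_over_ng) / df_b else NA_real_
  n2 <- if (df_a > 0) (sum_np2_over_ng - sum(n_p^2) / N) / df_a else NA_real_
  n3 <- if (df_a > 0) (N - sum(n_g^2) / N) / df_a else NA_real_
  ms_c <- if (df_c > 0) ss_wp / df_c else NA_real_
  ms_b <- if (df_b > 0) ss_ap / df_b else NA_real_
  ms_a <- if (df_a > 0) ss_ag / df_a else NA_real_
  sigma_c <- ms_c
  sigma_b <- if (df_b > 0) (ms_b - sigma_c) / n1 else NA_real_
  sigma_a <- if (df_a > 0) (ms_a - sigma_c - n2 * ifelse(is.na(sigma_b), 0, sigma_b)) / n3 else NA_real_
  list(
    ss = c(among_groups = ss_ag, among_pops_within = ss_ap, within_pops = ss_wp,
           total = ss_total),
    df = c(among_groups = df_a, among_pops_within = df_b, within_pops = df_c,
           total = N - 1),
    sigma = c(a = sigma_a, b = sigma_b, c = sigma_c)
  )
}

phi_from_sigma <- function(sigma) {
  tot <- sum(sigma, na.rm = TRUE)
  denom_sc <- sigma["b"] + sigma["c"]
  phi_sc <- if (is.na(sigma["b"])) {
    NA_real_
  } else if (denom_sc != 0) {
    unname(sigma["b"] / denom_sc)
  } else if (sigma["b"] == 0) 0 else NA_real_ # no variation below groups at all
  c(
    phi_st = if (tot != 0) sum(sigma[c("a", "b")], na.rm = TRUE) / tot else NA_real_,
    phi_sc = phi_sc,
    phi_ct = if (!is.na(sigma["a"]) && tot != 0) unname(sigma["a"] / tot) else NA_real_
  )
}

# individual-level expansion: haplogroup index, population index per individual
expand_individuals <- function(C) {
  hap <- rep(rep(seq_len(ncol(C)), nrow(C)), as.vector(t(C)))
  pop <- rep(seq_len(nrow(C)), rowSums(C))
  list(hap = hap, pop = pop)
}

tabulate_counts <- function(hap, pop, n_pop, n_hap) {
  m <- matrix(0L, n_pop, n_hap)
  t <- table(factor(pop, levels = seq_len(n_pop)), factor(hap, levels = seq_len(n_hap)))
  m[] <- as.integer(t)
  m
}

#' Hierarchical analysis of molecular variance on haplogroup counts
#'
#' Partitions haplogroup diversity into among-groups, among-populations-
#' within-groups, and within-population components via the pairwise 0/1
#' mismatch distance (Excoffier-Smouse-Quattro sums of squares with the
#' standard unequal-sample-size expected-mean-square coefficients), with
#' Phi-statistics and permutation p-values:
#' Phi_ST permutes individuals among all populations, Phi_SC permutes
#' individuals among populations within their group, and Phi_CT permutes
#' whole populations among groups. p-values use (b + 1) / (m + 1).
#'
#' Negative variance components are reported as estimated; a clamped-to-zero
#' copy is provided alongside. A level with a single unit is reported as not
#' testable (`NA`), not zero.
#'
#' @param x a `haplogroup_table` carrying integer counts (or a coercible
#'   data frame of counts).
#' @param groups top-level grouping: a named character vector
#'   (population -> group), the name of a metadata column of `x`, or `NULL`
#'   for a two-level AMOVA (among / within populations only).
#' @param permutations number of permutations per testable statistic
#'   (0 = no p-values).
#' @param seed integer seed for the permutation streams.
#' @return an object of class `amova_result`.
#' @export
amova <- function(x, groups = NULL, permutations = 999, seed = NULL) {
  C <- require_counts(x)
  x <- as_haplogroup_table(x)
  pops <- rownames(C)
  if (nrow(C) < 2) stop_input("AMOVA needs at least 2 populations")
  if (is.null(groups)) {
    group <- rep("all", nrow(C))
  } else if (length(groups) == 1 && is.character(groups) && !is.null(x$meta) &&
             groups %in% names(x$meta)) {
    group <- as.character(x$meta[[groups]][match(pops, x$meta$population)])
  } else {
    if (is.null(names(groups))) stop_input("groups must be named by population id")
    miss <- setdiff(pops, names(groups))
    if (length(miss)) stop_input("populations without a group: %s", paste(miss, collapse = ", "))
    group <- as.character(groups[pops])
  }
  two_level <- length(unique(group)) == 1
  dec <- amova_decompose(C, group)
  sigma <- dec$sigma
  if (two_level) {
    # relabel: among populations is the top stratum of a two-level design
    sigma <- c(a = unname(sigma["b"]), b = NA_real_, c = unname(sigma["c"]))
    phi <- c(phi_st = unname(sigma["a"] / (sigma["a"] + sigma["c"])),
             phi_sc = NA_real_, phi_ct = NA_real_)
    scl <- pmax(sigma, 0)
    phi_clamped <- c(
      phi_st = if ((scl["a"] + scl["c"]) > 0) unname(scl["a"] / (scl["a"] + scl["c"])) else 0,
      phi_sc = NA_real_, phi_ct = NA_real_
    )
  } else {
    phi <- phi_from_sigma(sigma)
    scl <- pmax(sigma, 0)
    tot_cl <- sum(scl, na.rm = TRUE)
    phi_clamped <- c(
      phi_st = if (tot_cl > 0) sum(scl[c("a", "b")], na.rm = TRUE) / tot_cl else 0,
      phi_sc = if (!is.na(scl["b"]) && (scl["b"] + scl["c"]) > 0)
        unname(scl["b"] / (scl["b"] + scl["c"])) else if (is.na(scl["b"])) NA_real_ else 0,
      phi_ct = if (is.na(scl["a"])) NA_real_ else if (tot_cl > 0) unname(scl["a"] / tot_cl) else 0
    )
  }
  p <- c(phi_st = NA_real_, phi_sc = NA_real_, phi_ct = NA_real_)
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    ind <- expand_individuals(C)
    n_pop <- nrow(C); n_hap <- ncol(C)
    # Phi_ST: individuals among all populations
    obs <- phi["phi_st"]
    if (!is.na(obs)) {
      b <- 0L
      for (i in seq_len(permutations)) {
        hp <- sample(ind$hap)
        Cp <- tabulate_counts(hp, ind$pop, n_pop, n_hap)
        rownames(Cp) <- pops
        dp <- amova_decompose(Cp, group)
        s <- dp$sigma
        stat <- if (two_level) s["b"] / (s["b"] + s["c"]) else
          sum(s[c("a", "b")], na.rm = TRUE) / sum(s, na.rm = TRUE)
        if (!is.na(stat) && stat >= obs) b <- b + 1L
      }
      p["phi_st"] <- (b + 1) / (permutations + 1)
    }
    if (!two_level) {
      # Phi_SC: individuals among populations within groups
      obs <- phi["phi_sc"]
      if (!is.na(obs)) {
        b <- 0L
        for (i in seq_len(permutations)) {
          hp <- ind$hap
          for (g in unique(group)) {
            sel <- ind$pop %in% which(group == g)
            hp[sel] <- sample(hp[sel])
          }
          Cp <- tabulate_counts(hp, ind$pop, n_pop, n_hap)
          dp <- amova_decompose(Cp, group)
          stat <- dp$sigma["b"] / (dp$sigma["b"] + dp$sigma["c"])
          if (!is.na(stat) && stat >= obs) b <- b + 1L
        }
        p["phi_sc"] <- (b + 1) / (permutations + 1)
      }
      # Phi_CT: whole populations among groups
      obs <- phi["phi_ct"]
      if (!is.na(obs)) {
        b <- 0L
        for (i in seq_len(permutations)) {
          gp <- sample(group)
          dp <- amova_decompose(C, gp)
          stat <- phi_from_sigma(dp$sigma)["phi_ct"]
          if (!is.na(stat) && stat >= obs) b <- b + 1L
        }
        p["phi_ct"] <- (b + 1) / (permutations + 1)
      }
    }
  }
  levels_tbl <- if (two_level) {
    tibble::tibble(
      level = c("among_populations", "within_populations", "total"),
      df = unname(dec$df[c("among_pops_within", "within_pops", "total")]),
      sum_sq = unname(dec$ss[c("among_pops_within", "within_pops", "total")]),
      variance = unname(c(sigma["a"], sigma["c"], sum(sigma, na.rm = TRUE)))
    )
  } else {
    tibble::tibble(
      level = c("among_groups", "among_populations_within_groups",
                "within_populations", "total"),
      df = unname(dec$df),
      sum_sq = unname(dec$ss),
      variance = unname(c(sigma["a"], sigma["b"], sigma["c"], sum(sigma, na.rm = TRUE)))
    )
  }
  levels_tbl$variance_clamped <- pmax(levels_tbl$variance, 0)
  levels_tbl$pct_total <- 100 * levels_tbl$variance / sum(sigma, na.rm = TRUE)
  structure(
    list(levels = levels_tbl, sigma = sigma, phi = phi, phi_clamped = phi_clamped,
         p_values = p,
         permutations = permutations, two_level = two_level,
         groups = if (two_level) NULL else stats::setNames(group, pops)),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(as.data.frame(x$levels), row.names = FALSE)
  phi <- x$phi; p <- x$p_values
  for (s in names(phi)) {
    if (!is.na(phi[[s]])) {
      cat(sprintf("  %s = %.4f%s\n", s, phi[[s]],
                  if (!is.na(p[[s]])) sprintf(" (p = %.4g, %d permutations)", p[[s]], x$permutations) else ""))
    }
  }
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$levels

#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(
    phi_st = unname(x$phi["phi_st"]), phi_sc = unname(x$phi["phi_sc"]),
    phi_ct = unname(x$phi["phi_ct"]),
    p_st = unname(x$p_values["phi_st"]), p_sc = unname(x$p_values["phi_sc"]),
    p_ct = unname(x$p_values["phi_ct"]),
    permutations = x$permutations
  )
}

#' Two-level AMOVA within each unit of a stratum
#'
#' Runs one among-local-populations AMOVA per unit of a chosen metadata
#' stratum (for example, Phi_ST among the local populations of each ethnic
#' group), mirroring per-language differentiation summaries. Units with
#' fewer than two populations are skipped with a message.
#'
#' @inheritParams amova
#' @param by name of the metadata column defining the units (e.g.
#'   `"ethnic_group"`), or a named character vector population -> unit.
#' @return a tibble with one row per analysed unit (`unit`, `n_populations`,
#'   `n_individuals`, `phi_st`, `p_value`) with the across-units average in
#'   attribute `"average_phi_st"`.
#' @export
amova_per_group <- function(x, by, permutations = 999, seed = NULL) {
  C <- require_counts(x)
  x <- as_haplogroup_table(x)
  pops <- rownames(C)
  if (length(by) == 1 && !is.null(x$meta) && by %in% names(x$meta)) {
    unit <- as.character(x$meta[[by]][match(pops, x$meta$population)])
  } else {
    unit <- as.character(by[pops])
  }
  rows <- list()
  for (u in unique(unit)) {
    members <- pops[unit == u]
    if (length(members) < 2) {
      message(sprintf("skipping unit '%s': fewer than 2 populations", u))
      next
    }
    sub <- haplogroup_table(
      C[members, , drop = FALSE] / rowSums(C[members, , drop = FALSE]),
      counts = C[members, , drop = FALSE]
    )
    res <- amova(sub, groups = NULL, permutations = permutations,
                 seed = derive_seed(seed, match(u, unique(unit))))
    rows[[u]] <- tibble::tibble(
      unit = u, n_populations = length(members),
      n_individuals = sum(C[members, ]),
      phi_st = unname(res$phi["phi_st"]),
      p_value = unname(res$p_values["phi_st"])
    )
  }
  if (!length(rows)) stop_input("no unit has >= 2 populations")
  out <- dplyr::bind_rows(rows)
  attr(out, "average_phi_st") <- mean(out$phi_st)
  out
}
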