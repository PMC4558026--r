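# Synthetic-data generators with known ground truth for every pipeline
# input class. Each generator is a pure function of its config and seed.

rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = pmax(alpha, 1e-12))
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Configuration for the hierarchical haplogroup simulator
#'
#' Defaults mirror a Balto-Slavic-sized survey: four linguistic branches,
#' three ethnic groups per branch, three local populations per group
#' (36 populations), twelve haplogroups and 100 sampled men per population.
#' The Dirichlet concentrations control similarity at each level (higher =
#' more similar): group frequencies are Dirichlet(`tau_group` x branch
#' frequencies), population frequencies Dirichlet(`tau_pop` x group
#' frequencies), so level-wise differentiation is roughly
#' `1 / (1 + tau)`. The defaults (`tau_branch = 1`, `tau_group = 30`,
#' `tau_pop = 100`) give branch / ethnic-group / local-population
#' differentiation of order 0.06 / 0.03 / 0.01, the magnitudes typical of
#' continental haplogroup surveys at those levels.
#'
#' @param n_branches,n_groups_per_branch,n_pops_per_group,n_haplogroups
#'   structure counts (all >= 1).
#' @param tau_branch,tau_group,tau_pop positive Dirichlet concentrations.
#' @param n_per_pop samples per population.
#' @param spatial_rho correlation length in km of an optional spatially
#'   autocorrelated log-frequency field (0 = off).
#' @param spatial_sd marginal sd of that field on the log scale.
#' @param pop_jitter_deg sd (degrees, lat then lon) of population scatter
#'   around its group center; widen it to spread populations over a larger
#'   territory.
#' @param seed integer seed.
#' @return a config list of class `haplo_sim_config`.
#' @export
haplo_sim_config <- function(n_branches = 4, n_groups_per_branch = 3,
                             n_pops_per_group = 3, n_haplogroups = 12,
                             tau_branch = 1, tau_group = 30, tau_pop = 100,
                             n_per_pop = 100, spatial_rho = 0,
                             spatial_sd = 0.5, pop_jitter_deg = c(0.4, 0.6),
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_branches, n_groups_per_branch, n_pops_per_group,
              n_haplogroups, n_per_pop)
  if (any(counts < 1)) stop_input("all counts must be >= 1")
  if (any(c(tau_branch, tau_group, tau_pop) <= 0)) stop_input("concentrations must be > 0")
  structure(cfg, class = "haplo_sim_config")
}

#' Simulate a hierarchically structured haplogroup survey
#'
#' Branch base frequencies are symmetric-Dirichlet draws; group frequencies
#' are Dirichlet around their branch (concentration `tau_group`), population
#' frequencies Dirichlet around their group (`tau_pop`); counts are
#' multinomial. Populations of a branch are placed geographically
#' contiguously (branch centers far apart, groups and populations jittered
#' around them), and an optional Gaussian-kernel-correlated perturbation of
#' log frequencies adds spatially autocorrelated drift.
#'
#' @param cfg a [haplo_sim_config()].
#' @return a `haplogroup_table` with counts and metadata (`population`,
#'   `ethnic_group`, `branch`, `language`, `lat`, `lon`, `n`); the true
#'   hierarchy is the metadata.
#' @export
simulate_haplogroups <- function(cfg = haplo_sim_config()) {
  stopifnot(inherits(cfg, "haplo_sim_config"))
  set.seed(cfg$seed)
  H <- cfg$n_haplogroups
  branch_centers <- cbind(lat = 44 + 4 * seq_len(cfg$n_branches),
                          lon = 12 + 9 * seq_len(cfg$n_branches))
  rows <- list(); freqs <- list()
  for (b in seq_len(cfg$n_branches)) {
    f_branch <- rdirichlet(rep(cfg$tau_branch, H))
    for (g in seq_len(cfg$n_groups_per_branch)) {
      f_group <- rdirichlet(cfg$tau_group * f_branch)
      g_center <- branch_centers[b, ] + rnorm(2, 0, 1.2)
      for (p in seq_len(cfg$n_pops_per_group)) {
        f_pop <- rdirichlet(cfg$tau_pop * f_group)
        id <- sprintf("B%dG%dP%d", b, g, p)
        rows[[id]] <- tibble::tibble(
          population = id,
          ethnic_group = sprintf("B%dG%d", b, g),
          branch = sprintf("B%d", b),
          language = sprintf("lang_B%dG%d", b, g),
          lat = g_center["lat"] + rnorm(1, 0, cfg$pop_jitter_deg[1]),
          lon = g_center["lon"] + rnorm(1, 0, cfg$pop_jitter_deg[2]),
          n = cfg$n_per_pop
        )
        freqs[[id]] <- f_pop
      }
    }
  }
  meta <- dplyr::bind_rows(rows)
  meta$lat <- pmin(pmax(meta$lat, -89), 89)
  FM <- do.call(rbind, freqs)
  if (cfg$spatial_rho > 0) {
    D <- haversine_matrix(meta)
    K <- exp(-(D / cfg$spatial_rho)^2) # Gaussian kernel in km
    cf <- chol(K + diag(1e-8, nrow(K)))
    for (h in seq_len(H)) {
      z <- drop(t(cf) %*% rnorm(nrow(FM))) * cfg$spatial_sd
      FM[, h] <- FM[, h] * exp(z)
    }
    FM <- FM / rowSums(FM)
  }
  counts <- t(apply(FM, 1, function(f) stats::rmultinom(1, cfg$n_per_pop, f)[, 1]))
  # guard: a multinomial draw can be all zero only if n_per_pop = 0
  dimnames(counts) <- list(meta$population, sprintf("hg%02d", seq_len(H)))
  haplogroup_table(counts / rowSums(counts), counts = counts, meta = meta)
}

#' Configuration for the IBD segment simulator
#'
#' The recombination-clock model: a pair of individuals whose groups share
#' ancestry `g` generations back carries a Poisson(`mu`) number of
#' detectable IBD segments whose cM lengths are exponential with mean
#' `100 / (2 g)`, left-truncated at the detection minimum `min_cM`
#' (truncation by the memoryless shift, equivalent to rejection sampling).
#' `mu` is the post-threshold per-pair mean, so the binning-free total of
#' the ibd-statistic is `mu` for every depth; depth moves mass between
#' short and long classes.
#'
#' @param group_sizes named integer vector: individuals per group.
#' @param depth named symmetric matrix of generations to common ancestry
#'   per group pair (diagonal = within-group depth).
#' @param mu mean detectable segments per pair (scalar or matrix shaped
#'   like `depth`).
#' @param min_cM detection threshold (default 1).
#' @param seed integer seed.
#' @return a config list of class `ibd_sim_config`.
#' @export
ibd_sim_config <- function(group_sizes, depth, mu = 2, min_cM = 1, seed = 1) {
  if (is.null(names(group_sizes))) stop_input("group_sizes must be named")
  gn <- names(group_sizes)
  if (!is.matrix(depth) || !identical(rownames(depth), gn) ||
      !identical(colnames(depth), gn)) {
    stop_input("depth must be a matrix with group names on both dimensions")
  }
  if (max(abs(depth - t(depth))) > 1e-9) stop_input("depth matrix must be symmetric")
  if (any(depth <= 0)) stop_input("depths must be positive")
  if (!is.matrix(mu)) {
    mu <- matrix(mu, nrow(depth), ncol(depth), dimnames = dimnames(depth))
  }
  if (any(mu < 0)) stop_input("mu must be >= 0")
  structure(list(group_sizes = group_sizes, depth = depth, mu = mu,
                 min_cM = min_cM, seed = seed),
            class = "ibd_sim_config")
}

#' Closed-form expected ibd-statistic per length class
#'
#' Under the recombination-clock model, the expected average segment count
#' per pair in class `[a, b)` is
#' `mu * (exp(-2 g a / 100) - exp(-2 g b / 100)) / exp(-2 g min_cM / 100)`.
#'
#' @param g generations to common ancestry.
#' @param mu mean detectable segments per pair.
#' @param bins class edges (see [ibd_length_bins()]).
#' @param min_cM detection threshold used in the simulation.
#' @return tibble with `class`, `lower`, `upper`, `expected`.
#' @export
ibd_expected_profile <- function(g, mu, bins = ibd_length_bins(), min_cM = 1) {
  edges <- ibd_length_bins(bins)
  r <- 2 * g / 100
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  surv <- function(x) ifelse(is.finite(x), exp(-r * pmax(x, min_cM)), 0)
  tibble::tibble(
    class = bin_labels(edges), lower = lo, upper = hi,
    expected = mu * (surv(lo) - surv(hi)) / exp(-r * min_cM)
  )
}

#' Simulate pairwise IBD segments with known sharing structure
#'
#' @param cfg an [ibd_sim_config()].
#' @return an `ibd_segments` object; individuals are labelled
#'   `<group>_i<k>` and registered with their group as population id.
#' @export
simulate_ibd <- function(cfg) {
  stopifnot(inherits(cfg, "ibd_sim_config"))
  set.seed(cfg$seed)
  gn <- names(cfg$group_sizes)
  ind <- dplyr::bind_rows(lapply(gn, function(g) {
    tibble::tibble(
      individual_id = sprintf("%s_i%03d", g, seq_len(cfg$group_sizes[[g]])),
      population_id = g
    )
  }))
  ids_by_group <- split(ind$individual_id, ind$population_id)[gn]
  segs <- list()
  for (a in seq_along(gn)) {
    for (b in a:length(gn)) {
      ids_a <- ids_by_group[[a]]; ids_b <- ids_by_group[[b]]
      if (a == b) {
        if (length(ids_a) < 2) next
        pairs <- t(combn(ids_a, 2))
      } else {
        pairs <- as.matrix(expand.grid(ids_a, ids_b, stringsAsFactors = FALSE))
      }
      g <- cfg$depth[a, b]
      mu <- cfg$mu[a, b]
      if (mu == 0 || nrow(pairs) == 0) next
      k <- rpois(nrow(pairs), mu)
      tot <- sum(k)
      if (tot == 0) next
      len <- cfg$min_cM + rexp(tot, rate = 2 * g / 100)
      start <- runif(tot, 0, 150)
      segs[[length(segs) + 1]] <- tibble::tibble(
        id1 = rep(pairs[, 1], k), id2 = rep(pairs[, 2], k),
        chromosome = as.character(sample.int(22, tot, replace = TRUE)),
        start_cM = start, end_cM = start + len
      )
    }
  }
  seg_tbl <- if (length(segs)) dplyr::bind_rows(segs) else {
    tibble::tibble(id1 = character(), id2 = character(), chromosome = character(),
                   start_cM = numeric(), end_cM = numeric())
  }
  ibd_segments(seg_tbl, ind)
}

#' Configuration for the wordlist simulator
#'
#' @param true_tree a `dated_tree` (years) along which items evolve.
#' @param n_items number of Swadesh-style concepts (default 110).
#' @param rates per-item replacement rate per millennium (scalar recycled;
#'   default 0.2, a typical basic-vocabulary turnover).
#' @param synonym_prob probability that a replacement adds a synonym
#'   instead of replacing the current class (default 0).
#' @param seed integer seed.
#' @return a config list of class `wordlist_sim_config`.
#' @export
wordlist_sim_config <- function(true_tree, n_items = 110, rates = 0.2,
                                synonym_prob = 0, seed = 1) {
  stopifnot(inherits(true_tree, "phylo"))
  rates <- rep_len(rates, n_items)
  if (any(rates <= 0)) stop_input("rates must be > 0")
  if (synonym_prob < 0 || synonym_prob >= 1) stop_input("synonym_prob must be in [0, 1)")
  structure(list(true_tree = dated_tree(true_tree), n_items = n_items,
                 rates = rates, synonym_prob = synonym_prob, seed = seed),
            class = "wordlist_sim_config")
}

#' Simulate cognate wordlists along a dated tree
#'
#' Poisson replacement: along a branch of `L` years, item `i` is hit by
#' `Poisson(rate_i * L / 1000)` replacement events, each drawing a globally
#' novel cognate class that replaces the current cell (or, with probability
#' `synonym_prob`, is added as a synonym). With `synonym_prob = 0`, two
#' lects separated by total path time `T` share an item's cognate class
#' with probability `exp(-rate_i * T / 1000)`.
#'
#' @param cfg a [wordlist_sim_config()].
#' @return a list with elements `wordlist` (a `wordlist`) and `true_tree`.
#' @export
simulate_wordlists <- function(cfg) {
  stopifnot(inherits(cfg, "wordlist_sim_config"))
  set.seed(cfg$seed)
  phy <- cfg$true_tree
  ntip <- ape::Ntip(phy)
  n_items <- cfg$n_items
  counter <- n_items # global novel-class counter; root classes are 1..n_items
  states <- vector("list", ntip + phy$Nnode)
  root <- ntip + 1
  states[[root]] <- lapply(seq_len(n_items), function(i) i)
  # preorder: parents before children
  for (e in rev(ape::postorder(phy))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    L <- phy$edge.length[e] / 1000
    st <- states[[p]]
    hits <- rpois(n_items, cfg$rates * L)
    for (i in which(hits > 0)) {
      for (h in seq_len(hits[i])) {
        counter <- counter + 1
        if (runif(1) < cfg$synonym_prob) {
          st[[i]] <- unique(c(st[[i]], counter))
        } else {
          st[[i]] <- counter
        }
      }
    }
    states[[ch]] <- st
  }
  cells <- matrix(vector("list", n_items * ntip), nrow = n_items,
                  dimnames = list(sprintf("item%03d", seq_len(n_items)),
                                  phy$tip.label))
  for (tip in seq_len(ntip)) {
    cells[, tip] <- lapply(states[[tip]], function(v) as.integer(v))
  }
  list(wordlist = wordlist(cells), true_tree = phy)
}
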