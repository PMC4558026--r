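# random small count tables for oracle comparisons
random_counts <- function(n_pop, n_hap, n_max, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_pop * n_hap, 1.2), n_pop, n_hap)
    if (all(rowSums(m) >= 2)) break
  }
  dimnames(m) <- list(paste0("p", seq_len(n_pop)), paste0("h", seq_len(n_hap)))
  m
}

counts_to_individuals <- function(C, group = NULL) {
  hap <- rep(rep(colnames(C), nrow(C)), as.vector(t(C)))
  pop <- rep(rownames(C), rowSums(C))
  g <- if (!is.null(group)) group[pop] else NULL
  list(hap = hap, pop = pop, group = g)
}

test_that("two-level AMOVA equals the brute-force pairwise-mismatch decomposition", {
  for (seed in 1:6) {
    C <- random_counts(n_pop = 3, n_hap = 3, n_max = 30, seed = seed)
    tbl <- haplogroup_table(C / rowSums(C), counts = C)
    res <- amova(tbl, permutations = 0)
    ind <- counts_to_individuals(C)
    ref <- brute_amova(ind$hap, ind$pop)
    expect_equal(res$levels$sum_sq[1], unname(ref$ss["among"]), tolerance = 1e-12)
    expect_equal(res$levels$sum_sq[2], unname(ref$ss["within"]), tolerance = 1e-12)
    expect_equal(unname(res$sigma["a"]), unname(ref$sigma["a"]), tolerance = 1e-9)
    expect_equal(unname(res$sigma["c"]), unname(ref$sigma["c"]), tolerance = 1e-9)
    expect_equal(unname(res$phi["phi_st"]), unname(ref$phi_st), tolerance = 1e-9)
  }
})

test_that("three-level AMOVA equals the brute-force decomposition on small instances", {
  for (seed in 1:6) {
    C <- random_counts(n_pop = 4, n_hap = 3, n_max = 30, seed = 50 + seed)
    group <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
    tbl <- haplogroup_table(C / rowSums(C), counts = C)
    res <- amova(tbl, groups = group, permutations = 0)
    ind <- counts_to_individuals(C, group)
    ref <- brute_amova(ind$hap, ind$pop, ind$group)
    expect_equal(res$levels$sum_sq[1:3],
                 unname(ref$ss[c("among_groups", "among_pops", "within")]),
                 tolerance = 1e-12)
    expect_equal(unname(res$sigma), unname(ref$sigma), tolerance = 1e-9)
    expect_equal(unname(res$phi), unname(ref$phi), tolerance = 1e-9)
    # components always sum to the total variance
    expect_equal(sum(res$sigma), res$levels$variance[res$levels$level == "total"])
  }
})

test_that("fixed opposite haplogroups give Phi_ST = 1 and Phi_SC = 0", {
  C <- matrix(c(10L, 0L, 10L, 0L, 0L, 10L, 0L, 10L), 4, 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), c("A", "B")))
  tbl <- haplogroup_table(C / rowSums(C), counts = C)
  res <- amova(tbl, groups = c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
               permutations = 0)
  expect_equal(unname(res$phi["phi_st"]), 1)
  expect_equal(unname(res$phi["phi_sc"]), 0)
  expect_equal(unname(res$phi["phi_ct"]), 1)
})

test_that("identical populations show no differentiation (clamped estimates zero)", {
  C <- matrix(rep(c(6L, 4L), each = 4), 4, 2,
              dimnames = list(paste0("p", 1:4), c("A", "B")))
  tbl <- haplogroup_table(C / rowSums(C), counts = C)
  res <- amova(tbl, groups = c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
               permutations = 0)
  expect_equal(res$levels$sum_sq[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(unname(res$phi_clamped["phi_st"]), 0)
  expect_equal(unname(res$phi_clamped["phi_sc"]), 0)
  expect_equal(unname(res$phi_clamped["phi_ct"]), 0)
  # raw method-of-moments estimates may be (slightly) negative, never positive
  expect_lte(res$phi["phi_st"], 0)
})

test_that("a level with a single unit is reported as not testable", {
  C <- random_counts(3, 3, 30, seed = 99)
  tbl <- haplogroup_table(C / rowSums(C), counts = C)
  res <- amova(tbl, groups = c(p1 = "g1", p2 = "g1", p3 = "g1"), permutations = 9)
  expect_true(is.na(res$phi["phi_ct"]))
  expect_true(is.na(res$p_values["phi_ct"]))
})

test_that("per-group two-level AMOVA matches a hand-computed decomposition", {
  # two local pops, counts (10,0) and (5,5): brute oracle over 20 individuals
  C <- matrix(c(10L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  ind <- counts_to_individuals(C)
  ref <- brute_amova(ind$hap, ind$pop)
  tbl <- haplogroup_table(C / rowSums(C), counts = C,
                          meta = tibble::tibble(population = c("p1", "p2"),
                                                ethnic_group = "eg1"))
  out <- amova_per_group(tbl, "ethnic_group", permutations = 0)
  expect_equal(out$phi_st, unname(ref$phi_st), tolerance = 1e-9)
  expect_equal(attr(out, "average_phi_st"), out$phi_st)
  # identical local populations give Phi_ST <= 0 (no among-population signal)
  C2 <- rbind(C, p3 = c(7L, 3L), p4 = c(7L, 3L))
  meta2 <- tibble::tibble(population = paste0("p", 1:4),
                          ethnic_group = c("eg1", "eg1", "eg2", "eg2"))
  tbl2 <- haplogroup_table(C2 / rowSums(C2), counts = C2, meta = meta2)
  out2 <- amova_per_group(tbl2, "ethnic_group", permutations = 0)
  expect_lte(out2$phi_st[out2$unit == "eg2"], 0)
  # singleton units are skipped with a message
  meta3 <- tibble::tibble(population = paste0("p", 1:4),
                          ethnic_group = c("eg1", "eg1", "eg2", "eg3"))
  tbl3 <- haplogroup_table(C2 / rowSums(C2), counts = C2, meta = meta3)
  expect_message(out3 <- amova_per_group(tbl3, "ethnic_group", permutations = 0),
                 "fewer than 2")
  expect_identical(out3$unit, "eg1")
})

test_that("permutation p-values are uniform under no structure", {
  # 200 unstructured datasets; Phi_ST p-values should be ~U(0,1)
  set.seed(1234)
  pvals <- numeric(200)
  for (r in seq_len(200)) {
    C <- t(stats::rmultinom(4, 12, prob = c(0.5, 0.3, 0.2)))
    rownames(C) <- paste0("p", 1:4); colnames(C) <- paste0("h", 1:3)
    if (any(rowSums(C) == 0)) { pvals[r] <- NA; next }
    tbl <- haplogroup_table(C / rowSums(C), counts = C)
    pvals[r] <- amova(tbl, permutations = 99, seed = r)$p_values["phi_st"]
  }
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  # and the rejection rate at 5% is not inflated
  expect_lt(mean(pvals <= 0.05), 0.12)
})
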