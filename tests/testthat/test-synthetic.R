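test_that("generators are pure functions of config and seed", {
  cfg <- haplo_sim_config(seed = 9)
  a <- simulate_haplogroups(cfg)
  b <- simulate_haplogroups(cfg)
  expect_equal(a$counts, b$counts)
  expect_equal(a$meta, b$meta)
  c <- simulate_haplogroups(haplo_sim_config(seed = 10))
  expect_false(identical(a$counts, c$counts))

  gn <- c(X = 6, Y = 6)
  dep <- matrix(30, 2, 2, dimnames = list(names(gn), names(gn)))
  s1 <- simulate_ibd(ibd_sim_config(gn, dep, mu = 1, seed = 4))
  s2 <- simulate_ibd(ibd_sim_config(gn, dep, mu = 1, seed = 4))
  expect_equal(s1$segments, s2$segments)

  tt <- reference_tree()
  w1 <- simulate_wordlists(wordlist_sim_config(tt, n_items = 40, seed = 2))
  w2 <- simulate_wordlists(wordlist_sim_config(tt, n_items = 40, seed = 2))
  expect_equal(w1$wordlist$cells, w2$wordlist$cells)
})

test_that("generator output passes the reader/validator round trip", {
  dir <- withr::local_tempdir()
  sim <- simulate_haplogroups(haplo_sim_config(
    n_branches = 2, n_groups_per_branch = 2, n_pops_per_group = 2, seed = 5))
  fp <- file.path(dir, "freq.tsv"); mp <- file.path(dir, "meta.tsv")
  write_haplogroup_table(sim, fp)
  readr::write_tsv(sim$meta, mp)
  back <- read_haplogroup_table(fp, mp)
  expect_equal(back$counts, sim$counts)

  gn <- c(X = 4, Y = 4)
  dep <- matrix(40, 2, 2, dimnames = list(names(gn), names(gn)))
  segs <- simulate_ibd(ibd_sim_config(gn, dep, mu = 2, seed = 6))
  sp <- file.path(dir, "segs.tsv"); ip <- file.path(dir, "ind.tsv")
  write_ibd_segments(segs, sp, ip)
  again <- ibd_segments(readr::read_tsv(sp, show_col_types = FALSE)[, 1:5],
                        readr::read_tsv(ip, show_col_types = FALSE))
  expect_equal(again$segments$length_cM, segs$segments$length_cM)

  w <- simulate_wordlists(wordlist_sim_config(reference_tree(), n_items = 30,
                                              synonym_prob = 0.2, seed = 7))$wordlist
  wp <- file.path(dir, "wl.tsv")
  write_wordlist(w, wp)
  wback <- read_wordlist(wp)
  expect_equal(lex_distance_matrix(wback), lex_distance_matrix(w))
})

test_that("degenerate limits behave as the hierarchy dictates", {
  # enormous tau_pop: populations within a group become nearly identical
  sim <- simulate_haplogroups(haplo_sim_config(
    n_branches = 1, n_groups_per_branch = 2, n_pops_per_group = 3,
    tau_pop = 1e6, n_per_pop = 5000, seed = 3))
  pg <- amova_per_group(sim, "ethnic_group", permutations = 0)
  expect_lt(max(abs(pg$phi_st)), 0.005)
  # mu = 0 gives an empty segment set, and ibd_statistic a zero profile
  gn <- c(X = 3, Y = 3)
  dep <- matrix(30, 2, 2, dimnames = list(names(gn), names(gn)))
  empty <- simulate_ibd(ibd_sim_config(gn, dep, mu = 0, seed = 1))
  expect_equal(nrow(empty$segments), 0)
  expect_equal(ibd_statistic(empty, "X", "Y")$total, 0)
  # vanishing replacement rates leave all lects identical
  w0 <- simulate_wordlists(wordlist_sim_config(reference_tree(), n_items = 50,
                                               rates = 1e-9, seed = 2))$wordlist
  d0 <- lex_distance_matrix(w0)
  expect_equal(max(d0), 0)
})

test_that("simulated IBD matches the closed-form expectation within 3 MC SE", {
  gn <- c(A = 45, B = 45) # 2025 cross pairs
  dep <- matrix(c(80, 30, 30, 80), 2, 2, dimnames = list(names(gn), names(gn)))
  segs <- simulate_ibd(ibd_sim_config(gn, dep, mu = 2, seed = 13))
  prof <- ibd_statistic(segs, "A", "B")
  expct <- ibd_expected_profile(30, 2)
  n_pairs <- prof$n_pairs
  for (k in seq_len(nrow(expct))) {
    se <- sqrt(expct$expected[k] / n_pairs) # Poisson class counts
    expect_lt(abs(prof$per_class$avg_segments[k] - expct$expected[k]),
              3 * se + 1e-9)
  }
  # conservation: expected class masses sum to mu
  expect_equal(sum(expct$expected), 2, tolerance = 1e-12)
})

test_that("deeper ancestry gives shorter segments, same per-pair total", {
  means <- vapply(c(10, 30, 60), function(g) {
    gn <- c(A = 20, B = 20)
    dep <- matrix(c(90, g, g, 90), 2, 2, dimnames = list(names(gn), names(gn)))
    segs <- simulate_ibd(ibd_sim_config(gn, dep, mu = 2, seed = 40 + g))
    cross <- segs$segments[xor(grepl("^A_", segs$segments$id1),
                               grepl("^A_", segs$segments$id2)), ]
    mean(cross$length_cM)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("pairwise cognate share follows exp(-rate * path time)", {
  # two-leaf tree, depth 1500 years each side, rate 0.2/millennium
  tt <- dated_tree(ape::read.tree(text = "(A:1500,B:1500);"))
  sim <- simulate_wordlists(wordlist_sim_config(tt, n_items = 110,
                                                rates = 0.2, seed = 21))
  share <- attr(lex_distance_matrix(sim$wordlist), "share")["A", "B"]
  p <- exp(-0.2 * 3) # total path 3 millennia
  se <- sqrt(p * (1 - p) / 110)
  expect_lt(abs(share - p), 3 * se)
})

test_that("AMOVA recovers the component ordering of graded concentrations", {
  # graded similarity: branches highly distinct (tau 0.02), groups strongly
  # differentiated within branches (tau 0.2 < 1 so the among-group component
  # exceeds the within-population one), populations nearly identical within
  # groups (tau 1000)
  ok <- 0
  for (s in 1:50) {
    sim <- simulate_haplogroups(haplo_sim_config(
      n_branches = 5, n_groups_per_branch = 5, n_pops_per_group = 2,
      n_haplogroups = 24, tau_branch = 0.02, tau_group = 0.2, tau_pop = 1000,
      n_per_pop = 100, seed = s))
    s3 <- amova(sim, groups = "branch", permutations = 0)$sigma
    ok <- ok + (s3["a"] > s3["b"] && s3["b"] > s3["c"])
  }
  expect_gte(ok, 45) # >= 90% of 50 seeds
})

test_that("spatially autocorrelated drift produces a geography-genetics Mantel signal", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_haplogroups(haplo_sim_config(
      n_branches = 1, n_groups_per_branch = 1, n_pops_per_group = 20,
      n_haplogroups = 12, tau_branch = 5, tau_group = 1000, tau_pop = 1000,
      n_per_pop = 200, spatial_rho = 1000, spatial_sd = 0.8,
      pop_jitter_deg = c(6, 10), seed = 300 + s))
    D <- nei_distance_matrix(sim)
    G <- haversine_matrix(sim$meta)
    mt <- mantel_test(D, G, permutations = 99, seed = s)
    hits <- hits + (mt$r > 0 && mt$p_value < 0.05)
  }
  expect_gte(hits, 18) # >= 90% of 20 runs
})
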