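test_that("the hand-counted two-pair example lands in the right classes", {
  segs <- toy_ibd()
  # groups A = {i1, i2}, B = {j1}: 2 pairs; segments 2.2 and 4.5 cM on i1-j1
  pr <- ibd_statistic(segs, "A", "B")
  expect_equal(pr$n_pairs, 2)
  got <- setNames(pr$per_class$avg_segments, pr$per_class$class)
  expect_equal(unname(got["[2,2.5)"]), 0.5)
  expect_equal(unname(got["[4,5)"]), 0.5)
  expect_equal(sum(got), 1)
  expect_equal(pr$total, 1)
})

test_that("the statistic matches a literal per-pair loop on simulated data", {
  cfg <- ibd_sim_config(c(A = 6, B = 5), matrix(c(25, 40, 40, 25), 2, 2,
                        dimnames = list(c("A", "B"), c("A", "B"))),
                        mu = 3, seed = 31)
  segs <- simulate_ibd(cfg)
  edges <- ibd_length_bins()
  pr <- ibd_statistic(segs, "A", "B")
  ids_a <- segs$individuals$individual_id[segs$individuals$population_id == "A"]
  ids_b <- segs$individuals$individual_id[segs$individuals$population_id == "B"]
  ref <- brute_ibd_statistic(segs$segments, ids_a, ids_b, edges)
  expect_equal(pr$per_class$avg_segments, ref, tolerance = 1e-12)
})

test_that("binning conserves the total and duplication scales it exactly", {
  cfg <- ibd_sim_config(c(A = 5, B = 5), matrix(30, 2, 2,
                        dimnames = list(c("A", "B"), c("A", "B"))),
                        mu = 2, seed = 7)
  segs <- simulate_ibd(cfg)
  pr <- ibd_statistic(segs, "A", "B")
  # conservation: class sums equal the binning-free per-pair average
  cross <- segs$segments[
    xor(grepl("^A_", segs$segments$id1), grepl("^A_", segs$segments$id2)), ]
  expect_equal(sum(pr$per_class$avg_segments),
               sum(cross$length_cM >= 1) / pr$n_pairs, tolerance = 1e-12)
  expect_equal(pr$total, sum(pr$per_class$avg_segments))
  # coarser bins, same mass
  pr2 <- ibd_statistic(segs, "A", "B", bins = c(1, 3, Inf))
  expect_equal(sum(pr2$per_class$avg_segments), pr$total, tolerance = 1e-12)
  # doubling every pair's segment list doubles every class exactly
  segs2 <- ibd_segments(dplyr::bind_rows(segs$segments[, 1:5], segs$segments[, 1:5]),
                        segs$individuals)
  prd <- ibd_statistic(segs2, "A", "B")
  expect_equal(prd$per_class$avg_segments, 2 * pr$per_class$avg_segments)
})

test_that("per-pair averaging is invariant to duplicating individuals with identical segments", {
  segs <- toy_ibd()
  pr <- ibd_statistic(segs, "A", "B")
  # clone i1 (and its segments) into group A
  ind2 <- dplyr::bind_rows(segs$individuals,
                           tibble::tibble(individual_id = "i1b", population_id = "A"))
  extra <- segs$segments[segs$segments$id1 == "i1", 1:5]
  extra$id1 <- "i1b"
  segs2 <- ibd_segments(dplyr::bind_rows(segs$segments[, 1:5], extra), ind2)
  # i2 shares nothing, i1 and i1b share identically: per-pair profile shifts
  # from 2 pairs to 3 pairs with 2 sharing individuals
  pr2 <- ibd_statistic(segs2, "A", "B")
  expect_equal(pr2$per_class$avg_segments * 3 / 2,
               pr$per_class$avg_segments * 2 / 1, tolerance = 1e-12)
})

test_that("group hygiene is enforced and empty sharing yields a zero profile", {
  segs <- toy_ibd()
  expect_error(ibd_statistic(segs, c("A", "B"), "B"), "overlap")
  pr <- ibd_statistic(segs, "A", "C") # no segments between A and C
  expect_equal(sum(pr$per_class$avg_segments), 0)
  expect_equal(pr$total, 0)
})

test_that("sharing_profile_table sweeps comparators like single calls", {
  cfg <- ibd_sim_config(c(F = 4, X = 4, Y = 4),
                        matrix(c(20, 30, 50, 30, 20, 40, 50, 40, 20), 3, 3,
                               dimnames = list(c("F", "X", "Y"), c("F", "X", "Y"))),
                        mu = 2, seed = 3)
  segs <- simulate_ibd(cfg)
  tab <- sharing_profile_table(segs, list(x = "X", y = "Y"), focal = "F")
  one <- ibd_statistic(segs, "F", "X", name_a = "focal", name_b = "x")
  expect_equal(tab$avg_segments[tab$group_b == "x"], one$per_class$avg_segments)
  # group order permutes rows only
  tab2 <- sharing_profile_table(segs, list(y = "Y", x = "X"), focal = "F")
  expect_equal(dplyr::arrange(tab, .data$group_b, .data$lower),
               dplyr::arrange(tab2, .data$group_b, .data$lower))
})

test_that("compare_sharing detects dominance and respects the null", {
  # c2's per-pair segments are a strict subset of c1's: delta > 0 in every
  # non-empty class
  ind <- tibble::tibble(individual_id = c("f1", "a1", "b1"),
                        population_id = c("F", "C1", "C2"))
  seg <- tibble::tibble(
    id1 = c("f1", "f1", "f1"), id2 = c("a1", "a1", "b1"),
    chromosome = "1", start_cM = c(0, 0, 0), end_cM = c(2.2, 4.5, 2.2)
  )
  segs <- ibd_segments(seg, ind)
  cmp <- compare_sharing(segs, "F", "C1", "C2", permutations = 0)
  nonzero <- cmp$per_class_delta$delta[c(3, 6)] # classes of 2.2 and 4.5 cM
  expect_true(all(nonzero >= 0))
  expect_gt(cmp$delta, 0)
  expect_true(is.na(cmp$p_value))
  expect_error(compare_sharing(segs, "F", "F", "C2", permutations = 0), "overlap")
})

test_that("statistically identical comparators give well-calibrated p-values", {
  pvals <- vapply(1:40, function(s) {
    cfg <- ibd_sim_config(c(F = 8, X = 8, Y = 8),
                          matrix(30, 3, 3,
                                 dimnames = list(c("F", "X", "Y"), c("F", "X", "Y"))),
                          mu = 1.5, seed = 500 + s)
    segs <- simulate_ibd(cfg)
    compare_sharing(segs, "F", "X", "Y", permutations = 59, seed = s)$p_value
  }, numeric(1))
  # under the null the p-values are roughly uniform: no mass pile-up at 0
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals <= 0.05), 0.25)
})
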