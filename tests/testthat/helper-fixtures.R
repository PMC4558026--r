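# Small programmatic fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(8L, 2L, 2L, 8L), 2, 2, byrow = TRUE,
              dimnames = list(c("popA", "popB"), c("hg1", "hg2")))
  m
}

toy_meta <- function(pops = c("popA", "popB"),
                     lat = c(55.75, 53.90), lon = c(37.62, 27.57)) {
  tibble::tibble(population = pops, ethnic_group = "eg", branch = "b",
                 language = "lang", lat = lat, lon = lon, n = 10L)
}

write_toy_freq_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  freq_path <- file.path(dir, "freq.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  readr::write_tsv(tibble::tibble(population = c("popA", "popB"),
                                  hg1 = c(8L, 2L), hg2 = c(2L, 8L)), freq_path)
  readr::write_tsv(toy_meta(), meta_path)
  list(freq = freq_path, meta = meta_path)
}

# a 3-group IBD fixture with hand-placed segments
toy_ibd <- function() {
  ind <- tibble::tibble(
    individual_id = c("i1", "i2", "j1", "k1"),
    population_id = c("A", "A", "B", "C")
  )
  seg <- tibble::tibble(
    id1 = c("i1", "i1"), id2 = c("j1", "j1"),
    chromosome = c("1", "2"),
    start_cM = c(10, 20), end_cM = c(12.2, 24.5)
  )
  ibd_segments(seg, ind)
}

write_toy_ibd_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  seg_path <- file.path(dir, "segments.txt")
  map_path <- file.path(dir, "map.txt")
  ind_path <- file.path(dir, "individuals.tsv")
  writeLines(c(
    "# id1 id2 chrom start end score",
    "i1 j1 1 m1 m2 10",
    "i1 j1 1 m1 m3 10"
  ), seg_path)
  writeLines(c(
    "1 m1 10.0",
    "1 m2 12.2",
    "1 m3 10.4"
  ), map_path)
  readr::write_tsv(tibble::tibble(individual_id = c("i1", "j1"),
                                  population_id = c("A", "B")), ind_path)
  list(segments = seg_path, map = map_path, individuals = ind_path)
}

# 5 planar points whose Euclidean distances embed perfectly in 2-D
planar_points <- function(n = 5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n, 2)
  rownames(x) <- paste0("p", seq_len(n))
  x
}

planar_dist <- function(n = 5, seed = 42) {
  as.matrix(dist(planar_points(n, seed)))
}

# small random positive distance matrix with labels
random_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 3), n, 3)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("l", seq_len(n)), paste0("l", seq_len(n)))
  d
}

# an 8-lect dated reference tree (years) with well-separated splits
reference_tree <- function() {
  txt <- paste0(
    "(((W1:600,W2:600):900,(E1:500,E2:500):1000):1900,",
    "((S1:700,S2:700):1200,(N1:800,N2:800):1100):1500);"
  )
  dated_tree(ape::read.tree(text = txt))
}
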