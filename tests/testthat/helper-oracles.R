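# Independent oracles used to cross-check the package implementations.
# These deliberately use the slow, literal definitions.

# AMOVA from first principles: explicit pairwise 0/1 mismatch sums over
# individuals. hap/pop/group are per-individual vectors.
brute_amova <- function(hap, pop, group = NULL) {
  n <- length(hap)
  delta2 <- outer(hap, hap, FUN = function(a, b) as.numeric(a != b))
  ss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) s <- s + delta2[idx[i], idx[j]]
    }
    s / length(idx)
  }
  pops <- unique(pop)
  ss_total <- ss_of(seq_len(n))
  ss_wp <- sum(vapply(pops, function(p) ss_of(which(pop == p)), numeric(1)))
  if (is.null(group)) {
    P <- length(pops)
    df_a <- P - 1; df_c <- n - P
    ss_ap <- ss_total - ss_wp
    n_p <- as.numeric(table(pop)[pops])
    ncoef <- (n - sum(n_p^2) / n) / df_a
    sigma_c <- ss_wp / df_c
    sigma_a <- (ss_ap / df_a - sigma_c) / ncoef
    return(list(ss = c(among = ss_ap, within = ss_wp, total = ss_total),
                sigma = c(a = sigma_a, c = sigma_c),
                phi_st = sigma_a / (sigma_a + sigma_c)))
  }
  groups <- unique(group)
  G <- length(groups); P <- length(pops)
  ss_wg <- sum(vapply(groups, function(g) ss_of(which(group == g)), numeric(1)))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  pg <- vapply(pops, function(p) group[which(pop == p)[1]], character(1))
  n_g <- vapply(groups, function(g) sum(group == g), numeric(1))
  s2 <- sum(vapply(groups, function(g) sum(n_p[pg == g]^2) / n_g[g == groups], numeric(1)))
  n1 <- (n - s2) / (P - G)
  n2 <- (s2 - sum(n_p^2) / n) / (G - 1)
  n3 <- (n - sum(n_g^2) / n) / (G - 1)
  sigma_c <- ss_wp / (n - P)
  sigma_b <- (ss_ap / (P - G) - sigma_c) / n1
  sigma_a <- (ss_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within = ss_wp, total = ss_total),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
       phi = c(phi_st = (sigma_a + sigma_b) / tot,
               phi_sc = sigma_b / (sigma_b + sigma_c),
               phi_ct = sigma_a / tot))
}

# all permutations of 1..n (recursive, independent of the package's version)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1)) {
    for (k in seq_len(n)) out[[length(out) + 1]] <- append(p, n, after = k - 1)
  }
  out
}

# exhaustive Mantel p-value by full enumeration
enum_mantel_p <- function(A, B, alternative = "greater") {
  v <- function(m) m[upper.tri(m)]
  r_obs <- cor(v(A), v(B))
  rs <- vapply(perms_of(nrow(A)), function(o) cor(v(A), v(B[o, o])), numeric(1))
  switch(alternative,
         greater = mean(rs >= r_obs - 1e-12),
         two.sided = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# pool-adjacent-violators by hand (explicit block merging)
pava <- function(y) {
  blocks <- lapply(y, function(v) list(sum = v, n = 1))
  i <- 1
  while (i < length(blocks)) {
    if (blocks[[i]]$sum / blocks[[i]]$n > blocks[[i + 1]]$sum / blocks[[i + 1]]$n + 1e-15) {
      blocks[[i]] <- list(sum = blocks[[i]]$sum + blocks[[i + 1]]$sum,
                          n = blocks[[i]]$n + blocks[[i + 1]]$n)
      blocks[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$n, b$n)))
}

# stress-1 from the definition, using the hand PAVA
oracle_stress1 <- function(D, conf) {
  v <- function(m) m[upper.tri(m)]
  dv <- v(D)
  del <- v(as.matrix(dist(conf[rownames(D), , drop = FALSE])))
  o <- order(dv, del)
  dhat <- pava(del[o])
  sqrt(sum((del[o] - dhat)^2) / sum(del^2))
}

# literal ibd-statistic: loop over every cross pair and every segment
brute_ibd_statistic <- function(segs, ids_a, ids_b, edges) {
  k <- length(edges) - 1
  counts <- numeric(k)
  for (ia in ids_a) {
    for (ib in ids_b) {
      sel <- (segs$id1 == ia & segs$id2 == ib) | (segs$id1 == ib & segs$id2 == ia)
      for (len in segs$end_cM[sel] - segs$start_cM[sel]) {
        for (cl in seq_len(k)) {
          if (len >= edges[cl] && len < edges[cl + 1]) counts[cl] <- counts[cl] + 1
        }
      }
    }
  }
  counts / (length(ids_a) * length(ids_b))
}
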