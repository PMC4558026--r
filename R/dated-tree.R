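# Dated language trees: rooted ultrametric ape::phylo objects whose branch
# lengths are years, so a node's date in years before present equals its
# height above the (date-0) leaves.

#' Construct a dated tree
#'
#' @param phy a rooted `ape::phylo` with branch lengths in years; every
#'   leaf must lie at the same total depth from the root (dates are node
#'   heights above the leaves, which sit at 0 YBP).
#' @param tol tolerance (years) for the ultrametricity check.
#' @return an object of class `dated_tree` (also a `phylo`).
#' @export
dated_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop_input("phy must be an ape phylo object")
  if (is.null(phy$edge.length)) stop_input("tree has no branch lengths")
  # note: a basal multifurcation (e.g. a ternary consensus root) is fine; we
  # treat the phylo root node as the root, so ape::is.rooted is not required
  if (any(phy$edge.length < -tol)) stop_input("negative branch length (child dated older than parent)")
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(ape::Ntip(phy))]
  if (diff(range(tip_depth)) > max(tol, 1e-8 * max(tip_depth, 1))) {
    stop_input("tree is not ultrametric: leaves do not all sit at 0 YBP")
  }
  class(phy) <- c("dated_tree", "phylo")
  phy
}

#' Node dates of a dated tree
#'
#' @param t a `dated_tree`.
#' @return numeric vector of dates in years before present, indexed by
#'   ape node number (tips first, then internal nodes); tip dates are 0.
#' @export
node_dates <- function(t) {
  stopifnot(inherits(t, "phylo"))
  depth <- ape::node.depth.edgelength(t)
  root_date <- max(depth[seq_len(ape::Ntip(t))])
  dates <- root_date - depth
  dates[abs(dates) < 1e-9] <- 0
  dates
}

#' @export
print.dated_tree <- function(x, ...) {
  nd <- node_dates(x)
  cat(sprintf("<dated_tree> %d lects, root at %.0f YBP\n",
              ape::Ntip(x), max(nd)))
  invisible(x)
}

# rebuild an ultrametric phylo from explicit node dates (years)
set_node_dates <- function(phy, dates) {
  phy$edge.length <- dates[phy$edge[, 1]] - dates[phy$edge[, 2]]
  dated_tree(phy)
}

#' Dated neighbor-joining tree from a wordlist (StarlingNJ-style)
#'
#' Builds the topology by neighbor joining on the lexicostatistical
#' distance matrix, roots it (midpoint by default, or at an outgroup),
#' then dates every internal node by [glotto_date()] applied to the mean
#' cognate share between the leaf sets of its child clusters. Dates are
#' monotonised root-ward by a running maximum so a parent is never younger
#' than a child.
#'
#' @param w a `wordlist`.
#' @param lambda,law passed to [glotto_date()].
#' @param exclude lects dropped before tree building (e.g. heavily admixed
#'   ones such as Slovenian in Balto-Slavic work); default none.
#' @param outgroup optional lect to root on instead of midpoint rooting.
#' @return a `dated_tree`.
#' @export
starling_nj <- function(w, lambda = 0.05, law = "starostin",
                        exclude = character(), outgroup = NULL) {
  stopifnot(inherits(w, "wordlist"))
  keep <- setdiff(w$lects, exclude)
  if (length(keep) < 3) stop_input("need at least 3 lects after exclusions")
  w <- wordlist(w$cells[, keep, drop = FALSE], w$weights)
  d <- lex_distance_matrix(w)
  share <- attr(d, "share")
  phy <- ape::nj(stats::as.dist(d))
  phy <- if (!is.null(outgroup)) {
    ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(phy)
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  # leaf sets per node
  tipsets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  for (e in ape::postorder(phy)) { # children are visited before parents
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  dates <- numeric(ntip + nnode)
  for (node in (ntip + 1):(ntip + nnode)) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    # mean share over pairs of leaves spanning different child clades
    tot <- 0; npair <- 0
    kid_tips <- lapply(kids, function(k) tipsets[[k]])
    for (i in seq_along(kids)[-length(kids)]) {
      for (j in (i + 1):length(kids)) {
        sub <- share[phy$tip.label[kid_tips[[i]]], phy$tip.label[kid_tips[[j]]], drop = FALSE]
        tot <- tot + sum(sub); npair <- npair + length(sub)
      }
    }
    dates[node] <- glotto_date(max(tot / npair, 1e-12), lambda = lambda, law = law)
  }
  # running maximum root-ward: a parent is at least as old as its children
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    dates[p] <- max(dates[p], dates[ch])
  }
  set_node_dates(phy, dates)
}

#' Collapse near-simultaneous internal splits into multifurcations
#'
#' Contracts every internal edge whose parent-child date gap is at most
#' `threshold_years`, producing multifurcations (the consensus-tree rule:
#' ternary nodes arise from neighboring binary nodes at most 300 years
#' apart). The contracted node takes the parent's date. Idempotent.
#'
#' @param t a `dated_tree`.
#' @param threshold_years maximum gap contracted (default 300).
#' @return a `dated_tree`, possibly multifurcating.
#' @export
collapse_consensus <- function(t, threshold_years = 300) {
  stopifnot(inherits(t, "phylo"))
  dates <- node_dates(t)
  ntip <- ape::Ntip(t)
  internal <- t$edge[, 2] > ntip
  gap <- dates[t$edge[, 1]] - dates[t$edge[, 2]]
  to_collapse <- internal & gap <= threshold_years + 1e-9
  if (!any(to_collapse)) return(dated_tree(t))
  # map each collapsed child onto its (transitively resolved) parent
  target <- seq_len(ntip + t$Nnode)
  for (e in which(to_collapse)) target[t$edge[e, 2]] <- t$edge[e, 1]
  resolve <- function(v) { while (target[v] != v) v <- target[v]; v }
  merged_parent <- vapply(t$edge[, 1], resolve, numeric(1))
  keep <- !to_collapse
  new_edges <- cbind(merged_parent[keep], t$edge[keep, 2])
  # rebuild newick bottom-up from the merged children lists
  kids <- split(new_edges[, 2], new_edges[, 1])
  root <- resolve(ntip + 1)
  build <- function(node) {
    if (node <= ntip) {
      list(str = t$tip.label[node], date = 0)
    } else {
      parts <- lapply(kids[[as.character(node)]], build)
      strs <- vapply(parts, function(p) {
        sprintf("%s:%.8f", p$str, dates[node] - p$date)
      }, character(1))
      list(str = sprintf("(%s)", paste(strs, collapse = ",")), date = dates[node])
    }
  }
  out <- ape::read.tree(text = paste0(build(root)$str, ";"))
  dated_tree(out)
}

#' Write a dated tree as Newick
#'
#' Branch lengths are years (parent date minus child date);
#' multifurcations are preserved.
#'
#' @param t a `dated_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  ape::write.tree(t, file = path)
  invisible(path)
}

#' Read a dated tree from Newick
#'
#' The file must encode an ultrametric tree with branch lengths in years.
#'
#' @param path Newick file.
#' @return a `dated_tree`.
#' @export
read_dated_tree <- function(path) {
  dated_tree(ape::read.tree(path), tol = 1e-3)
}
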