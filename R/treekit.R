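#' Uncorrected p-distance matrix from an alignment
#'
#' Proportion of differing sites per sequence pair. Two gap handling modes:
#' `"gaps_as_difference"` (a gap aligned to a residue counts as a
#' difference; columns where both rows are gapped are ignored for that
#' pair) and `"pairwise_deletion"` (only columns where both rows carry a
#' residue are compared).
#'
#' @param aln Named character vector of equal-length gapped rows (>= 2).
#' @param gap_mode `"gaps_as_difference"` (default, the curation setting)
#'   or `"pairwise_deletion"`.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
p_distance_matrix <- function(aln,
                              gap_mode = c("gaps_as_difference",
                                           "pairwise_deletion")) {
  gap_mode <- match.arg(gap_mode)
  if (length(aln) < 2L) stop("need at least two aligned sequences")
  m <- as_char_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    ri <- m[i, ]
    gi <- ri == "-"
    for (j in seq(i + 1L, n)) {
      rj <- m[j, ]
      gj <- rj == "-"
      if (gap_mode == "pairwise_deletion") {
        use <- !gi & !gj
      } else {
        use <- !(gi & gj)
      }
      if (!any(use)) {
        stop("no comparable sites between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      }
      D[i, j] <- D[j, i] <- sum(ri[use] != rj[use]) / sum(use)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining with two determinism guarantees: ties in the
#' Q-criterion are broken by the lexicographically smallest pair of cluster
#' representative ids, and negative branch-length estimates are clamped to
#' zero (optional). Exact on additive distance matrices.
#'
#' @param D Symmetric distance matrix with id dimnames (n >= 2).
#' @param clamp_negative Clamp negative branch lengths to 0 (default TRUE).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  if (!is.matrix(D) || is.null(rownames(D))) {
    stop("D must be a matrix with id dimnames")
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  ids <- rownames(D)
  n <- length(ids)
  if (n < 2L) stop("need at least two taxa")
  fmt <- function(x) sprintf("%.15g", x)
  clamp <- function(x) if (clamp_negative) max(x, 0) else x
  if (n == 2L) {
    d <- clamp(D[1, 2] / 2)
    txt <- paste0("(", ids[1], ":", fmt(d), ",", ids[2], ":", fmt(d), ");")
    return(ape::read.tree(text = txt))
  }
  # active clusters: newick fragment + lexicographically smallest member id
  frag <- ids
  rep_id <- ids
  Dm <- D
  while (length(frag) > 3L) {
    nn <- length(frag)
    R <- rowSums(Dm)
    Q <- (nn - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(r) {
      a <- rep_id[cand[r, 1]]; b <- rep_id[cand[r, 2]]
      paste(min(a, b), max(a, b), sep = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    di <- clamp(dij / 2 + (R[i] - R[j]) / (2 * (nn - 2)))
    dj <- clamp(dij - (dij / 2 + (R[i] - R[j]) / (2 * (nn - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(di), ",",
                       frag[j], ":", fmt(dj), ")")
    new_rep <- min(rep_id[i], rep_id[j])
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_id <- c(rep_id[keep], new_rep)
    rownames(Dm) <- colnames(Dm) <- rep_id
  }
  da <- clamp((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2)
  db <- clamp((Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2)
  dc <- clamp((Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  txt <- paste0("(", frag[1], ":", fmt(da), ",", frag[2], ":", fmt(db),
                ",", frag[3], ":", fmt(dc), ");")
  ape::read.tree(text = txt)
}

#' Patristic (tree-path) distances between leaves
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric matrix of path-length distances between tips.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

bipartition_keys <- function(tree) {
  # canonical key per internal edge: the side of the split NOT containing
  # the alphabetically first tip, as a sorted id string
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  # accumulate tip sets bottom-up over edges in postorder
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  keys <- character(0)
  nodes <- integer(0)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    side <- sort(unique(desc[[node]]))
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0L || length(side) == nt) next
    keys <- c(keys, paste(side, collapse = "\r"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicates containing the same bipartition. Supports are
#' stored as internal node labels (the common Newick dialect).
#'
#' @param aln Named character vector of equal-length gapped rows (>= 4).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param gap_mode Passed to [p_distance_matrix()].
#' @return The NJ tree with `node.label` holding support percentages.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              gap_mode = "gaps_as_difference") {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (length(aln) < 4L) stop("need at least 4 sequences for supports")
  m <- as_char_matrix(aln)
  tree <- neighbor_joining(p_distance_matrix(aln, gap_mode))
  bp <- bipartition_keys(tree)
  counts <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- collapse_rows(m[, cols, drop = FALSE])
    rep_tree <- try(neighbor_joining(p_distance_matrix(rep_aln, gap_mode)),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rk <- bipartition_keys(rep_tree)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps)
  labels <- rep("", tree$Nnode)
  labels[bp$nodes - length(tree$tip.label)] <- as.character(support)
  tree$node.label <- labels
  tree
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup.
#' If the outgroup is not monophyletic with respect to the ingroup, a
#' warning is issued and midpoint rooting is used instead.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Tip labels of the outgroup (all present in the tree).
#' @return A rooted [ape::phylo] tree.
#' @export
root_tree <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  rooted <- try(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                silent = TRUE)
  if (inherits(rooted, "try-error")) {
    warning("outgroup is not monophyletic; falling back to midpoint rooting")
    rooted <- phangorn::midpoint(tree)
  }
  rooted
}

#' Terminal branch lengths in a leaf's neighborhood
#'
#' Returns the pendant branch lengths of all leaves hanging off internal
#' nodes within `k` internal nodes of the query leaf (the query's parent
#' counts as the first), excluding the query itself. This is the
#' "related branches" context used by long-branch outlier detection.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param leaf Tip label.
#' @param k Neighborhood radius in internal nodes (default 2).
#' @return Named numeric vector of pendant branch lengths.
#' @export
neighborhood_lengths <- function(tree, leaf, k = 2L) {
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("leaf '", leaf, "' not in tree")
  nt <- length(tree$tip.label)
  # adjacency over all nodes
  adj <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  # BFS over internal nodes, depth = number of internal nodes crossed
  depth <- rep(NA_integer_, nt + tree$Nnode)
  depth[parent] <- 1L
  queue <- parent
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    if (depth[node] >= k) next
    for (nb in adj[[node]]) {
      if (nb > nt && is.na(depth[nb])) {
        depth[nb] <- depth[node] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  visited <- which(!is.na(depth))
  tips <- integer(0)
  for (node in visited) {
    nb <- adj[[node]]
    tips <- c(tips, nb[nb <= nt])
  }
  tips <- setdiff(unique(tips), tip)
  if (!length(tips)) return(stats::setNames(numeric(0), character(0)))
  pend <- vapply(tips, function(tp) {
    tree$edge.length[tree$edge[, 2] == tp]
  }, numeric(1))
  stats::setNames(pend, tree$tip.label[tips])
}
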