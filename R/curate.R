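#' Curation parameters
#'
#' Thresholds for the iterative phylogeny-driven curation loop. The
#' defaults are the published rules: a pendant branch longer than 0.3 in a
#' neighborhood of branches all under 0.1 flags a long-branch outlier, and
#' tree distances under 0.01 group putative isoforms.
#'
#' @param long_branch_threshold Pendant-branch length above which a leaf is
#'   an outlier candidate (default 0.3).
#' @param related_branch_threshold Every neighborhood pendant branch must
#'   be below this for the outlier call (default 0.1).
#' @param isoform_distance Tree distance below which two sequences are
#'   isoform candidates (default 0.01).
#' @param short_fraction A sequence shorter than this fraction of its
#'   partner is treated as a truncated fragment and may join an isoform
#'   group at a slightly larger distance when its motif architecture is a
#'   strict prefix of the partner's (default 0.5).
#' @param max_iterations Iteration cap for the curation loop (default 10).
#' @param architecture_rule How motif architectures gate isoform grouping:
#'   `"prefix_or_equal"` (default), `"exact"`, or `"ignore"`.
#' @param neighborhood_radius Radius (internal nodes) for the related-
#'   branch context (default 2).
#' @param isoform_metric `"patristic"` (tree-path distance, default) or
#'   `"pendant"` (attach distances via shared parent only).
#' @return An object of class `curation_params`.
#' @export
curation_params <- function(long_branch_threshold = 0.3,
                            related_branch_threshold = 0.1,
                            isoform_distance = 0.01,
                            short_fraction = 0.5,
                            max_iterations = 10L,
                            architecture_rule = c("prefix_or_equal",
                                                  "exact", "ignore"),
                            neighborhood_radius = 2L,
                            isoform_metric = c("patristic", "pendant")) {
  architecture_rule <- match.arg(architecture_rule)
  isoform_metric <- match.arg(isoform_metric)
  if (!(0 < isoform_distance &&
        isoform_distance < related_branch_threshold &&
        related_branch_threshold < long_branch_threshold)) {
    stop("need 0 < isoform_distance < related_branch_threshold ",
         "< long_branch_threshold")
  }
  structure(list(long_branch_threshold = long_branch_threshold,
                 related_branch_threshold = related_branch_threshold,
                 isoform_distance = isoform_distance,
                 short_fraction = short_fraction,
                 max_iterations = as.integer(max_iterations),
                 architecture_rule = architecture_rule,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 isoform_metric = isoform_metric),
            class = "curation_params")
}

#' Remove redundant sequences
#'
#' Drops sequences that are identical to, or exact substrings of, another
#' sequence; the longer sequence survives (ties by lexicographically
#' smaller id).
#'
#' @param seqs Named character vector of sequences.
#' @return List with `kept` (surviving sequences) and `removed`
#'   (data.frame: id, reason, target).
#' @export
remove_redundant <- function(seqs) {
  if (length(seqs) <= 1L) {
    return(list(kept = seqs,
                removed = data.frame(id = character(), reason = character(),
                                     target = character(),
                                     stringsAsFactors = FALSE)))
  }
  ord <- order(-nchar(seqs), names(seqs))
  kept_idx <- integer(0)
  removed_id <- character(0)
  removed_target <- character(0)
  for (i in ord) {
    dup_of <- NA_character_
    for (j in kept_idx) {
      if (grepl(seqs[[i]], seqs[[j]], fixed = TRUE)) {
        dup_of <- names(seqs)[j]
        break
      }
    }
    if (is.na(dup_of)) {
      kept_idx <- c(kept_idx, i)
    } else {
      removed_id <- c(removed_id, names(seqs)[i])
      removed_target <- c(removed_target, dup_of)
    }
  }
  kept <- seqs[sort(kept_idx)]
  list(kept = kept,
       removed = data.frame(id = removed_id,
                            reason = rep("duplicate", length(removed_id)),
                            target = removed_target,
                            stringsAsFactors = FALSE))
}

#' Detect long-branch outliers on a phylogram
#'
#' A leaf is flagged when its pendant branch exceeds
#' `long_branch_threshold` while every terminal branch in its neighborhood
#' (within `neighborhood_radius` internal nodes) is below
#' `related_branch_threshold`. Leaves with no neighborhood context are
#' never flagged.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param params A [curation_params()] object.
#' @param candidates Tip labels eligible for flagging (default: all tips).
#' @param ignore Tip labels whose pendant branches are excluded from the
#'   neighborhood context (the rule concerns non-outgroup branches, so
#'   rooting sequences are passed here). When exclusion empties the
#'   neighborhood — e.g. a rogue sequence drawn toward the outgroup —
#'   the radius expands until family context is found.
#' @return Character vector of flagged leaf ids.
#' @export
detect_long_branches <- function(tree, params = curation_params(),
                                 candidates = tree$tip.label,
                                 ignore = NULL) {
  flagged <- character(0)
  for (leaf in intersect(candidates, tree$tip.label)) {
    pend <- tree$edge.length[tree$edge[, 2] == match(leaf, tree$tip.label)]
    if (length(pend) != 1L || pend <= params$long_branch_threshold) next
    radius <- params$neighborhood_radius
    repeat {
      nb <- neighborhood_lengths(tree, leaf, radius)
      nb_all <- nb
      nb <- nb[setdiff(names(nb), ignore)]
      if (length(nb) || length(nb_all) >= length(tree$tip.label) - 1L) {
        break
      }
      radius <- radius + 1L
    }
    if (length(nb) && all(nb < params$related_branch_threshold)) {
      flagged <- c(flagged, leaf)
    }
  }
  flagged
}

union_find_components <- function(ids, edges) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(match(edges[r, 1], ids))
      b <- find(match(edges[r, 2], ids))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  split(ids, roots)
}

#' Group putative isoforms on a phylogram
#'
#' Builds a graph joining leaf pairs whose tree distance is below
#' `isoform_distance` and whose motif architectures satisfy the configured
#' rule (when architectures are supplied). Truncated-isoform evidence is
#' handled separately: tree distances count the missing tail as
#' difference, so a strictly shorter sequence whose architecture is a
#' strict prefix of its partner's joins the pair when the two agree over
#' their shared aligned region (pairwise-deletion distance below
#' `isoform_distance`, requires `aln`); without an alignment a fragment
#' below `short_fraction` of its partner's length with a strict-prefix
#' architecture joins at up to the related-branch threshold. Returns the
#' connected components with two or more members.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param seqs Named character vector of the leaf sequences.
#' @param architectures Optional named list of ordered motif-id vectors.
#' @param params A [curation_params()] object.
#' @param candidates Tip labels eligible for grouping (default: all tips).
#' @param aln Optional alignment covering the candidates, used for the
#'   shared-region distance of truncated-isoform pairs.
#' @return List of character vectors (disjoint groups, singletons
#'   omitted).
#' @export
detect_isoform_groups <- function(tree, seqs, architectures = NULL,
                                  params = curation_params(),
                                  candidates = tree$tip.label,
                                  aln = NULL) {
  ids <- intersect(tree$tip.label, intersect(candidates, names(seqs)))
  if (length(ids) < 2L) return(list())
  if (params$isoform_metric == "patristic") {
    Dfull <- patristic_distances(tree)
    D <- Dfull[ids, ids, drop = FALSE]
  } else {
    pend <- vapply(ids, function(lf) {
      tree$edge.length[tree$edge[, 2] == match(lf, tree$tip.label)]
    }, numeric(1))
    D <- outer(pend, pend, "+")
    dimnames(D) <- list(ids, ids)
  }
  arch_ok <- function(a, b) {
    if (is.null(architectures) || params$architecture_rule == "ignore") {
      return(TRUE)
    }
    architecture_match(architectures[[a]], architectures[[b]],
                       params$architecture_rule)
  }
  strict_prefix <- function(a, b) {
    aa <- architectures[[a]]; bb <- architectures[[b]]
    length(aa) < length(bb) && identical(aa, bb[seq_along(aa)])
  }
  aln_rows <- if (!is.null(aln)) as_char_matrix(aln[intersect(names(aln),
                                                              ids)])
  shared_region_dist <- function(a, b) {
    ra <- aln_rows[a, ]; rb <- aln_rows[b, ]
    use <- ra != "-" & rb != "-"
    if (!any(use)) return(NA_real_)
    sum(ra[use] != rb[use]) / sum(use)
  }
  edges <- matrix(character(0), ncol = 2)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      a <- ids[i]; b <- ids[j]
      d <- D[i, j]
      hit <- FALSE
      if (d < params$isoform_distance && arch_ok(a, b)) {
        hit <- TRUE
      } else if (!is.null(architectures)) {
        la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
        trunc_pair <- (la < lb && strict_prefix(a, b)) ||
          (lb < la && strict_prefix(b, a))
        if (trunc_pair && !is.null(aln_rows) &&
            all(c(a, b) %in% rownames(aln_rows))) {
          pd <- shared_region_dist(a, b)
          hit <- !is.na(pd) && pd < params$isoform_distance
        } else if (trunc_pair && d < params$related_branch_threshold &&
                   (min(la, lb) < params$short_fraction * max(la, lb))) {
          hit <- TRUE
        }
      }
      if (hit) edges <- rbind(edges, c(a, b))
    }
  }
  comps <- union_find_components(ids, edges)
  comps <- comps[vapply(comps, length, integer(1)) >= 2L]
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

#' Collapse isoform groups to representatives
#'
#' Keeps the longest member of each group (ties by lexicographically
#' smallest id); the others are ledgered as isoforms of the
#' representative.
#'
#' @param groups List of disjoint character vectors of sequence ids.
#' @param seqs Named character vector covering all group members.
#' @return List with `representatives` (kept ids) and `ledger`
#'   (data.frame: id, reason, target).
#' @export
collapse_isoforms <- function(groups, seqs) {
  reps <- character(0)
  led_id <- character(0)
  led_target <- character(0)
  for (g in groups) {
    lens <- nchar(seqs[g])
    rep_id <- g[order(-lens, g)][1]
    reps <- c(reps, rep_id)
    others <- setdiff(g, rep_id)
    led_id <- c(led_id, others)
    led_target <- c(led_target, rep(rep_id, length(others)))
  }
  reason <- if (length(led_target)) paste0("isoform_of:", led_target)
    else character(0)
  list(representatives = reps,
       ledger = data.frame(id = led_id, reason = reason,
                           target = led_target, stringsAsFactors = FALSE))
}

empty_ledger <- function() {
  data.frame(id = character(), reason = character(), target = character(),
             iteration = integer(), stringsAsFactors = FALSE)
}

#' Iterative phylogeny-driven family curation
#'
#' The full curation loop: remove redundant sequences, align and trim to
#' the coverage fixpoint, build a neighbor-joining tree on uncorrected
#' p-distances (gaps counted as differences), remove long-branch outliers,
#' collapse isoform groups, and repeat until an iteration makes no removal
#' (or `max_iterations` is reached, in which case the result carries a
#' warning flag). Reference sequences steady the alignment and tree but
#' are never removed or collapsed.
#'
#' @param candidates Named character vector of candidate proteins (>= 3).
#' @param refs Optional named character vector of reference/outgroup
#'   proteins.
#' @param params A [curation_params()] object.
#' @param architectures Optional named list of motif architectures.
#' @param neighborhood_ignore Tip ids (e.g. the outgroup) excluded from
#'   the long-branch neighborhood context.
#' @param matrix,gap_open,gap_ext Alignment parameters, passed through.
#' @return An object of class `curated_family`: `representatives`,
#'   `ledger` (id, reason, target, iteration), `iterations`, `alignment`,
#'   `tree`, `incomplete` (TRUE when the iteration cap was hit).
#' @export
curate_family <- function(candidates, refs = NULL,
                          params = curation_params(),
                          architectures = NULL,
                          neighborhood_ignore = NULL,
                          matrix = "BLOSUM62", gap_open = 10, gap_ext = 1) {
  if (length(candidates) < 3L) stop("need at least three candidates")
  stopifnot(!is.null(names(candidates)))
  ledger <- empty_ledger()
  iter <- 0L
  incomplete <- FALSE
  aln <- NULL
  tree <- NULL
  repeat {
    iter <- iter + 1L
    removed_this_iter <- 0L

    red <- remove_redundant(candidates)
    if (nrow(red$removed)) {
      red$removed$iteration <- iter
      ledger <- rbind(ledger, red$removed)
      removed_this_iter <- removed_this_iter + nrow(red$removed)
      candidates <- red$kept
    }

    pool <- c(candidates, refs)
    if (length(pool) < 2L) break
    atc <- align_trim_cycle(pool, matrix = matrix, gap_open = gap_open,
                            gap_ext = gap_ext)
    lowcov <- intersect(atc$removed, names(candidates))
    if (length(lowcov)) {
      ledger <- rbind(ledger, data.frame(
        id = lowcov, reason = "low_coverage", target = "",
        iteration = iter, stringsAsFactors = FALSE))
      removed_this_iter <- removed_this_iter + length(lowcov)
      candidates <- candidates[setdiff(names(candidates), lowcov)]
    }
    aln <- atc$alignment
    if (length(aln) < 3L || length(intersect(names(aln),
                                             names(candidates))) < 2L) {
      tree <- NULL
      break
    }
    D <- p_distance_matrix(aln, gap_mode = "gaps_as_difference")
    tree <- neighbor_joining(D)

    # isoform evidence is gathered before outlier removal: a truncated
    # isoform can sit on a long branch (its missing tail counts as
    # difference), and isoform identity trumps the outlier call
    groups <- detect_isoform_groups(tree, candidates, architectures,
                                    params, candidates = names(candidates),
                                    aln = aln)
    grouped_ids <- unlist(groups, use.names = FALSE)

    long <- detect_long_branches(tree, params,
                                 candidates = setdiff(names(candidates),
                                                      grouped_ids),
                                 ignore = neighborhood_ignore)
    if (length(long)) {
      ledger <- rbind(ledger, data.frame(
        id = long, reason = "long_branch_outlier", target = "",
        iteration = iter, stringsAsFactors = FALSE))
      removed_this_iter <- removed_this_iter + length(long)
      candidates <- candidates[setdiff(names(candidates), long)]
    }
    if (length(groups)) {
      col <- collapse_isoforms(groups, candidates)
      col$ledger$iteration <- iter
      ledger <- rbind(ledger, col$ledger)
      removed_this_iter <- removed_this_iter + nrow(col$ledger)
      candidates <- candidates[setdiff(names(candidates), col$ledger$id)]
    }

    if (removed_this_iter == 0L) break
    if (iter >= params$max_iterations) {
      incomplete <- TRUE
      break
    }
  }
  rownames(ledger) <- NULL
  structure(list(representatives = candidates, ledger = ledger,
                 iterations = iter, alignment = aln, tree = tree,
                 incomplete = incomplete),
            class = "curated_family")
}

#' @export
print.curated_family <- function(x, ...) {
  cat("Curated family:", length(x$representatives),
      "representative sequence(s) after", x$iterations, "iteration(s)\n")
  if (nrow(x$ledger)) {
    reason <- sub(":.*$", "", x$ledger$reason)
    tab <- table(reason)
    cat("Removed:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  } else {
    cat("Removed: none\n")
  }
  if (isTRUE(x$incomplete)) {
    cat("NOTE: iteration cap reached with removals still occurring\n")
  }
  invisible(x)
}
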