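#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 digits), the
#' convention that reproduces the published census percentages; base R's
#' `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

node_descendant_tips <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

#' Assign clades from labeled reference anchors
#'
#' For each non-reference leaf of a rooted tree, walks from its parent
#' toward the root and takes the first ancestral clade that contains at
#' least one reference; if that clade's references carry a single label,
#' the query inherits it (method `"monophyletic"`). Otherwise the nearest
#' reference by patristic distance decides (method `"nearest"`; distance
#' ties break to the lexicographically smaller label and are flagged).
#' With no references on the tree every query is `"unassigned"`.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param ref_labels Named character vector: reference tip id -> clade
#'   label. References absent from the tree are ignored.
#' @return data.frame with columns `id`, `clade`, `method`, `support`,
#'   `tie`.
#' @export
assign_clades <- function(tree, ref_labels) {
  ref_ids <- intersect(names(ref_labels), tree$tip.label)
  queries <- setdiff(tree$tip.label, names(ref_labels))
  out <- data.frame(id = queries, clade = "unassigned", method = "none",
                    support = NA_real_, tie = FALSE,
                    stringsAsFactors = FALSE)
  if (!length(ref_ids) || !length(queries)) return(out)
  nt <- length(tree$tip.label)
  desc <- node_descendant_tips(tree)
  parent_of <- integer(nt + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  Dp <- patristic_distances(tree)
  has_support <- !is.null(tree$node.label)
  for (r in seq_len(nrow(out))) {
    tip <- match(out$id[r], tree$tip.label)
    node <- parent_of[tip]
    assigned <- FALSE
    while (TRUE) {
      refs_here <- intersect(desc[[node]], ref_ids)
      if (length(refs_here)) {
        labels_here <- unique(ref_labels[refs_here])
        if (length(labels_here) == 1L) {
          out$clade[r] <- labels_here
          out$method[r] <- "monophyletic"
          if (has_support) {
            lab <- tree$node.label[node - nt]
            sup <- suppressWarnings(as.numeric(lab))
            if (!is.na(sup)) out$support[r] <- sup
          }
          assigned <- TRUE
        }
        break
      }
      if (node == root) break
      node <- parent_of[node]
    }
    if (!assigned) {
      d <- Dp[out$id[r], ref_ids]
      best <- min(d)
      nearest <- ref_ids[d <= best + 1e-12]
      labs <- sort(unique(ref_labels[nearest]))
      out$clade[r] <- labs[1]
      out$method[r] <- "nearest"
      out$tie[r] <- length(labs) > 1L
    }
  }
  out
}

#' Build a per-species, per-clade census table
#'
#' Tabulates clade assignments per species within each family, with
#' percentages of the species' family total computed half-up to two
#' decimals. Unassigned sequences are counted separately and excluded
#' from percentage denominators. An optional removed-sequence tally
#' (isoforms + outliers from the curation ledger) is carried alongside.
#'
#' @param assignments data.frame with columns `id`, `species`, `family`,
#'   `clade` (clade `"unassigned"` allowed).
#' @param removed_tally Optional data.frame with columns `species`,
#'   `family`, `n` (isoform/outlier counts).
#' @param clade_levels Optional named list: family -> character vector
#'   fixing clade order (clades absent from the data are reported as 0).
#' @return An object of class `census_table`: `cells` (family, clade,
#'   species, count, percent [numeric], percent_label), `totals` (family,
#'   species, total_on_tree, unassigned), `removed` (the tally).
#' @export
census <- function(assignments, removed_tally = NULL,
                   clade_levels = NULL) {
  stopifnot(all(c("id", "species", "family", "clade") %in%
                  names(assignments)))
  fams <- unique(assignments$family)
  cells <- NULL
  totals <- NULL
  for (fam in fams) {
    sub <- assignments[assignments$family == fam, , drop = FALSE]
    species <- sort(unique(sub$species))
    clades <- if (!is.null(clade_levels) && fam %in% names(clade_levels)) {
      clade_levels[[fam]]
    } else {
      sort(setdiff(unique(sub$clade), "unassigned"))
    }
    for (sp in species) {
      ss <- sub[sub$species == sp, , drop = FALSE]
      n_unassigned <- sum(ss$clade == "unassigned")
      on_tree <- ss[ss$clade != "unassigned", , drop = FALSE]
      total <- nrow(on_tree)
      counts <- vapply(clades, function(cl) sum(on_tree$clade == cl),
                       integer(1))
      pct <- if (total > 0) round_half_up(100 * counts / total, 2L) else
        rep(0, length(clades))
      cells <- rbind(cells, data.frame(
        family = fam, clade = clades, species = sp,
        count = as.integer(counts), percent = pct,
        percent_label = sprintf("%.2f%%", pct),
        stringsAsFactors = FALSE))
      totals <- rbind(totals, data.frame(
        family = fam, species = sp, total_on_tree = total,
        unassigned = n_unassigned, stringsAsFactors = FALSE))
    }
  }
  structure(list(cells = cells, totals = totals, removed = removed_tally),
            class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  for (fam in unique(x$cells$family)) {
    cat("Family:", fam, "\n")
    sub <- x$cells[x$cells$family == fam, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("clade", "species", "count", "percent_label")],
      direction = "wide", idvar = "clade", timevar = "species")
    names(wide) <- sub("^(count|percent_label)\\.", "\\1:", names(wide))
    print(wide, row.names = FALSE)
    tot <- x$totals[x$totals$family == fam, , drop = FALSE]
    cat("Total on tree:",
        paste(sprintf("%s=%d", tot$species, tot$total_on_tree),
              collapse = ", "), "\n")
    if (!is.null(x$removed)) {
      rem <- x$removed[x$removed$family == fam, , drop = FALSE]
      if (nrow(rem)) {
        cat("Isoforms and outliers:",
            paste(sprintf("%s=%d", rem$species, rem$n), collapse = ", "),
            "\n")
      }
    }
  }
  invisible(x)
}

#' @export
as.data.frame.census_table <- function(x, ...) x$cells

subtree_edges <- function(tree, node, desc_nodes) {
  # indices of edges fully inside the subtree rooted at `node`
  which(tree$edge[, 1] %in% desc_nodes[[node]])
}

#' Collapse tight groups for display
#'
#' Replaces every maximal clade whose mean branch length (over all edges
#' inside the clade) is below `threshold` with a single marker leaf named
#' `collapsed:<n>(<size> tips)`; the leaf content is returned in a sidecar
#' list. Marker leaves from a previous pass are never re-collapsed, so the
#' operation is idempotent.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param threshold Mean branch-length threshold (default 0.025).
#' @return List with `tree` (display tree) and `groups` (named list:
#'   marker label -> tip labels).
#' @export
collapse_display_groups <- function(tree, threshold = 0.025) {
  nt <- length(tree$tip.label)
  desc_tips <- node_descendant_tips(tree)
  # node sets per internal node (nodes inside subtree, including itself)
  desc_nodes <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt + tree$Nnode)) desc_nodes[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc_nodes[[parent]] <- c(desc_nodes[[parent]], desc_nodes[[child]])
  }
  qualifies <- rep(FALSE, nt + tree$Nnode)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    tips_here <- desc_tips[[node]]
    if (length(tips_here) < 2L) next
    if (any(startsWith(tips_here, "collapsed:"))) next
    ed <- subtree_edges(tree, node, desc_nodes)
    if (!length(ed)) next
    qualifies[node] <- mean(tree$edge.length[ed]) < threshold
  }
  parent_of <- integer(nt + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  is_maximal <- function(node) {
    p <- node
    while (p != root) {
      p <- parent_of[p]
      if (qualifies[p]) return(FALSE)
    }
    TRUE
  }
  targets <- which(qualifies)
  targets <- targets[vapply(targets, is_maximal, logical(1))]
  groups <- list()
  display <- tree
  for (k in seq_along(targets)) {
    node <- targets[k]
    tips_here <- desc_tips[[node]]
    marker <- sprintf("collapsed:%d(%d tips)", k, length(tips_here))
    groups[[marker]] <- sort(tips_here)
    keep_one <- tips_here[1]
    drop <- setdiff(tips_here, keep_one)
    display <- ape::drop.tip(display, drop,
                             trim.internal = TRUE, collapse.singles = TRUE)
    display$tip.label[display$tip.label == keep_one] <- marker
  }
  list(tree = display, groups = groups)
}
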