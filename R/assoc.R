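#' Build motif architectures from a hit table
#'
#' Orders each sequence's motif hits by start position (ties by motif id)
#' into an architecture: the ordered list of motif ids along the protein.
#' Hit coordinates are 1-based inclusive and must lie within the
#' sequence.
#'
#' @param hits data.frame with columns `sequence_id`, `motif_id`, `start`,
#'   `stop`.
#' @param seq_lengths Named integer vector of sequence lengths; sequences
#'   without hits receive an empty architecture.
#' @return Named list: sequence id -> character vector of motif ids.
#' @export
build_architectures <- function(hits, seq_lengths) {
  stopifnot(all(c("sequence_id", "motif_id", "start", "stop") %in%
                  names(hits)))
  unknown <- setdiff(unique(hits$sequence_id), names(seq_lengths))
  if (length(unknown)) {
    stop("motif hit(s) for unknown sequence id: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  bad <- hits$start < 1L | hits$stop < hits$start |
    hits$stop > seq_lengths[hits$sequence_id]
  if (any(bad)) {
    stop("out-of-bounds motif hit for sequence '",
         hits$sequence_id[which(bad)[1]], "'")
  }
  arch <- stats::setNames(
    replicate(length(seq_lengths), character(0), simplify = FALSE),
    names(seq_lengths))
  if (nrow(hits)) {
    ord <- order(hits$sequence_id, hits$start, hits$motif_id)
    h <- hits[ord, , drop = FALSE]
    by_seq <- split(h$motif_id, h$sequence_id)
    arch[names(by_seq)] <- by_seq
  }
  arch
}

#' Compare two motif architectures
#'
#' `"exact"`: identical ordered lists. `"prefix_or_equal"`: one list is a
#' prefix of (or equal to) the other — the natural rule for truncated
#' isoforms.
#'
#' @param a,b Character vectors of ordered motif ids.
#' @param rule `"exact"` or `"prefix_or_equal"`.
#' @return TRUE or FALSE.
#' @export
architecture_match <- function(a, b, rule = c("prefix_or_equal",
                                              "exact")) {
  rule <- match.arg(rule)
  a <- as.character(a); b <- as.character(b)
  if (rule == "exact") return(identical(a, b))
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  identical(a, b[seq_along(a)])
}

#' Motif association with clades, stages, or species
#'
#' For each motif, counts its occurrences per group (clade, stage of
#' strongest expression, or species of the carrying sequence), reports
#' the modal group with its count and percentage of the motif's total
#' occurrences, and flags motifs exclusive to one group. Count ties break
#' to the lexicographically smaller group id and are flagged.
#'
#' @param hits Motif hit data.frame (`sequence_id`, `motif_id`, ...).
#' @param group_map Named character vector: sequence id -> group value.
#'   Every hit's sequence must be mapped.
#' @param key Label for the grouping ("clade", "stage", or "species");
#'   recorded in the output.
#' @return data.frame with columns `motif_id`, `key`, `modal_group`,
#'   `count`, `total`, `percent`, `exclusive`, `tie`. The full
#'   motif-by-group count table is attached as attribute `"by_group"`.
#' @export
motif_association <- function(hits, group_map, key = "group") {
  unmapped <- setdiff(unique(hits$sequence_id), names(group_map))
  if (length(unmapped)) {
    stop("hit sequence(s) without a value for the grouping key: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  if (nrow(hits) == 0L) {
    out <- data.frame(motif_id = character(), key = character(),
                      modal_group = character(), count = integer(),
                      total = integer(), percent = numeric(),
                      exclusive = logical(), tie = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "by_group") <- out[0, 0]
    return(out)
  }
  grp <- unname(group_map[hits$sequence_id])
  tab <- table(hits$motif_id, grp)
  rows <- lapply(rownames(tab), function(m) {
    counts <- tab[m, ]
    total <- sum(counts)
    best <- max(counts)
    modal_ids <- sort(names(counts)[counts == best])
    data.frame(motif_id = m, key = key, modal_group = modal_ids[1],
               count = as.integer(best), total = as.integer(total),
               percent = round_half_up(100 * best / total, 2L),
               exclusive = sum(counts > 0) == 1L,
               tie = length(modal_ids) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "by_group") <- tab
  out
}

#' Orthogroup-by-clade contingency table
#'
#' Cross-tabulates orthogroup membership against clade assignment and
#' flags orthogroups spanning multiple clades and clades split over
#' multiple orthogroups. Assigned sequences without a membership are
#' listed as unmatched.
#'
#' @param orthogroups data.frame with columns `sequence_id`,
#'   `orthogroup_id`.
#' @param assignments data.frame with columns `id`, `clade`.
#' @return List with `crosstab` (long data.frame: orthogroup_id, clade,
#'   n), `orthogroup_flags` (orthogroup_id, n_clades,
#'   orthogroup_multi_clade), `clade_flags` (clade, n_orthogroups,
#'   clade_multi_orthogroup), `unmatched` (assigned ids without
#'   membership).
#' @export
orthogroup_clade_crosstab <- function(orthogroups, assignments) {
  merged <- merge(orthogroups, assignments[, c("id", "clade")],
                  by.x = "sequence_id", by.y = "id")
  unmatched <- setdiff(assignments$id, orthogroups$sequence_id)
  if (nrow(merged) == 0L) {
    return(list(
      crosstab = data.frame(orthogroup_id = character(),
                            clade = character(), n = integer(),
                            stringsAsFactors = FALSE),
      orthogroup_flags = data.frame(orthogroup_id = character(),
                                    n_clades = integer(),
                                    orthogroup_multi_clade = logical(),
                                    stringsAsFactors = FALSE),
      clade_flags = data.frame(clade = character(),
                               n_orthogroups = integer(),
                               clade_multi_orthogroup = logical(),
                               stringsAsFactors = FALSE),
      unmatched = unmatched))
  }
  agg <- stats::aggregate(rep(1L, nrow(merged)),
                          by = list(orthogroup_id = merged$orthogroup_id,
                                    clade = merged$clade),
                          FUN = sum)
  names(agg)[3] <- "n"
  agg <- agg[order(agg$orthogroup_id, agg$clade), , drop = FALSE]
  rownames(agg) <- NULL
  og_flags <- stats::aggregate(agg$clade,
                               by = list(orthogroup_id =
                                           agg$orthogroup_id),
                               FUN = function(x) length(unique(x)))
  names(og_flags)[2] <- "n_clades"
  og_flags$orthogroup_multi_clade <- og_flags$n_clades > 1L
  cl_flags <- stats::aggregate(agg$orthogroup_id,
                               by = list(clade = agg$clade),
                               FUN = function(x) length(unique(x)))
  names(cl_flags)[2] <- "n_orthogroups"
  cl_flags$clade_multi_orthogroup <- cl_flags$n_orthogroups > 1L
  list(crosstab = agg, orthogroup_flags = og_flags,
       clade_flags = cl_flags, unmatched = unmatched)
}

#' Modal strongest-expression stage per orthogroup
#'
#' For each orthogroup, the most common stage of strongest expression
#' among its members with a call; ties break to the earliest stage in the
#' fixed stage order and are flagged.
#'
#' @param orthogroups data.frame with columns `sequence_id`,
#'   `orthogroup_id`.
#' @param calls Stage calls (`gene_id`, `stage`) from [stage_calls()].
#' @return data.frame with columns `orthogroup_id`, `modal_stage`,
#'   `n_members`, `n_with_call`, `tie`.
#' @export
orthogroup_stage_preference <- function(orthogroups, calls) {
  merged <- merge(orthogroups, calls[, c("gene_id", "stage")],
                  by.x = "sequence_id", by.y = "gene_id", all.x = TRUE)
  ogs <- sort(unique(orthogroups$orthogroup_id))
  rows <- lapply(ogs, function(og) {
    sub <- merged[merged$orthogroup_id == og, , drop = FALSE]
    st <- sub$stage[!is.na(sub$stage) & sub$stage != "none"]
    if (!length(st)) {
      return(data.frame(orthogroup_id = og, modal_stage = "none",
                        n_members = nrow(sub), n_with_call = 0L,
                        tie = FALSE, stringsAsFactors = FALSE))
    }
    counts <- table(st)
    best <- max(counts)
    modal <- names(counts)[counts == best]
    modal <- modal[order(match(modal, stage_set()))][1]
    data.frame(orthogroup_id = og, modal_stage = modal,
               n_members = nrow(sub), n_with_call = length(st),
               tie = sum(counts == best) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
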