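resolve_isoform_map <- function(representatives, ledger) {
  # map every sequence id to its surviving representative (or drop it)
  target <- stats::setNames(ledger$target, ledger$id)
  collapsed <- ledger$id[grepl("^isoform_of:", ledger$reason) |
                           ledger$reason == "duplicate"]
  map <- stats::setNames(representatives, representatives)
  for (id in collapsed) {
    cur <- id
    steps <- 0L
    while (!(cur %in% representatives) && steps < 100L) {
      nxt <- target[[cur]]
      if (is.null(nxt) || is.na(nxt) || !nzchar(nxt)) break
      cur <- nxt
      steps <- steps + 1L
    }
    if (cur %in% representatives) map[id] <- cur
  }
  map
}

#' Run the full mining pipeline
#'
#' Chains the pipeline stages: translated homology screening, best-hit
#' confirmation against an annotated database, iterative phylogeny-driven
#' curation, outgroup rooting and reference-anchored clade assignment,
#' the per-species census, stage-of-strongest-expression profiling, and
#' motif / orthogroup association summaries. Deterministic for fixed
#' inputs; every output lands under `out_dir` when given.
#'
#' @param transcripts Named nucleotide sequences to mine.
#' @param refs Named bait/reference proteins.
#' @param ref_labels data.frame (`id`, `clade`, optionally `family`)
#'   labeling the references.
#' @param outgroup Named outgroup protein(s) used for rooting.
#' @param annotated_db,db_families Optional confirmation database (named
#'   proteins; named family labels, decoys unlabeled). When omitted the
#'   confirmation stage is skipped.
#' @param expression Optional per-isoform FPKM table (`sequence_id`,
#'   `species`, `stage`, `fpkm`).
#' @param motif_hits Optional motif hit table (`sequence_id`, `motif_id`,
#'   `start`, `stop`), in best-frame protein coordinates.
#' @param orthogroups Optional membership table (`sequence_id`,
#'   `orthogroup_id`).
#' @param species_map Named character vector: transcript id -> species.
#' @param stage_masks Named list of per-species stage masks (defaults to
#'   [default_stage_masks()] over the species present).
#' @param scoring A [scoring_params()] object.
#' @param curation A [curation_params()] object.
#' @param clade_levels Optional named list fixing census clade order.
#' @param family Family label used in the census (default `"FAM"`).
#' @param out_dir Optional output directory.
#' @return A list: `candidates`, `confirmed`, `curated`
#'   (the [curate_family()] result), `rooted_tree`, `assignments`,
#'   `census`, `gene_expression`, `stage_calls`, `clade_stage_summary`,
#'   `motif_assoc` (by clade/stage/species), `og_crosstab`,
#'   `og_stage_pref`, `report` (per-stage counts and parameters).
#' @export
run_pipeline <- function(transcripts, refs, ref_labels, outgroup,
                         annotated_db = NULL, db_families = NULL,
                         expression = NULL, motif_hits = NULL,
                         orthogroups = NULL, species_map,
                         stage_masks = NULL,
                         scoring = scoring_params(),
                         curation = curation_params(),
                         clade_levels = NULL, family = "FAM",
                         out_dir = NULL) {
  stage <- "screen"
  res <- tryCatch({
    candidates <- screen_transcriptome(transcripts, refs, scoring)

    stage <- "confirm"
    if (!is.null(annotated_db)) {
      bh <- best_hit_confirm(candidates, annotated_db, db_families,
                             scoring)
      confirmed <- bh$confirmed
    } else {
      confirmed <- candidates
      confirmed$best_match <- NA_character_
      confirmed$best_family <- NA_character_
    }
    cand_prot <- stats::setNames(confirmed$protein,
                                 confirmed$transcript_id)

    stage <- "curate"
    architectures <- NULL
    if (!is.null(motif_hits)) {
      sub_hits <- motif_hits[motif_hits$sequence_id %in%
                               names(cand_prot), , drop = FALSE]
      architectures <- build_architectures(sub_hits, nchar(cand_prot))
    }
    cf <- curate_family(cand_prot, refs = c(refs, outgroup),
                        params = curation, architectures = architectures,
                        neighborhood_ignore = names(outgroup))

    stage <- "classify"
    if (is.null(cf$tree)) stop("curation left no usable tree")
    og_in_tree <- intersect(names(outgroup), cf$tree$tip.label)
    rooted <- if (length(og_in_tree)) root_tree(cf$tree, og_in_tree) else
      phangorn::midpoint(cf$tree)
    anchor_labels <- c(stats::setNames(ref_labels$clade, ref_labels$id),
                       stats::setNames(rep("outgroup", length(outgroup)),
                                       names(outgroup)))
    assignments <- assign_clades(rooted, anchor_labels)
    # a candidate resolving to the outgroup anchor has no family clade
    assignments$clade[assignments$clade == "outgroup"] <- "unassigned"
    assignments$species <- unname(species_map[assignments$id])
    assignments$family <- family

    stage <- "census"
    led <- cf$ledger
    io_rows <- led[grepl("^isoform_of:", led$reason) |
                     led$reason == "long_branch_outlier", , drop = FALSE]
    removed_tally <- NULL
    if (nrow(io_rows)) {
      agg <- stats::aggregate(rep(1L, nrow(io_rows)),
                              by = list(species =
                                          unname(species_map[io_rows$id])),
                              FUN = sum)
      removed_tally <- data.frame(species = agg[[1]], family = family,
                                  n = agg[[2]], stringsAsFactors = FALSE)
    }
    cen <- census(assignments, removed_tally, clade_levels)

    stage <- "profiles"
    gene_table <- NULL; calls <- NULL; css <- NULL
    masks <- stage_masks
    if (!is.null(expression)) {
      if (is.null(masks)) {
        masks <- default_stage_masks(unique(expression$species))
      }
      iso_map <- resolve_isoform_map(names(cf$representatives), led)
      expr_use <- expression[expression$sequence_id %in% names(iso_map), ,
                             drop = FALSE]
      gene_table <- gene_fpkm(expr_use, iso_map)
      calls <- stage_calls(gene_table, masks)
      css <- clade_stage_summary(assignments, calls)
    }

    stage <- "assoc"
    motif_assoc <- NULL; og_crosstab <- NULL; og_stage_pref <- NULL
    if (!is.null(motif_hits)) {
      rep_hits <- motif_hits[motif_hits$sequence_id %in%
                               names(cf$representatives), , drop = FALSE]
      clade_map <- stats::setNames(assignments$clade, assignments$id)
      motif_assoc <- list(
        clade = motif_association(rep_hits, clade_map, "clade"),
        species = motif_association(rep_hits, species_map, "species"))
      if (!is.null(calls)) {
        stage_map <- stats::setNames(calls$stage, calls$gene_id)
        hits_called <- rep_hits[rep_hits$sequence_id %in%
                                  names(stage_map), , drop = FALSE]
        motif_assoc$stage <- motif_association(hits_called, stage_map,
                                               "stage")
      }
    }
    if (!is.null(orthogroups)) {
      og_rep <- orthogroups[orthogroups$sequence_id %in%
                              names(cf$representatives), , drop = FALSE]
      og_crosstab <- orthogroup_clade_crosstab(og_rep, assignments)
      if (!is.null(calls)) {
        og_stage_pref <- orthogroup_stage_preference(og_rep, calls)
      }
    }

    report <- list(
      n_transcripts = length(transcripts),
      n_candidates = nrow(candidates),
      n_confirmed = nrow(confirmed),
      n_representatives = length(cf$representatives),
      removals_by_reason = if (nrow(led))
        table(sub(":.*$", "", led$reason)) else table(character(0)),
      curation_iterations = cf$iterations,
      n_assigned = sum(assignments$clade != "unassigned"),
      evalue_cutoff = scoring$evalue_cutoff,
      long_branch_threshold = curation$long_branch_threshold,
      related_branch_threshold = curation$related_branch_threshold,
      isoform_distance = curation$isoform_distance)

    list(candidates = candidates, confirmed = confirmed, curated = cf,
         rooted_tree = rooted, assignments = assignments, census = cen,
         gene_expression = gene_table, stage_calls = calls,
         clade_stage_summary = css, motif_assoc = motif_assoc,
         og_crosstab = og_crosstab, og_stage_pref = og_stage_pref,
         report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_table(res$candidates[, setdiff(names(res$candidates),
                                           "protein")],
                  p("candidates.tsv"))
  write_fasta(res$curated$representatives, p("curated.fasta"))
  write_tsv_table(res$curated$ledger, p("ledger.tsv"))
  if (!is.null(res$curated$tree)) {
    write_newick(res$curated$tree, p("tree.nwk"))
  }
  write_newick(res$rooted_tree, p("rooted_tree.nwk"))
  write_tsv_table(res$assignments, p("assignments.tsv"))
  write_tsv_table(res$census$cells, p("census.tsv"))
  write_tsv_table(res$census$totals, p("census_totals.tsv"))
  if (!is.null(res$gene_expression)) {
    write_tsv_table(res$gene_expression, p("gene_expression.tsv"))
    write_tsv_table(res$stage_calls, p("stage_calls.tsv"))
    write_tsv_table(res$clade_stage_summary$summary,
                    p("clade_stage_summary.tsv"))
  }
  if (!is.null(res$motif_assoc)) {
    for (key in names(res$motif_assoc)) {
      write_tsv_table(res$motif_assoc[[key]],
                      p(sprintf("motif_assoc_%s.tsv", key)))
    }
  }
  if (!is.null(res$og_crosstab)) {
    write_tsv_table(res$og_crosstab$crosstab, p("og_clade_crosstab.tsv"))
  }
  if (!is.null(res$og_stage_pref)) {
    write_tsv_table(res$og_stage_pref, p("og_stage_pref.tsv"))
  }
  invisible(out_dir)
}

#' Generate a synthetic data set and run the pipeline on it
#'
#' Convenience driver for validation studies: generates the reference
#' panel, transcriptome, expression, motif and orthogroup tables from one
#' [synth_config()], runs [run_pipeline()], and returns the pipeline
#' result together with the generator truth table.
#'
#' @param config A [synth_config()] object.
#' @param out_dir Optional output directory (passed to the pipeline).
#' @param ... Overrides passed to [run_pipeline()] (e.g. `curation`).
#' @return A list: all [run_pipeline()] components plus `truth`, `panel`,
#'   and the generated inputs.
#' @export
run_synthetic_pipeline <- function(config = synth_config(),
                                   out_dir = NULL, ...) {
  panel <- generate_reference_panel(config)
  tx <- generate_transcriptome(panel, config)
  expr <- generate_expression(tx$truth, config)
  hits <- generate_motif_hits(tx$truth, config)
  ogs <- generate_orthogroups(tx$truth)
  species_map <- stats::setNames(tx$truth$species,
                                 tx$truth$transcript_id)
  db <- c(panel$refs, panel$decoy_db)
  db_fam <- c(stats::setNames(panel$labels$family, panel$labels$id),
              stats::setNames(rep("", length(panel$decoy_db)),
                              names(panel$decoy_db)))
  res <- run_pipeline(
    transcripts = tx$transcripts, refs = panel$refs,
    ref_labels = panel$labels, outgroup = panel$outgroup,
    annotated_db = db, db_families = db_fam,
    expression = expr, motif_hits = hits, orthogroups = ogs,
    species_map = species_map,
    stage_masks = config$species_masks,
    clade_levels = stats::setNames(list(config$clades), "FAM"),
    out_dir = out_dir, ...)
  c(res, list(truth = tx$truth, panel = panel, transcripts = tx$transcripts,
              proteins = tx$proteins, expression = expr,
              motif_hits = hits, orthogroups = ogs))
}
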