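test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_clades = 1), "at least 2")
  expect_error(synth_config(isoform_rate = 1.5), "rates")
  expect_error(synth_config(isoform_divergence = 0.02),
               "isoform_divergence")
  expect_error(synth_config(paralog_divergence = 0.005),
               "isoform_divergence")
  expect_error(synth_config(inter_clade_divergence = 0.1),
               "inter-clade")
  expect_error(synth_config(genes_per_clade_per_species = 0),
               "non-positive")
  cfg <- synth_config()
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$isoform_divergence, 0.004)
  expect_equal(cfg$paralog_divergence, 0.15)
  expect_equal(cfg$inter_clade_divergence, 0.45)
})

test_that("the reference panel is labeled, rooted, and deterministic", {
  cfg <- synth_config(seed = 9, n_clades = 2, refs_per_clade = 1)
  panel <- generate_reference_panel(cfg)
  # minimal case: one labeled ref per clade plus one outgroup
  expect_equal(length(panel$refs), 2L)
  expect_equal(sort(unique(panel$labels$clade)), sort(cfg$clades))
  expect_equal(length(panel$outgroup), 1L)
  # byte-identical under the same seed
  panel2 <- generate_reference_panel(cfg)
  expect_identical(panel, panel2)
  # outgroup farther from every clade ancestor than clades are from
  # each other
  pd <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca != cb)
  }
  anc <- panel$clade_ancestors
  inter <- pd(anc[[1]], anc[[2]])
  out_d <- vapply(anc, function(a) pd(a, panel$outgroup[[1]]),
                  numeric(1))
  expect_true(all(out_d > inter))
})

test_that("inter-clade divergence is calibrated to its target", {
  # mean pairwise ancestor p-distance across seeds near 0.45
  pd <- function(a, b) mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  ds <- c()
  for (sd in 1:10) {
    cfg <- synth_config(seed = sd, n_clades = 3)
    anc <- generate_reference_panel(cfg)$clade_ancestors
    ds <- c(ds, pd(anc[[1]], anc[[2]]), pd(anc[[1]], anc[[3]]),
            pd(anc[[2]], anc[[3]]))
  }
  expect_lt(abs(mean(ds) - 0.45), 0.1)
})

test_that("the transcriptome matches its truth table", {
  cfg <- synth_config(seed = 17)
  panel <- generate_reference_panel(cfg)
  tx <- generate_transcriptome(panel, cfg)
  # truth completeness: every transcript appears exactly once
  expect_equal(sort(names(tx$transcripts)),
               sort(tx$truth$transcript_id))
  expect_equal(anyDuplicated(tx$truth$transcript_id), 0L)
  # isoforms reference an existing gene
  iso <- tx$truth[tx$truth$role == "isoform", ]
  genes <- tx$truth$transcript_id[tx$truth$role == "gene"]
  expect_true(all(iso$true_gene %in% genes))
  # determinism
  tx2 <- generate_transcriptome(panel, cfg)
  expect_identical(tx, tx2)
  # no isoform rows when the rate is zero
  cfg0 <- synth_config(seed = 17, isoform_rate = 0)
  tx0 <- generate_transcriptome(generate_reference_panel(cfg0), cfg0)
  expect_equal(sum(tx0$truth$role == "isoform"), 0L)
})

test_that("truncated isoforms have the advertised lengths and prefixes", {
  cfg <- synth_config(seed = 25, isoform_rate = 1,
                      truncated_isoform_share = 1,
                      truncation_fraction = c(0.3, 0.5))
  panel <- generate_reference_panel(cfg)
  tx <- generate_transcriptome(panel, cfg)
  iso <- tx$truth[tx$truth$role == "isoform", ]
  L <- cfg$protein_length
  expect_true(all(iso$length_aa >= floor(0.5 * L) - 1))
  expect_true(all(iso$length_aa <= ceiling(0.7 * L) + 1))
  # architecture is a prefix of the parent gene's
  for (r in seq_len(nrow(iso))) {
    par_arch <- strsplit(
      tx$truth$true_motif_architecture[
        tx$truth$transcript_id == iso$true_gene[r]], ",")[[1]]
    iso_arch <- strsplit(iso$true_motif_architecture[r], ",")[[1]]
    expect_true(architecture_match(iso_arch, par_arch,
                                   "prefix_or_equal"))
  }
})

test_that("isoform and paralog distances separate around 0.01", {
  pd <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    mean(strsplit(substr(a, 1, L), "")[[1]] !=
           strsplit(substr(b, 1, L), "")[[1]])
  }
  iso_d <- c(); par_d <- c()
  for (sd in 1:10) {
    cfg <- synth_config(seed = sd)
    panel <- generate_reference_panel(cfg)
    tx <- generate_transcriptome(panel, cfg)
    truth <- tx$truth
    iso <- truth[truth$role == "isoform", ]
    for (r in seq_len(nrow(iso))) {
      iso_d <- c(iso_d, pd(tx$proteins[[iso$transcript_id[r]]],
                           tx$proteins[[iso$true_gene[r]]]))
    }
    genes <- truth[truth$role == "gene", ]
    for (cl in unique(genes$true_clade)) {
      ids <- genes$transcript_id[genes$true_clade == cl]
      if (length(ids) >= 2) {
        par_d <- c(par_d, pd(tx$proteins[[ids[1]]],
                             tx$proteins[[ids[2]]]))
      }
    }
  }
  # distributions do not overlap across the 0.01 rule
  expect_lt(max(iso_d), 0.01)
  expect_gte(min(par_d), 0.01)
  # measured isoform distance below 0.01 in at least 99% of pairs
  expect_gte(mean(iso_d < 0.01), 0.99)
})

test_that("expression tables respect masks, conservation and argmax", {
  cfg <- synth_config(seed = 33)
  panel <- generate_reference_panel(cfg)
  tx <- generate_transcriptome(panel, cfg)
  expr <- generate_expression(tx$truth, cfg)
  expect_true(all(expr$fpkm >= 0))
  # masked stages are absent per species
  for (sp in names(cfg$species_masks)) {
    got <- unique(expr$stage[expr$species == sp])
    expect_true(all(got %in% cfg$species_masks[[sp]]))
  }
  # gene-level sum equals isoform sum by construction (via gene_fpkm)
  map <- stats::setNames(
    ifelse(is.na(tx$truth$true_gene), tx$truth$transcript_id,
           tx$truth$true_gene),
    tx$truth$transcript_id)
  gt <- gene_fpkm(expr, map)
  for (st in unique(expr$stage)) {
    expect_equal(sum(gt$fpkm[gt$stage == st]),
                 sum(expr$fpkm[expr$stage == st]))
  }
  # empty truth gives an empty table
  expect_equal(nrow(generate_expression(tx$truth[0, ], cfg)), 0L)
  # determinism
  expect_identical(expr, generate_expression(tx$truth, cfg))
})

test_that("designated stages win the argmax in nearly all genes", {
  hits <- 0; total <- 0
  for (sd in 1:10) {
    cfg <- synth_config(seed = sd, expression_dynamic_range = 10)
    panel <- generate_reference_panel(cfg)
    tx <- generate_transcriptome(panel, cfg)
    expr <- generate_expression(tx$truth, cfg)
    map <- stats::setNames(
      ifelse(is.na(tx$truth$true_gene), tx$truth$transcript_id,
             tx$truth$true_gene), tx$truth$transcript_id)
    gt <- gene_fpkm(expr, map)
    calls <- stage_calls(gt, cfg$species_masks)
    truth_g <- tx$truth[tx$truth$role == "gene", ]
    m <- merge(calls, truth_g, by.x = "gene_id",
               by.y = "transcript_id")
    hits <- hits + sum(m$stage == m$true_strongest_stage)
    total <- total + nrow(m)
  }
  expect_gte(hits / total, 0.95)
})

test_that("motif hits are ordered and orthogroups follow the config", {
  cfg <- synth_config(seed = 41, n_clades = 7,
                      genes_per_clade_per_species = 5,
                      orthogroup_splits = c(STP = 5))
  panel <- generate_reference_panel(cfg)
  tx <- generate_transcriptome(panel, cfg)
  hits <- generate_motif_hits(tx$truth, cfg)
  # within every sequence, start positions strictly increase
  for (sid in unique(hits$sequence_id)) {
    st <- hits$start[hits$sequence_id == sid]
    expect_true(all(diff(st) > 0))
  }
  # grammar order: shared motif first
  arch <- build_architectures(
    hits, stats::setNames(tx$truth$length_aa, tx$truth$transcript_id))
  g1 <- tx$truth$transcript_id[tx$truth$role == "gene"][1]
  expect_equal(arch[[g1]][1], "m_shared")
  # decoys carry no planted motifs
  decoys <- tx$truth$transcript_id[tx$truth$role == "decoy"]
  expect_equal(sum(hits$sequence_id %in% decoys), 0L)
  # STP-like clade split into five orthogroups, recounted from the TSV
  ogs <- generate_orthogroups(tx$truth)
  stp_ids <- tx$truth$transcript_id[!is.na(tx$truth$true_clade) &
                                      tx$truth$true_clade == "STP"]
  stp_ogs <- unique(ogs$orthogroup_id[ogs$sequence_id %in% stp_ids])
  expect_equal(length(stp_ogs), 5L)
  # other clades keep one orthogroup
  erd_ids <- tx$truth$transcript_id[!is.na(tx$truth$true_clade) &
                                      tx$truth$true_clade == "ERD6"]
  expect_equal(length(unique(ogs$orthogroup_id[ogs$sequence_id %in%
                                                 erd_ids])), 1L)
})
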