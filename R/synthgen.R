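AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# fixed most-frequent-codon back-translation table; codon choice does not
# affect any downstream protein-level computation
CODON_OF <- c(A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGA", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# i.i.d. per-site substitution under a uniform replacement kernel:
# each site mutates with probability p, to one of the 19 other residues
evolve_protein <- function(seq, p) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < p
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# exactly n substitutions at distinct random sites (used for isoform
# copies, where the separation below the 0.01 grouping threshold must be
# controlled tightly)
mutate_exact <- function(seq, n_sub) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_sub > 0L) {
    sites <- sample.int(length(chars), min(n_sub, length(chars)))
    for (i in sites) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# per-branch substitution probability so that two sequences evolved
# independently from a common ancestor sit at expected p-distance D:
# 1 - [(1-p)^2 + p^2/19] = D
p_for_pairwise <- function(D) {
  a <- 20 / 19
  (1 - sqrt(1 - a * D)) / a
}

# branch probability for the second lineage when the first used p_fixed
# and the target pairwise distance is D
p_for_cross <- function(D, p_fixed) {
  (D - p_fixed) / (1 - p_fixed * 20 / 19)
}

back_translate <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(CODON_OF[chars], collapse = "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

default_clade_names <- function(n) {
  base <- c("ERD6", "pGLT_SGB", "INT", "TMT", "PMT", "VGT", "STP")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("CL", seq_len(n - length(base))))
}

#' Configuration for the synthetic transcriptome generator
#'
#' Defines the statistical structure of a synthetic multi-clade gene
#' family: divergence levels chosen so that the curation thresholds
#' separate sequence classes (isoform copies well below the 0.01 grouping
#' distance, paralogs well above it), near-identical and truncated
#' isoforms, fast-evolving outliers, non-family decoys, planted ordered
#' motif architectures, and stage-structured expression with one
#' designated strongest stage per gene. The seed fully determines every
#' output.
#'
#' @param seed Integer seed.
#' @param n_clades Number of clades (>= 2).
#' @param genes_per_clade_per_species Genes per clade in each species
#'   (single integer, or named integer vector by species id).
#' @param species_masks Named list: species id -> available stage ids.
#'   Default: three species, the third of which reaches stage 6.3.
#' @param isoform_rate Fraction of genes receiving an extra isoform.
#' @param isoform_divergence Expected per-site substitution fraction for
#'   isoform copies (default 0.004; must stay below 0.01).
#' @param paralog_divergence Expected pairwise divergence between genes
#'   within a clade (default 0.15; must exceed 0.01).
#' @param inter_clade_divergence Expected pairwise divergence between
#'   clade ancestors (default 0.45).
#' @param outlier_rate Planted outliers as a fraction of gene count.
#' @param outlier_branch_scale Outlier branch substitution-event
#'   multiplier relative to a within-clade gene branch (default 10);
#'   multiple hits saturate the observed divergence, so outliers stay
#'   recognizable homologs on branches far beyond 0.3.
#' @param decoy_count Number of non-family decoy transcripts (and of
#'   decoy proteins in the annotated database).
#' @param truncation_fraction Range of the sequence fraction removed from
#'   a truncated isoform (default `c(0.3, 0.5)`).
#' @param truncated_isoform_share Fraction of isoforms that are
#'   truncations rather than full-length copies.
#' @param motif_grammar Named list: clade -> ordered motif ids. Default:
#'   one shared motif followed by two clade-specific motifs.
#' @param motif_width Planted motif width in residues.
#' @param expression_dynamic_range Ratio of the designated strongest
#'   stage's mean FPKM to background (default 10).
#' @param background_fpkm Background mean FPKM (default 2.0).
#' @param fpkm_noise_sd Log-normal sigma of multiplicative FPKM noise
#'   (default 0.3).
#' @param protein_length Full-length protein size in residues (default
#'   450, the scale of a 12-transmembrane MFS transporter; the sampling
#'   noise of branch-length estimates shrinks as 1/sqrt(length), which
#'   the 0.1 related-branch bound relies on).
#' @param refs_per_clade Labeled reference proteins per clade.
#' @param revcomp_fraction Fraction of transcripts emitted on the reverse
#'   strand.
#' @param orthogroup_splits Named integer vector: clade -> number of
#'   orthogroups it is split into (default: one orthogroup per clade).
#'   Genes of a split clade share a designated strongest stage per
#'   orthogroup.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_clades = 4L,
                         genes_per_clade_per_species = 2L,
                         species_masks = NULL,
                         isoform_rate = 0.3,
                         isoform_divergence = 0.004,
                         paralog_divergence = 0.15,
                         inter_clade_divergence = 0.45,
                         outlier_rate = 0.05,
                         outlier_branch_scale = 10,
                         decoy_count = 8L,
                         truncation_fraction = c(0.3, 0.5),
                         truncated_isoform_share = 0.3,
                         motif_grammar = NULL,
                         motif_width = 30L,
                         expression_dynamic_range = 10,
                         background_fpkm = 2.0,
                         fpkm_noise_sd = 0.3,
                         protein_length = 450L,
                         refs_per_clade = 2L,
                         revcomp_fraction = 0.25,
                         orthogroup_splits = integer(0)) {
  if (n_clades < 2L) stop("configuration error: need at least 2 clades")
  if (any(c(genes_per_clade_per_species, decoy_count, refs_per_clade,
            protein_length, motif_width) < 0) ||
      all(genes_per_clade_per_species <= 0)) {
    stop("configuration error: non-positive counts")
  }
  rates <- c(isoform_rate, outlier_rate, revcomp_fraction,
             truncated_isoform_share)
  if (any(rates < 0 | rates > 1)) {
    stop("configuration error: rates must lie in [0, 1]")
  }
  if (!(isoform_divergence < 0.01 && 0.01 < paralog_divergence)) {
    stop("configuration error: need isoform_divergence < 0.01 < ",
         "paralog_divergence")
  }
  if (inter_clade_divergence <= paralog_divergence) {
    stop("configuration error: inter-clade divergence must exceed ",
         "paralog divergence")
  }
  stopifnot(length(truncation_fraction) == 2L,
            truncation_fraction[1] <= truncation_fraction[2],
            all(truncation_fraction > 0), all(truncation_fraction < 1))
  if (is.null(species_masks)) {
    species_masks <- default_stage_masks(c("PaSyn", "ShSyn", "TvSyn"),
                                         has_6_3 = "TvSyn")
  }
  clades <- default_clade_names(n_clades)
  if (is.null(motif_grammar)) {
    motif_grammar <- stats::setNames(lapply(clades, function(cl) {
      c("m_shared", paste0("m_", cl, "_1"), paste0("m_", cl, "_2"))
    }), clades)
  }
  stopifnot(all(names(orthogroup_splits) %in% clades))
  structure(list(
    seed = as.integer(seed), n_clades = as.integer(n_clades),
    genes_per_clade_per_species = genes_per_clade_per_species,
    species_masks = species_masks, clades = clades,
    isoform_rate = isoform_rate,
    isoform_divergence = isoform_divergence,
    paralog_divergence = paralog_divergence,
    inter_clade_divergence = inter_clade_divergence,
    outlier_rate = outlier_rate,
    outlier_branch_scale = outlier_branch_scale,
    decoy_count = as.integer(decoy_count),
    truncation_fraction = truncation_fraction,
    truncated_isoform_share = truncated_isoform_share,
    motif_grammar = motif_grammar, motif_width = as.integer(motif_width),
    expression_dynamic_range = expression_dynamic_range,
    background_fpkm = background_fpkm, fpkm_noise_sd = fpkm_noise_sd,
    protein_length = as.integer(protein_length),
    refs_per_clade = as.integer(refs_per_clade),
    revcomp_fraction = revcomp_fraction,
    orthogroup_splits = orthogroup_splits), class = "synth_config")
}

genes_for_species <- function(config, sp) {
  g <- config$genes_per_clade_per_species
  if (length(g) == 1L && is.null(names(g))) return(as.integer(g))
  if (!sp %in% names(g)) stop("no gene count for species ", sp)
  as.integer(g[[sp]])
}

#' Generate a labeled reference panel
#'
#' Builds, from one family-root protein: clade ancestors separated by the
#' configured inter-clade divergence, `refs_per_clade` labeled reference
#' proteins per clade, one outgroup protein more divergent from every
#' clade than any inter-clade distance, and a decoy protein set for the
#' annotated confirmation database.
#'
#' @param config A [synth_config()] object.
#' @return List with `refs` (named proteins), `labels` (data.frame: id,
#'   family, clade), `outgroup`, `decoy_db`, `clade_ancestors`.
#' @export
generate_reference_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    L <- config$protein_length
    root <- random_protein(L)
    p_clade <- p_for_pairwise(config$inter_clade_divergence)
    ancestors <- stats::setNames(
      vapply(config$clades, function(cl) evolve_protein(root, p_clade),
             character(1)),
      config$clades)
    p_gene <- p_for_pairwise(config$paralog_divergence)
    refs <- character(0)
    labels <- NULL
    for (cl in config$clades) {
      for (r in seq_len(config$refs_per_clade)) {
        id <- sprintf("REF_%s_%d", cl, r)
        refs[id] <- evolve_protein(ancestors[[cl]], p_gene)
        labels <- rbind(labels, data.frame(id = id, family = "FAM",
                                           clade = cl,
                                           stringsAsFactors = FALSE))
      }
    }
    p_out <- p_for_cross(min(0.9, config$inter_clade_divergence + 0.15),
                         p_clade)
    outgroup <- stats::setNames(evolve_protein(root, p_out), "OUTG_1")
    decoy_db <- stats::setNames(
      vapply(seq_len(max(config$decoy_count, 1L)),
             function(i) random_protein(L), character(1)),
      sprintf("DBDECOY_%d", seq_len(max(config$decoy_count, 1L))))
    list(refs = refs, labels = labels, outgroup = outgroup,
         decoy_db = decoy_db, clade_ancestors = ancestors)
  })
}

motif_positions <- function(grammar, full_len, width) {
  k <- length(grammar)
  if (k == 0L) return(NULL)
  span <- full_len - width - 10L
  starts <- if (k == 1L) 5L else
    5L + round((seq_len(k) - 1L) * span / (k - 1L))
  data.frame(motif_id = grammar, start = as.integer(starts),
             stop = as.integer(starts + width - 1L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic transcriptome with a truth table
#'
#' Emits nucleotide transcripts (fixed-codon back-translations of evolved
#' proteins, a fraction on the reverse strand): true genes per clade and
#' species, near-identical isoform copies (some 3'-truncated),
#' fast-evolving outliers, and non-family decoys derived from the decoy
#' database. The truth table records, per transcript, its gene, clade,
#' role, strand, designated strongest stage, motif architecture and
#' orthogroup.
#'
#' @param panel Output of [generate_reference_panel()].
#' @param config The same [synth_config()] object.
#' @return List with `transcripts` (named nucleotide sequences),
#'   `proteins` (their true translations), `truth` (data.frame).
#' @export
generate_transcriptome <- function(panel, config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 1L, {
    L <- config$protein_length
    p_gene <- p_for_pairwise(config$paralog_divergence)
    common_stages <- Reduce(intersect, config$species_masks)
    og_of <- function(cl, g) {
      k <- if (cl %in% names(config$orthogroup_splits))
        config$orthogroup_splits[[cl]] else 1L
      sprintf("OG_%s_%d", cl, ((g - 1L) %% k) + 1L)
    }
    # designated stage per orthogroup of split clades (shared across
    # species), sampled without replacement from the common stages
    og_stage <- list()
    for (cl in names(config$orthogroup_splits)) {
      k <- config$orthogroup_splits[[cl]]
      st <- sample(common_stages, min(k, length(common_stages)))
      for (j in seq_len(k)) {
        og_stage[[sprintf("OG_%s_%d", cl, j)]] <-
          st[((j - 1L) %% length(st)) + 1L]
      }
    }
    transcripts <- character(0)
    proteins <- character(0)
    truth <- NULL
    add_row <- function(id, species, clade, role, true_gene, strand,
                        stage, arch, og, len_aa) {
      rbind(truth, data.frame(
        transcript_id = id, species = species,
        true_clade = if (is.na(clade)) NA_character_ else clade,
        role = role, true_gene = true_gene, strand = strand,
        true_strongest_stage = stage,
        true_motif_architecture = arch, true_orthogroup = og,
        length_aa = len_aa, stringsAsFactors = FALSE))
    }
    emit <- function(protein) {
      nt <- back_translate(protein)
      strand <- if (stats::runif(1) < config$revcomp_fraction) "-" else "+"
      list(nt = if (strand == "-") revcomp(nt) else nt, strand = strand)
    }
    arch_string <- function(grammar, len_aa) {
      pos <- motif_positions(grammar, L, config$motif_width)
      if (is.null(pos)) return("")
      paste(pos$motif_id[pos$stop <= len_aa], collapse = ",")
    }
    n_genes_total <- 0L
    for (sp in names(config$species_masks)) {
      mask <- config$species_masks[[sp]]
      for (cl in config$clades) {
        n_g <- genes_for_species(config, sp)
        for (g in seq_len(n_g)) {
          n_genes_total <- n_genes_total + 1L
          gid <- sprintf("%s_%s_g%d", sp, cl, g)
          prot <- evolve_protein(panel$clade_ancestors[[cl]], p_gene)
          og <- og_of(cl, g)
          stage <- if (!is.null(og_stage[[og]])) og_stage[[og]] else
            sample(mask, 1L)
          tr <- emit(prot)
          transcripts[gid] <- tr$nt
          proteins[gid] <- prot
          truth <- add_row(gid, sp, cl, "gene", gid, tr$strand, stage,
                           arch_string(config$motif_grammar[[cl]], L),
                           og, L)
          if (stats::runif(1) < config$isoform_rate) {
            iid <- paste0(gid, "_i1")
            n_sub <- max(1L, round(config$isoform_divergence * L))
            iso <- mutate_exact(prot, n_sub)
            if (stats::runif(1) < config$truncated_isoform_share) {
              cut <- stats::runif(1, config$truncation_fraction[1],
                                  config$truncation_fraction[2])
              keep_aa <- max(config$motif_width + 6L,
                             floor(L * (1 - cut)))
              iso <- substr(iso, 1L, keep_aa)
            }
            tr_i <- emit(iso)
            transcripts[iid] <- tr_i$nt
            proteins[iid] <- iso
            truth <- add_row(iid, sp, cl, "isoform", gid, tr_i$strand,
                             stage,
                             arch_string(config$motif_grammar[[cl]],
                                         nchar(iso)),
                             og, nchar(iso))
          }
        }
      }
    }
    n_outliers <- round(config$outlier_rate * n_genes_total)
    if (n_outliers > 0L) {
      sps <- names(config$species_masks)
      for (o in seq_len(n_outliers)) {
        sp <- sps[((o - 1L) %% length(sps)) + 1L]
        cl <- sample(config$clades, 1L)
        oid <- sprintf("%s_outlier%d", sp, o)
        # outlier lineages carry scale-times the substitution events of a
        # normal gene branch; multiple hits saturate the observed
        # divergence (20-state Poisson correction), keeping outliers
        # recognizably homologous while far beyond the 0.3 branch rule
        d_events <- config$outlier_branch_scale * p_gene
        p_out <- (19 / 20) * (1 - exp(-(20 / 19) * d_events))
        prot <- evolve_protein(panel$clade_ancestors[[cl]], p_out)
        tr <- emit(prot)
        transcripts[oid] <- tr$nt
        proteins[oid] <- prot
        truth <- add_row(oid, sp, cl, "outlier", oid, tr$strand,
                         NA_character_, "", NA_character_, L)
      }
    }
    if (config$decoy_count > 0L) {
      sps <- names(config$species_masks)
      for (d in seq_len(config$decoy_count)) {
        sp <- sps[((d - 1L) %% length(sps)) + 1L]
        did <- sprintf("%s_decoy%d", sp, d)
        prot <- evolve_protein(panel$decoy_db[[((d - 1L) %%
          length(panel$decoy_db)) + 1L]], 0.05)
        tr <- emit(prot)
        transcripts[did] <- tr$nt
        proteins[did] <- prot
        truth <- add_row(did, sp, NA_character_, "decoy",
                         NA_character_, tr$strand, NA_character_, "",
                         NA_character_, L)
      }
    }
    rownames(truth) <- NULL
    list(transcripts = transcripts, proteins = proteins, truth = truth)
  })
}

#' Generate a per-isoform FPKM table
#'
#' For each gene, a gene-level profile is drawn (log-normal multiplicative
#' noise around stage means; the designated strongest stage's mean is
#' `expression_dynamic_range` times background) and split across the
#' gene's transcripts by fixed random usage weights, so gene-level values
#' are exactly the sum of their isoform rows. Outlier and decoy
#' transcripts receive background-only profiles. Stages outside a
#' species' mask are omitted.
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @param config The same [synth_config()] object.
#' @return data.frame with columns `sequence_id`, `species`, `stage`,
#'   `fpkm`.
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  empty <- data.frame(sequence_id = character(), species = character(),
                      stage = character(), fpkm = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(truth) || nrow(truth) == 0L) return(empty)
  with_seed(config$seed + 2L, {
    rows <- list()
    units <- split(truth, ifelse(is.na(truth$true_gene),
                                 truth$transcript_id, truth$true_gene))
    for (u in units) {
      sp <- u$species[1]
      mask <- config$species_masks[[sp]]
      designated <- u$true_strongest_stage[1]
      means <- ifelse(!is.na(designated) & mask == designated,
                      config$background_fpkm *
                        config$expression_dynamic_range,
                      config$background_fpkm)
      gene_vals <- means *
        exp(stats::rnorm(length(mask), 0, config$fpkm_noise_sd))
      w <- stats::rexp(nrow(u))
      w <- w / sum(w)
      for (i in seq_len(nrow(u))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = u$transcript_id[i], species = sp, stage = mask,
          fpkm = w[i] * gene_vals, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$sequence_id, match(out$stage, stage_set())), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a motif-hit table from the truth table
#'
#' Emits one hit row per planted motif occurrence, with 1-based inclusive
#' coordinates at the deterministic planted positions (evenly spaced
#' along the full-length protein; truncated isoforms keep the motifs that
#' still fit, so their architecture is a prefix of the parent's).
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @param config The same [synth_config()] object.
#' @return data.frame with columns `sequence_id`, `motif_id`, `start`,
#'   `stop`.
#' @export
generate_motif_hits <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    arch <- truth$true_motif_architecture[i]
    if (is.na(arch) || arch == "") next
    cl <- truth$true_clade[i]
    pos <- motif_positions(config$motif_grammar[[cl]],
                           config$protein_length, config$motif_width)
    pos <- pos[pos$motif_id %in% strsplit(arch, ",")[[1]], , drop = FALSE]
    if (!nrow(pos)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence_id = truth$transcript_id[i], motif_id = pos$motif_id,
      start = pos$start, stop = pos$stop, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(), motif_id = character(),
               start = integer(), stop = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate an orthogroup membership table from the truth table
#'
#' One row per gene or isoform transcript, carrying its true orthogroup
#' (orthogroups refine clades; a clade may be split into several
#' orthogroups via `orthogroup_splits`).
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @return data.frame with columns `sequence_id`, `orthogroup_id`.
#' @export
generate_orthogroups <- function(truth) {
  keep <- !is.na(truth$true_orthogroup)
  out <- data.frame(sequence_id = truth$transcript_id[keep],
                    orthogroup_id = truth$true_orthogroup[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
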