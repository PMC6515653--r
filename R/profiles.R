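#' The ordered developmental stage set
#'
#' Stage ids for the parasite life cycle: 0 germination, 1-2 radicle
#' elongation and haustorial differentiation, 3 host attachment, 4.x
#' vascular connection, 5.1/5.2 pre-emergent root and shoot growth,
#' 6.1 post-emergent growth, 6.2 reproduction, 6.3 further floral
#' maturation (present only in some species).
#'
#' @return Character vector of stage ids in fixed order.
#' @export
stage_set <- function() {
  c("0", "1", "2", "3", "4.1", "4.2", "5.1", "5.2", "6.1", "6.2", "6.3")
}

#' Canonicalize stage id spelling
#'
#' Accepts hyphen and en-dash forms (`"6-2"`, `"6–2"`) and returns the
#' dotted canonical form (`"6.2"`).
#'
#' @param x Character vector of stage ids.
#' @return Canonical stage ids.
#' @export
normalize_stage <- function(x) {
  gsub("(?<=[0-9])[–-](?=[0-9])", ".", x, perl = TRUE)
}

#' Default per-species stage availability masks
#'
#' All stages through 6.2 are available to every species; stage 6.3 only
#' to species flagged in `has_6_3` (in the published system only
#' Triphysaria reaches that stage).
#'
#' @param species Character vector of species ids.
#' @param has_6_3 Species ids whose mask includes stage 6.3.
#' @return Named list: species -> character vector of available stages.
#' @export
default_stage_masks <- function(species, has_6_3 = character(0)) {
  base <- setdiff(stage_set(), "6.3")
  masks <- lapply(species, function(sp) {
    if (sp %in% has_6_3) stage_set() else base
  })
  stats::setNames(masks, species)
}

#' Aggregate isoform FPKM to gene level
#'
#' Sums per-isoform FPKM within each gene at every stage; every isoform
#' must be mapped to a gene.
#'
#' @param expr data.frame with columns `sequence_id`, `species`, `stage`,
#'   `fpkm` (stages absent for a species are simply not present as rows).
#' @param isoform_map Named character vector: sequence id -> gene id
#'   (representatives map to themselves).
#' @return data.frame with columns `gene_id`, `species`, `stage`, `fpkm`.
#' @export
gene_fpkm <- function(expr, isoform_map) {
  stopifnot(all(c("sequence_id", "species", "stage", "fpkm") %in%
                  names(expr)))
  if (nrow(expr) == 0L) {
    return(data.frame(gene_id = character(), species = character(),
                      stage = character(), fpkm = numeric(),
                      stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(expr$sequence_id), names(isoform_map))
  if (length(unknown)) {
    stop("sequence id(s) with no gene mapping: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (any(expr$fpkm < 0)) stop("negative FPKM value")
  gene <- unname(isoform_map[expr$sequence_id])
  stage <- normalize_stage(as.character(expr$stage))
  agg <- stats::aggregate(expr$fpkm,
                          by = list(gene_id = gene,
                                    species = expr$species,
                                    stage = stage),
                          FUN = sum)
  names(agg)[4] <- "fpkm"
  ord <- order(agg$gene_id, match(agg$stage, stage_set()))
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Stage of strongest expression for one gene
#'
#' Argmax of FPKM over the stages available to the gene's species; ties
#' break to the earliest stage in the fixed stage order; an all-zero (or
#' empty) profile returns `"none"`.
#'
#' @param values Named numeric vector of FPKM by stage id.
#' @param mask Character vector of available stages (non-empty).
#' @return A stage id or `"none"`.
#' @export
strongest_stage <- function(values, mask) {
  if (length(mask) == 0L) stop("empty stage mask")
  stages <- intersect(stage_set(), mask)
  v <- values[stages]
  v[is.na(v)] <- 0
  if (all(v == 0)) return("none")
  stages[which.max(v)]
}

#' Stage-of-strongest-expression calls for a gene table
#'
#' @param gene_table Gene-level table from [gene_fpkm()].
#' @param masks Stage masks from [default_stage_masks()] (or equivalent).
#' @return data.frame with columns `gene_id`, `species`, `stage` (id or
#'   `"none"`).
#' @export
stage_calls <- function(gene_table, masks) {
  if (nrow(gene_table) == 0L) {
    return(data.frame(gene_id = character(), species = character(),
                      stage = character(), stringsAsFactors = FALSE))
  }
  keys <- unique(gene_table[, c("gene_id", "species")])
  calls <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- gene_table[gene_table$gene_id == keys$gene_id[i] &
                        gene_table$species == keys$species[i], ,
                      drop = FALSE]
    v <- stats::setNames(sub$fpkm, sub$stage)
    mask <- masks[[keys$species[i]]]
    if (is.null(mask)) stop("no stage mask for species ", keys$species[i])
    calls[i] <- strongest_stage(v, mask)
  }
  data.frame(gene_id = keys$gene_id, species = keys$species,
             stage = calls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Clade-by-stage summary of strongest-expression calls
#'
#' Counts genes per (species, clade, stage of strongest expression);
#' genes with call `"none"` are excluded from the matrix and reported
#' separately.
#'
#' @param assignments data.frame with columns `id`, `species`, `clade`.
#' @param calls Stage calls from [stage_calls()] (gene ids match
#'   assignment ids).
#' @return List with `summary` (long data.frame: species, clade, stage,
#'   n) and `no_call` (data.frame of genes with call `"none"`).
#' @export
clade_stage_summary <- function(assignments, calls) {
  merged <- merge(calls, assignments[, c("id", "clade")],
                  by.x = "gene_id", by.y = "id")
  no_call <- merged[merged$stage == "none", , drop = FALSE]
  ok <- merged[merged$stage != "none", , drop = FALSE]
  if (nrow(ok)) {
    agg <- stats::aggregate(rep(1L, nrow(ok)),
                            by = list(species = ok$species,
                                      clade = ok$clade,
                                      stage = ok$stage),
                            FUN = sum)
    names(agg)[4] <- "n"
    agg <- agg[order(agg$species, agg$clade,
                     match(agg$stage, stage_set())), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(species = character(), clade = character(),
                      stage = character(), n = integer(),
                      stringsAsFactors = FALSE)
  }
  list(summary = agg, no_call = no_call)
}

#' Export per-leaf stage annotations for tree viewers
#'
#' One row per tree leaf with FPKM values in fixed stage order; stages
#' masked out for the leaf's species are emitted as a sentinel token
#' (masked is not the same as zero). Leaves without expression data get a
#' sentinel-only row with a warning.
#'
#' @param gene_table Gene-level table from [gene_fpkm()].
#' @param tree An [ape::phylo] tree whose tips are gene ids.
#' @param species_map Named character vector: gene id -> species.
#' @param masks Stage masks (see [default_stage_masks()]).
#' @param sentinel Token for unavailable stages (default `"-"`).
#' @return data.frame with column `id` then one column per stage.
#' @export
export_heatmap_annotations <- function(gene_table, tree, species_map,
                                       masks, sentinel = "-") {
  stages <- stage_set()
  out <- data.frame(id = tree$tip.label, stringsAsFactors = FALSE)
  for (s in stages) out[[s]] <- sentinel
  missing_leaves <- character(0)
  for (i in seq_along(tree$tip.label)) {
    leaf <- tree$tip.label[i]
    sub <- gene_table[gene_table$gene_id == leaf, , drop = FALSE]
    if (nrow(sub) == 0L) {
      missing_leaves <- c(missing_leaves, leaf)
      next
    }
    sp <- species_map[[leaf]]
    mask <- if (!is.null(sp) && sp %in% names(masks)) masks[[sp]] else
      stages
    for (s in intersect(stages, mask)) {
      v <- sub$fpkm[sub$stage == s]
      out[i, s] <- if (length(v)) format(v[1], digits = 6) else "0"
    }
  }
  if (length(missing_leaves)) {
    warning("no expression data for leaf/leaves: ",
            paste(utils::head(missing_leaves, 5L), collapse = ", "))
  }
  out
}
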