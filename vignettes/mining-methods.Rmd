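---
title: "Phylogeny-driven mining of transporter families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-driven mining of transporter families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomine)
```

## The problem

De novo transcriptome assemblies of non-model plants — here, parasitic
plants whose sugar metabolism is of particular interest — contain the
expressed members of large transporter superfamilies (the monosaccharide
transporters MST, sucrose transporters SUT, and SWEETs), but buried
among assembly isoforms, truncated contigs, chimeric or fast-evolving
artifacts, and unrelated genes. phylomine implements a reproducible
version of the mining workflow such studies use: screen the assembly for
candidates by translated homology, curate the candidate set on
neighbor-joining phylograms until isoforms and artifacts are gone,
classify the survivors against labeled reference anchors, count them per
species and clade, and summarize their life-cycle expression and
motif/orthogroup structure.

Every stage is a plain R function with a documented contract, so each
rule — an E-value cutoff, a branch-length threshold, a rounding
convention — is visible and testable rather than folded into manual
inspection.

## Screening

Transcripts are translated in all six reading frames (codons containing
`N` become `X`; stops become `*` and score prohibitively against every
residue, so alignments cannot read through them). Each frame is aligned
against every bait protein with a full Smith–Waterman affine-gap
alignment; a gap of length $L$ costs `gap_open` $+ L\cdot$`gap_ext`
(defaults 11/1 with BLOSUM62). We deliberately do not reproduce the
k-tuple heuristics of the classic FASTA-style search programs: at the
scale of one gene family against one transcriptome, the exact algorithm
is affordable and strictly more sensitive, and the downstream filter is
defined on E-values, not on search heuristics.

Expectation values use the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with fixed per-matrix parameters
($K = 0.041$, $\lambda = 0.267$ for gapped BLOSUM62 — the conventional
values) and raw sequence lengths for $m$ and $n$, with no edge-effect
correction. Fixing $K$ and $\lambda$ rather than estimating them keeps
E-values reproducible bit-for-bit; the screening logic only needs a
consistent, monotone score-to-E mapping. A transcript is kept when its
best hit reaches $E \le 10^{-3}$, with the boundary value kept.

Confirmation re-aligns each candidate against an annotated database
containing both family and non-family proteins; a candidate survives
only if its single best match is family-labeled (the top 50 matches per
query are retained for audit).

## Alignment and trimming

The built-in aligner is progressive: a UPGMA guide tree on k-mer
distances (one minus the multiset Jaccard similarity of 3-mer spectra),
then profile–profile merges under the same affine gap model, scoring
column pairs by the expected substitution score between the columns'
residue frequency profiles. This is a deliberate simplification of
consistency-based aligners; any externally computed alignment can be
substituted wherever an alignment is consumed, since alignments are
plain named character vectors.

Trimming applies two published rules in a fixed order within each
cycle: drop columns with non-gap occupancy strictly below 10%, then
drop rows covering strictly less than 50% of the remaining columns
(both boundary values are retained — "less than" is taken literally).
Align–trim cycles repeat until no row is removed; the result is a
fixpoint, and re-running on the survivors changes nothing.

## Trees

Distances are uncorrected p-distances. The curation default counts a
gap aligned to a residue as a difference ("no gap exclusion" in the
original tooling's terms); columns where both rows are gapped carry no
signal for that pair and are ignored. Pairwise deletion is available as
a flag; the two modes genuinely differ for truncated sequences, which
is exploited below.

Neighbor joining is the canonical algorithm with two determinism
guarantees: Q-matrix ties break to the lexicographically smallest pair
of cluster representative ids, and negative branch-length estimates are
clamped to zero (the curation thresholds are meaningless on negative
lengths). On additive matrices the implementation is exact to floating
point (property-tested against random trees, and cross-checked against
an independent NJ implementation). Bootstrap supports are bipartition
frequencies over column-resampled replicates, seeded and reproducible.
Rooting places the root on the edge separating a designated outgroup;
if the outgroup is not monophyletic the tree falls back to midpoint
rooting with a warning.

## Curation

Each iteration runs: redundancy removal (exact duplicates and exact
substrings; the longer sequence survives, ties to the smaller id) —
align–trim to the coverage fixpoint — NJ tree on gaps-as-difference
p-distances — long-branch outlier removal — isoform collapsing. The
loop repeats until an iteration removes nothing (a fixpoint), with a
default cap of 10 iterations; hitting the cap flags the result.

**Long branches.** A leaf is an outlier when its pendant branch exceeds
0.3 while every terminal branch in its neighborhood is below 0.1.
"Related branches" is operationalized as the terminal branches of
leaves within two internal nodes — narrow enough to be local, wide
enough to exist for cherries; the radius is configurable. Outgroup
pendant branches never count as context (the published rule concerns
non-outgroup branches); if excluding them empties the neighborhood the
radius expands until family context is found. Where the original
workflow manually re-curated long-branch sequences with external
annotation before deciding, this package removes them automatically and
records each in the ledger — manual rescue is outside automatable
scope.

**Isoforms.** Leaf pairs at patristic distance below 0.01 whose motif
architectures are compatible (one a prefix of the other, or exact,
configurable) join an isoform group; groups are connected components of
this graph, and the longest member survives (ties to the smaller id).
Path distance on the phylogram, rather than raw p-distance, implements
"short distances on the tree"; a flag switches to pendant-sum distance.

A truncated isoform needs special handling: with gaps counted as
differences, a transcript missing 40% of its tail sits at tree distance
roughly 0.4 from its parent — far beyond 0.01 — yet it is exactly the
kind of sequence the original workflow recognized by its shortness and
its motif architecture. The package automates that judgment: a strictly
shorter sequence whose architecture is a strict prefix of its partner's
is collapsed when the two agree over their shared aligned region
(pairwise-deletion distance below the same 0.01). Isoform evidence is
gathered before outlier removal in each iteration, because a truncated
isoform can also sit on a long branch, and isoform identity trumps the
outlier call.

The ledger records every removal with its reason (`duplicate`,
`isoform_of:<id>`, `long_branch_outlier`, `low_coverage`) and the
iteration; input count always equals representatives plus ledger rows.
A truncated isoform whose point mutations happen to fall in the removed
tail is an exact substring of its parent and is taken out by redundancy
removal — the ledger then says `duplicate`, which is the same scientific
outcome reached one step earlier.

## Classification and census

Clades are assigned on the rooted tree from labeled reference anchors:
the smallest ancestral clade containing at least one reference gives
the query its label if those references agree (method `monophyletic`);
otherwise the nearest reference by patristic distance decides (method
`nearest`, ties to the lexicographically smaller label and flagged).
The original study assigned clades by visual tree inspection; the
monophyletic-then-nearest rule is the automated stand-in, and each
assignment records its method for audit.

The census tabulates representatives per species and clade, with
percentages of the species' family total computed half-up to two
decimals — the convention that reproduces every percentage in the
published family-size table (base R's `round` is half-to-even and does
not). Unassigned sequences are reported separately and excluded from
percentage denominators. The pGLT clade and its SGB sub-clade are
reported as one label, as the published table groups them. For display,
clades whose mean internal branch length falls below 0.025 can be
collapsed to marker leaves with a sidecar listing; marker leaves are
never re-collapsed, making the operation idempotent.

## Expression profiles

FPKM is consumed, never computed: per-isoform values are summed into
gene-level values using the curation ledger's isoform map, exactly
(conservation is asserted, not approximated). A gene's stage of
strongest expression is the argmax over the stages available to its
species; ties break to the earliest stage in the fixed order
0, 1, 2, 3, 4.1, 4.2, 5.1, 5.2, 6.1, 6.2, 6.3; an all-zero profile
gets no call. A stage missing from a species' mask is not zero
expression — masks are carried through every summary, and exported
annotation rows emit a sentinel token for masked stages. Dotted stage
ids are canonical; hyphen and en-dash spellings are accepted on input.

## Motifs and orthogroups

Motif discovery and orthology clustering are external, pluggable
stages: the package consumes a hit table (sequence, motif, 1-based
inclusive coordinates) and a membership table. Architectures are hits
ordered by start (ties by motif id). Association tables report, per
motif, the modal clade/stage/species by raw occurrence count, its
percentage of the motif's occurrences, and an exclusivity flag;
"strongly represented" is operationalized as a configurable modal
percentage (default 75%), since no published number exists.
Orthogroup-by-clade cross-tabs flag orthogroups spanning clades and
clades split across orthogroups; per-orthogroup stage preference is the
modal strongest-stage call with the same tie rule. No significance
testing is attached — the published analysis reports counts and
percentages, and so does the package.

## The synthetic generator

The generator exists so the whole pipeline can be validated against a
machine-readable truth table. It emulates the statistical structure the
curation rules assume, not the biology of any particular data set:

* **Sequence evolution** is i.i.d. per-site substitution under a
  uniform replacement kernel — the simplest model satisfying the
  separation the thresholds require. Branch substitution probabilities
  are calibrated so that expected pairwise divergences hit their
  targets exactly: clade ancestors at 0.45, within-clade paralogs at
  0.15, the outgroup beyond any inter-clade distance.
* **Isoform copies** receive a fixed substitution count
  (`round(0.004 × length)` at distinct random sites) rather than
  per-site Bernoulli draws: with 450-residue proteins a Bernoulli model
  would put a nontrivial fraction of isoforms above the 0.01 grouping
  threshold by sampling noise alone, destroying the separation the
  curation rules rely on. A configurable share of isoforms is
  additionally 3'-truncated by 30–50% of the coding region, so their
  architectures are prefixes of their parents'.
* **Outliers** carry `outlier_branch_scale` (default 10) times the
  substitution events of a normal gene branch, converted to an observed
  divergence through a 20-state Poisson multiple-hit correction
  ($p_{obs} = \tfrac{19}{20}(1 - e^{-\tfrac{20}{19} d})$). Without the
  correction a 10× branch saturates near random-sequence divergence and
  legitimately fails the homology screen — a contaminant, not an
  outlier. One outlier is planted per run at the default rate (0.05 of
  gene count): mutually adjacent fast-evolving sequences shield each
  other from the local related-branch rule by construction, a situation
  the original workflow resolved manually.
* **Decoys** are near-copies of unrelated proteins that also sit in the
  annotated confirmation database, emulating non-family genes present
  in both the assembly and the annotation source.
* **Proteins are 450 residues** — the scale of a 12-transmembrane MFS
  transporter. Length matters beyond realism: branch-length sampling
  noise shrinks as $1/\sqrt{L}$, and at 300 residues a normal gene
  pendant branch (expectation ≈ 0.075) crosses the 0.1 related-branch
  bound often enough by chance to defeat the long-branch rule in a way
  full-length transporter data does not.
* **Expression** draws a gene-level profile with log-normal
  multiplicative noise (σ = 0.3) around stage means — background 2.0
  FPKM, the designated strongest stage 10× that — and splits it across
  the gene's transcripts by fixed random usage weights, so gene sums are
  conserved exactly by construction. Stage masks default to the
  published species pattern (only the Triphysaria-like species reaches
  stage 6.3). The noise structure and dynamic range are free parameters
  of the generator, not claims about any real data set.
* **Orthogroups** refine clades; a clade can be split into several
  orthogroups whose genes share a designated stage, supporting the
  published observation of multi-orthogroup clades with stage-divergent
  members.
* **Determinism**: one integer seed fixes every output byte.

Default problem sizes (3 species × 4 clades × 2 genes, one outlier,
8 decoys, ~30% isoform rate) were chosen as the smallest configuration
in which every rule of the pipeline is exercised with realistic
statistical margins; validation studies in the test suite run 20 such
seeds.

What passing synthetic tests does **not** show: robustness to
alignment-degrading domain shuffling, chimeric contigs, rate
heterogeneity across sites, compositional bias, or assembly fragment
distributions — none of which the generator emulates. Results on real
assemblies still require the audit trail (ledger, per-iteration trees,
top-hit tables) the pipeline writes.

## Numerical choices and degenerate inputs

* Scores are floating-point throughout; NJ branch lengths survive a
  text round-trip at 15 significant digits.
* Empty transcripts translate to six empty frames; empty alignments and
  empty truth tables produce empty outputs rather than errors; a family
  whose every row fails coverage is a named error ("degenerate
  family").
* Tie-breaks are deterministic everywhere (lexicographic ids for NJ
  joins, duplicates and isoform representatives; earliest fixed-order
  stage; smallest label for nearest-anchor ties) so identical inputs
  give identical bytes.
* The iteration cap (10) exists for pathological inputs; on generated
  data the loop converges in 2–3 iterations.

## Known limitations

* The built-in progressive aligner trades accuracy for simplicity; for
  publication-grade trees an external alignment should be imported.
* The long-branch rule inherits the brittleness of its published
  thresholds: a neighborhood branch at exactly 0.10 vetoes an outlier
  call, and sampling noise occasionally produces one.
* Maximum-likelihood tree inference and model selection are out of
  scope; external ML trees can be imported as Newick wherever a tree is
  consumed.
* Isoform/outlier semantics target de novo transcriptome artifacts;
  genome-annotated inputs mostly bypass those rules.
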