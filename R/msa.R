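#' Remove gap characters from aligned sequences
#' @param x Character vector of (possibly gapped) sequences.
#' @return Character vector without `-` characters.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

as_char_matrix <- function(aln) {
  stopifnot(length(aln) >= 1L)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (L == 0L) return(matrix(character(0), nrow = length(aln), ncol = 0,
                             dimnames = list(names(aln), NULL)))
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

collapse_rows <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) out <- rep("", nrow(m))
  names(out) <- rownames(m)
  out
}

#' k-mer distance between two sequences
#'
#' One minus the multiset Jaccard similarity of the two sequences' k-mer
#' spectra; used for guide-tree construction. 0 iff the k-mer multisets are
#' identical, 1 when no k-mer is shared.
#'
#' @param a,b Sequences (single strings), each at least `k` long.
#' @param k Word length (default 3).
#' @return Distance in \[0, 1\].
#' @export
kmer_distance <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k) {
    stop("sequences must be at least k = ", k, " residues long")
  }
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  ta <- table(kmers(a))
  tb <- table(kmers(b))
  keys <- union(names(ta), names(tb))
  ca <- as.numeric(ta[keys]); ca[is.na(ca)] <- 0
  cb <- as.numeric(tb[keys]); cb[is.na(cb)] <- 0
  1 - sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

profile_of <- function(m, alphabet) {
  P <- matrix(0, nrow = length(alphabet), ncol = ncol(m),
              dimnames = list(alphabet, NULL))
  nr <- nrow(m)
  for (a in alphabet) P[a, ] <- colSums(m == a) / nr
  P
}

#' Progressive multiple sequence alignment
#'
#' Built-in progressive aligner: UPGMA guide tree on k-mer distances,
#' profile-profile merges under an affine gap model with expected
#' substitution scores between columns. Deterministic for a fixed input
#' order and parameters. An externally produced alignment (e.g. from a
#' dedicated MSA tool) can be substituted anywhere an alignment is
#' consumed.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param matrix Substitution matrix name or matrix.
#' @param gap_open,gap_ext Affine gap penalties.
#' @param k Word length for guide-tree distances.
#' @return Named character vector of gapped rows (equal lengths), in the
#'   input order.
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62", gap_open = 10,
                              gap_ext = 1, k = 3L) {
  if (length(seqs) == 0L) stop("no sequences to align")
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  submat <- substitution_matrix(matrix)
  alphabet <- rownames(submat)
  k_eff <- max(1L, min(k, min(nchar(seqs))))
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k_eff)
  }
  merge_order <- stats::hclust(stats::as.dist(D), method = "average")$merge
  blocks <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[[i]], "", fixed = TRUE)[[1]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", nrow(merge_order))
  get_block <- function(id) if (id < 0L) blocks[[-id]] else merged[[id]]
  for (s in seq_len(nrow(merge_order))) {
    b1 <- get_block(merge_order[s, 1])
    b2 <- get_block(merge_order[s, 2])
    P1 <- profile_of(b1, alphabet)
    P2 <- profile_of(b2, alphabet)
    S <- crossprod(P1, submat %*% P2)
    path <- nw_profile_path_cpp(S, gap_open, gap_ext)
    L <- length(path)
    out <- matrix("-", nrow = nrow(b1) + nrow(b2), ncol = L,
                  dimnames = list(c(rownames(b1), rownames(b2)), NULL))
    i1 <- cumsum(path != 3L)
    i2 <- cumsum(path != 2L)
    take1 <- path != 3L
    take2 <- path != 2L
    out[seq_len(nrow(b1)), take1] <- b1[, i1[take1], drop = FALSE]
    out[nrow(b1) + seq_len(nrow(b2)), take2] <- b2[, i2[take2], drop = FALSE]
    merged[[s]] <- out
  }
  final <- merged[[nrow(merge_order)]]
  final <- final[names(seqs), , drop = FALSE]
  collapse_rows(final)
}

#' Remove low-occupancy alignment columns
#'
#' Drops every column whose non-gap fraction is strictly below
#' `min_occupancy` (the boundary value is retained). Row order is
#' preserved; idempotent.
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param min_occupancy Minimum retained non-gap fraction (default 0.10).
#' @return Trimmed alignment.
#' @export
trim_columns <- function(aln, min_occupancy = 0.10) {
  m <- as_char_matrix(aln)
  if (ncol(m) == 0L) return(aln)
  occ <- colMeans(m != "-")
  collapse_rows(m[, occ >= min_occupancy, drop = FALSE])
}

#' Drop sequences covering too little of the alignment
#'
#' Removes rows whose non-gap fraction of alignment columns is strictly
#' below `min_cov` (a row covering exactly `min_cov` is retained).
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param min_cov Minimum retained coverage (default 0.50).
#' @return List with `alignment` (retained rows) and `removed` (ids).
#' @export
drop_low_coverage <- function(aln, min_cov = 0.50) {
  m <- as_char_matrix(aln)
  if (ncol(m) == 0L) return(list(alignment = aln, removed = character(0)))
  cov <- rowMeans(m != "-")
  keep <- cov >= min_cov
  if (!any(keep)) {
    stop("degenerate family: every sequence covers less than ",
         round(100 * min_cov), "% of the alignment")
  }
  list(alignment = collapse_rows(m[keep, , drop = FALSE]),
       removed = rownames(m)[!keep])
}

#' Align-and-trim to a coverage fixpoint
#'
#' Repeats align -> trim low-occupancy columns -> drop low-coverage rows
#' until no row is removed (columns are evaluated before rows within each
#' cycle). Re-running on the surviving sequences changes nothing.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param min_occupancy,min_cov Trimming thresholds.
#' @param ... Passed to [progressive_align()].
#' @return List with `alignment` (trimmed), `sequences` (surviving inputs),
#'   `removed` (ids dropped for low coverage), `cycles`.
#' @export
align_trim_cycle <- function(seqs, min_occupancy = 0.10, min_cov = 0.50,
                             ...) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  removed_all <- character(0)
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    aln <- progressive_align(seqs, ...)
    aln <- trim_columns(aln, min_occupancy)
    res <- drop_low_coverage(aln, min_cov)
    if (length(res$removed) == 0L || length(res$alignment) < 2L) {
      return(list(alignment = res$alignment, sequences = seqs,
                  removed = removed_all, cycles = cycles))
    }
    removed_all <- c(removed_all, res$removed)
    seqs <- seqs[setdiff(names(seqs), res$removed)]
  }
}
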