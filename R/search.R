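#' Scoring parameters for translated homology screening
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters used by the screening stage. A gap of length L
#' costs `gap_open + L * gap_ext`. The default K and lambda are the
#' conventional gapped BLOSUM62 values; they are fixed per matrix rather
#' than estimated, so E-values are reproducible bit-for-bit.
#'
#' @param matrix Substitution matrix name (currently `"BLOSUM62"` or
#'   `"BLOSUM50"`, taken from Biostrings) or a numeric matrix with residue
#'   dimnames.
#' @param gap_open Gap opening penalty (>= 0).
#' @param gap_ext Gap extension penalty (>= 0).
#' @param K,lambda Karlin-Altschul parameters (> 0).
#' @param evalue_cutoff Expectation-value cutoff; candidates are kept when
#'   their best E-value is less than or equal to this (default 1e-3).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1,
                           K = 0.041, lambda = 0.267, evalue_cutoff = 1e-3) {
  stopifnot(gap_open >= 0, gap_ext >= 0, K > 0, lambda > 0, evalue_cutoff > 0)
  sm <- substitution_matrix(matrix)
  structure(list(matrix = sm,
                 matrix_name = if (is.character(matrix)) matrix else "custom",
                 gap_open = gap_open, gap_ext = gap_ext,
                 K = K, lambda = lambda, evalue_cutoff = evalue_cutoff),
            class = "scoring_params")
}

# Stop codons must never align through: '*' is given a prohibitive score
# against everything, including itself.
STOP_SCORE <- -1e6

#' Fetch a protein substitution matrix
#'
#' Loads a named matrix from Biostrings and overrides the stop symbol `*`
#' to a prohibitive penalty so that translated frames cannot align through
#' stop codons.
#'
#' @param name Matrix name or a numeric matrix (returned with the stop
#'   override applied if a `*` row exists).
#' @return Numeric matrix with residue dimnames.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) {
    m <- name
  } else {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
  }
  if ("*" %in% rownames(m)) {
    m["*", ] <- STOP_SCORE
    m[, "*"] <- STOP_SCORE
  }
  m
}

encode_protein <- function(x, submat) {
  if (nchar(x) == 0L) return(integer(0))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(submat))
  # unknown residues score through the wildcard row
  idx[is.na(idx)] <- match("X", rownames(submat))
  idx - 1L
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates a transcript in all six reading frames (three forward, three
#' on the reverse complement) under the standard genetic code. Codons
#' containing `N` translate to the unknown-residue symbol `X`; stop codons
#' are rendered as `*`.
#'
#' @param nt A single nucleotide sequence (alphabet ACGTN; case
#'   insensitive).
#' @return A data.frame with columns `frame` (1, 2, 3, -1, -2, -3) and
#'   `protein`.
#' @export
six_frame_translate <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  six_frame_translate_all(nt)[[1]]
}

# vectorized six-frame translation over many transcripts (one Biostrings
# call per frame, not per sequence)
six_frame_translate_all <- function(nts) {
  nts <- toupper(nts)
  bad <- grepl("[^ACGTN]", nts)
  if (any(bad)) {
    stop("illegal nucleotide character in sequence (allowed: A, C, G, T, N)")
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  n <- length(nts)
  prot <- matrix("", nrow = 6L, ncol = n)
  nonempty <- which(nchar(nts) > 0L)
  if (length(nonempty)) {
    fwd <- Biostrings::DNAStringSet(nts[nonempty])
    rev <- Biostrings::reverseComplement(fwd)
    for (o in 0:2) {
      for (strand in 1:2) {
        set <- if (strand == 1L) fwd else rev
        widths <- pmax(0L, ((Biostrings::width(set) - o) %/% 3L) * 3L)
        ok <- widths > 0L
        if (!any(ok)) next
        sub <- Biostrings::subseq(set[ok], start = o + 1L,
                                  width = widths[ok])
        tr <- as.character(Biostrings::translate(
          sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
        row <- o + 1L + (strand - 1L) * 3L
        prot[row, nonempty[ok]] <- tr
      }
    }
  }
  out <- lapply(seq_len(n), function(i) {
    data.frame(frame = frames, protein = prot[, i],
               stringsAsFactors = FALSE)
  })
  names(out) <- names(nts)
  out
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw alignment score `S`, query
#' search length `m` and database length `n`. Raw lengths are used with no
#' edge-effect correction.
#'
#' @param score Raw alignment score.
#' @param m Query length (> 0).
#' @param n Database length (> 0).
#' @param params A [scoring_params()] object.
#' @return Expectation value (vectorised over `score`).
#' @export
evalue <- function(score, m, n, params) {
  stopifnot(m > 0, n > 0)
  params$K * m * n * exp(-params$lambda * score)
}

#' Bit score from a raw score
#' @inheritParams evalue
#' @return Bit score.
#' @export
bit_score <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Affine-gap local protein alignment
#'
#' Full Smith-Waterman alignment (no heuristic pre-filtering): the maximum
#' affine-gap local alignment score and its aligned spans. Unknown residues
#' score through the matrix wildcard row; stop symbols are prohibitive.
#'
#' @param query,subject Protein sequences (single strings).
#' @param params A [scoring_params()] object.
#' @return A list with `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive spans; zeros with score 0 when no positive-scoring
#'   alignment exists).
#' @export
local_align <- function(query, subject, params = scoring_params()) {
  qi <- encode_protein(query, params$matrix)
  si <- encode_protein(subject, params$matrix)
  res <- sw_align_cpp(qi, si, params$matrix, params$gap_open, params$gap_ext)
  res$score <- as.numeric(res$score)
  res
}

#' Screen a transcriptome against bait proteins
#'
#' Translates every transcript in six frames, aligns each frame against
#' every bait, and keeps transcripts whose best hit has
#' `E <= evalue_cutoff`. Each candidate carries its best frame's
#' translation for downstream curation.
#'
#' @param transcripts Named character vector of nucleotide sequences.
#' @param baits Named character vector of bait proteins (>= 1).
#' @param params A [scoring_params()] object.
#' @return A data.frame (one row per kept transcript) with columns
#'   `transcript_id`, `frame`, `subject`, `score`, `bits`, `evalue`,
#'   `protein`.
#' @export
screen_transcriptome <- function(transcripts, baits,
                                 params = scoring_params()) {
  stopifnot(length(baits) >= 1L, !is.null(names(baits)))
  n_db <- sum(nchar(baits))
  bait_codes <- lapply(baits, encode_protein, submat = params$matrix)
  frames <- six_frame_translate_all(transcripts)
  all_prot <- unlist(lapply(frames, `[[`, "protein"), use.names = FALSE)
  frame_codes <- lapply(all_prot, encode_protein, submat = params$matrix)
  scores <- sw_score_matrix_cpp(frame_codes, bait_codes, params$matrix,
                                params$gap_open, params$gap_ext)
  rows <- vector("list", length(transcripts))
  for (t in seq_along(transcripts)) {
    fr <- frames[[t]]
    best <- NULL
    for (f in seq_len(nrow(fr))) {
      prot <- fr$protein[f]
      if (nchar(prot) == 0L) next
      m <- nchar(prot)
      sc <- scores[(t - 1L) * 6L + f, ]
      ev <- evalue(sc, m, n_db, params)
      b <- order(ev, -sc, names(baits))[1]
      if (is.null(best) || ev[b] < best$evalue ||
          (ev[b] == best$evalue && sc[b] > best$score)) {
        best <- list(frame = fr$frame[f], subject = names(baits)[b],
                     score = sc[b], evalue = ev[b], protein = prot)
      }
    }
    if (!is.null(best) && best$evalue <= params$evalue_cutoff) {
      rows[[t]] <- data.frame(
        transcript_id = names(transcripts)[t], frame = best$frame,
        subject = best$subject, score = best$score,
        bits = bit_score(best$score, params), evalue = best$evalue,
        protein = best$protein, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), frame = integer(),
                      subject = character(), score = numeric(),
                      bits = numeric(), evalue = numeric(),
                      protein = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Confirm candidates against an annotated protein database
#'
#' Emulates best-match inspection against a mixed database of family and
#' non-family (decoy) proteins: a candidate is confirmed if and only if its
#' single best-scoring match is family-labeled and meets the E-value
#' cutoff. The top-k matches per query are returned for audit.
#'
#' @param candidates Candidate data.frame from [screen_transcriptome()]
#'   (needs `transcript_id` and `protein`).
#' @param db Named character vector of database proteins (non-empty).
#' @param db_families Named character vector mapping database ids to family
#'   labels; ids absent or `NA` are treated as non-family decoys.
#' @param params A [scoring_params()] object.
#' @param k Number of matches listed per query (default 50).
#' @return A list with `confirmed` (subset of `candidates` plus
#'   `best_match`, `best_family`) and `top_hits` (audit table).
#' @export
best_hit_confirm <- function(candidates, db, db_families,
                             params = scoring_params(), k = 50L) {
  if (length(db) == 0L) stop("annotated database is empty")
  n_db <- sum(nchar(db))
  confirmed <- logical(nrow(candidates))
  best_match <- character(nrow(candidates))
  best_family <- character(nrow(candidates))
  audit <- vector("list", nrow(candidates))
  db_codes <- lapply(db, encode_protein, submat = params$matrix)
  cand_codes <- lapply(candidates$protein, encode_protein,
                       submat = params$matrix)
  score_mat <- sw_score_matrix_cpp(cand_codes, db_codes, params$matrix,
                                   params$gap_open, params$gap_ext)
  for (i in seq_len(nrow(candidates))) {
    prot <- candidates$protein[i]
    m <- nchar(prot)
    sc <- stats::setNames(score_mat[i, ], names(db))
    ev <- evalue(sc, m, n_db, params)
    ord <- order(-sc, ev, names(db))
    top <- ord[seq_len(min(k, length(ord)))]
    fam <- db_families[names(db)[top]]
    audit[[i]] <- data.frame(
      transcript_id = candidates$transcript_id[i], rank = seq_along(top),
      subject = names(db)[top], score = sc[top], evalue = ev[top],
      family = ifelse(is.na(fam), "", fam), stringsAsFactors = FALSE)
    b <- ord[1]
    best_match[i] <- names(db)[b]
    bf <- db_families[names(db)[b]]
    best_family[i] <- if (is.na(bf)) "" else bf
    confirmed[i] <- !is.na(bf) && nzchar(bf) &&
      ev[b] <= params$evalue_cutoff
  }
  out <- candidates[confirmed, , drop = FALSE]
  out$best_match <- best_match[confirmed]
  out$best_family <- best_family[confirmed]
  rownames(out) <- NULL
  list(confirmed = out,
       top_hits = if (length(audit)) do.call(rbind, audit) else
         data.frame())
}
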