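# Independent oracles used across the suite. These are deliberately naive
# implementations (enumeration, direct recursion, direct recounting) kept
# separate from the package's own algorithms.

# --- exhaustive affine-gap local alignment -------------------------------
# Best local score = best over all substring pairs of an exhaustive
# enumeration of their global alignments (gap of length L costs
# gap_open + L * gap_ext, matching the package convention).
oracle_global_enum <- function(a, b, submat, gap_open, gap_ext) {
  rec <- function(i, j, state) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      sc <- submat[substr(a, i, i), substr(b, j, j)]
      best <- max(best, sc + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= nchar(a)) {
      cost <- if (state == "ga") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i + 1L, j, "ga"))
    }
    if (j <= nchar(b)) {
      cost <- if (state == "gb") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

oracle_local_align <- function(a, b, submat, gap_open, gap_ext) {
  best <- 0
  for (i1 in seq_len(nchar(a) + 1L) - 1L) {
    for (i2 in i1:nchar(a)) {
      qa <- substr(a, i1 + 1L, i2)
      if (i2 > i1 && nchar(qa) == 0L) next
      for (j1 in seq_len(nchar(b) + 1L) - 1L) {
        for (j2 in j1:nchar(b)) {
          qb <- substr(b, j1 + 1L, j2)
          if (nchar(qa) == 0L && nchar(qb) == 0L) next
          if (nchar(qa) == 0L || nchar(qb) == 0L) next
          best <- max(best, oracle_global_enum(qa, qb, submat,
                                               gap_open, gap_ext))
        }
      }
    }
  }
  best
}

# --- independent codon-table translation --------------------------------
ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  # third base fastest, matching the standard-code string below
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3L * i - 2L, 3L * i)
    out[i] <- if (grepl("N", codon)) "X" else ORACLE_CODONS[[codon]]
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(nt) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(nt, "")[[1]]]), collapse = "")
}

# --- exact three-sequence alignment by 3D dynamic programming -----------
# Sum-of-pairs scoring with linear gap cost: residue/residue from the
# matrix, residue/gap -gap, gap/gap 0.
oracle_align3 <- function(s1, s2, s3, submat, gap) {
  n1 <- nchar(s1); n2 <- nchar(s2); n3 <- nchar(s3)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  c3 <- strsplit(s3, "")[[1]]
  D <- array(-Inf, dim = c(n1 + 1L, n2 + 1L, n3 + 1L))
  D[1, 1, 1] <- 0
  col_score <- function(a, b, cc) {
    pair <- function(x, y) {
      if (is.na(x) && is.na(y)) return(0)
      if (is.na(x) || is.na(y)) return(-gap)
      submat[x, y]
    }
    pair(a, b) + pair(a, cc) + pair(b, cc)
  }
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0L) next
    best <- -Inf
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0L) next
      if (i - di < 0L || j - dj < 0L || k - dk < 0L) next
      prev <- D[i - di + 1L, j - dj + 1L, k - dk + 1L]
      if (!is.finite(prev)) next
      a <- if (di == 1L) c1[i] else NA_character_
      b <- if (dj == 1L) c2[j] else NA_character_
      cc <- if (dk == 1L) c3[k] else NA_character_
      best <- max(best, prev + col_score(a, b, cc))
    }
    D[i + 1L, j + 1L, k + 1L] <- best
  }
  D[n1 + 1L, n2 + 1L, n3 + 1L]
}

# sum-of-pairs score of an existing alignment under the same convention
oracle_sp_score <- function(aln, submat, gap) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  total <- 0
  for (col in seq_len(ncol(m))) {
    v <- m[, col]
    for (i in seq_len(length(v) - 1L)) for (j in seq(i + 1L, length(v))) {
      if (v[i] == "-" && v[j] == "-") next
      total <- total + if (v[i] == "-" || v[j] == "-") -gap else
        submat[v[i], v[j]]
    }
  }
  total
}

# --- tree neighborhoods by direct breadth-first search ------------------
oracle_neighborhood <- function(tree, leaf, k) {
  nt <- length(tree$tip.label)
  edges <- tree$edge
  adj <- list()
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    adj[[a]] <- c(adj[[a]], edges[e, 2])
    adj[[b]] <- c(adj[[b]], edges[e, 1])
  }
  tip <- match(leaf, tree$tip.label)
  parent <- edges[edges[, 2] == tip, 1]
  seen <- stats::setNames(1L, as.character(parent))
  frontier <- parent
  while (length(frontier)) {
    nxt <- integer(0)
    for (node in frontier) {
      d <- seen[[as.character(node)]]
      if (d >= k) next
      for (nb in adj[[as.character(node)]]) {
        if (nb > nt && !(as.character(nb) %in% names(seen))) {
          seen[as.character(nb)] <- d + 1L
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  tips <- integer(0)
  for (node in as.integer(names(seen))) {
    for (nb in adj[[as.character(node)]]) if (nb <= nt) tips <- c(tips, nb)
  }
  tips <- setdiff(unique(tips), tip)
  stats::setNames(
    vapply(tips, function(tp) tree$edge.length[edges[, 2] == tp],
           numeric(1)),
    tree$tip.label[tips])
}

# shared fixture: one small curated synthetic run per seed, computed once
synthetic_runs <- local({
  cache <- new.env(parent = emptyenv())
  function(seeds = 1:20) {
    key <- paste(seeds, collapse = ",")
    if (is.null(cache[[key]])) {
      cache[[key]] <- lapply(seeds, function(sd) {
        run_synthetic_pipeline(synth_config(seed = sd))
      })
    }
    cache[[key]]
  }
})
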