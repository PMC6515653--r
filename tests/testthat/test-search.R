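test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  expect_equal(fr$protein[fr$frame == 1], "MA")

  # trailing bases are dropped
  fr2 <- six_frame_translate("ATGGCCA")
  expect_equal(fr2$protein[fr2$frame == 1], "MA")

  # empty input gives six empty frames; bad characters error
  fr0 <- six_frame_translate("")
  expect_equal(fr0$protein, rep("", 6))
  expect_error(six_frame_translate("ATGU"), "illegal")
})

test_that("six-frame translation matches an independent codon table", {
  set.seed(11)
  for (rep in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    fr <- six_frame_translate(nt)
    rc <- oracle_revcomp(nt)
    for (o in 0:2) {
      expect_equal(fr$protein[fr$frame == o + 1],
                   oracle_translate(substr(nt, o + 1, nchar(nt))))
      expect_equal(fr$protein[fr$frame == -(o + 1)],
                   oracle_translate(substr(rc, o + 1, nchar(rc))))
    }
  }
  # N-containing codons become X
  expect_equal(six_frame_translate("ATGANT")$protein[1], "MX")
})

test_that("local alignment scores self-alignments and empty input", {
  p <- scoring_params()
  sm <- substitution_matrix("BLOSUM62")
  q <- "HEAGAWGHEE"
  al <- local_align(q, q, p)
  chars <- strsplit(q, "")[[1]]
  expect_equal(al$score, sum(diag(sm[chars, chars])))
  expect_equal(c(al$q_start, al$q_end), c(1L, 10L))

  expect_equal(local_align("", "HEAG", p)$score, 0)
  # symmetry for a symmetric matrix
  expect_equal(local_align("WHE", "HEAGAW", p)$score,
               local_align("HEAGAW", "WHE", p)$score)
})

test_that("local alignment equals exhaustive enumeration on small strings", {
  p <- scoring_params(gap_open = 3, gap_ext = 1)
  sm <- p$matrix
  alpha <- c("A", "R", "N")
  strings <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(alpha), k)), 1, paste, collapse = "")
  }))
  for (a in strings) {
    for (b in strings) {
      expect_equal(local_align(a, b, p)$score,
                   oracle_local_align(a, b, sm, 3, 1),
                   info = paste(a, b))
    }
  }
  # longer sampled pairs
  set.seed(7)
  for (rep in 1:12) {
    a <- paste(sample(alpha, sample(4:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(alpha, sample(4:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(local_align(a, b, p)$score,
                 oracle_local_align(a, b, sm, 3, 1),
                 info = paste(a, b))
  }
})

test_that("expectation values follow the Karlin-Altschul form", {
  p <- scoring_params(K = 0.041, lambda = 0.267)
  # zero score: exponent vanishes
  expect_equal(evalue(0, 100, 100, p), 0.041 * 1e4)
  # direct evaluation at S = 30
  expect_equal(evalue(30, 100, 100, p), 0.041 * 1e4 * exp(-8.01),
               tolerance = 1e-12)
  # linear in database size; strictly decreasing in score
  expect_equal(evalue(30, 100, 200, p), 2 * evalue(30, 100, 100, p))
  expect_true(all(diff(evalue(0:50, 100, 100, p)) < 0))
})

test_that("screening keeps hits at the cutoff boundary and is monotone", {
  set.seed(21)
  bait <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E"), 60,
                       replace = TRUE), collapse = "")
  nt_hit <- phylomine:::back_translate(bait)
  nt_junk <- paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
                   collapse = "")
  tx <- c(hit = nt_hit, junk = nt_junk)
  p <- scoring_params()
  kept <- screen_transcriptome(tx, c(b1 = bait), p)
  expect_true("hit" %in% kept$transcript_id)
  expect_equal(kept$frame[kept$transcript_id == "hit"], 1L)

  # boundary: a hit whose E-value equals the cutoff exactly is kept
  score_hit <- kept$score[kept$transcript_id == "hit"]
  e_hit <- kept$evalue[kept$transcript_id == "hit"]
  p_exact <- scoring_params(evalue_cutoff = e_hit)
  kept_exact <- screen_transcriptome(tx, c(b1 = bait), p_exact)
  expect_true("hit" %in% kept_exact$transcript_id)
  # and excluded just below it
  p_below <- scoring_params(evalue_cutoff = e_hit * 0.99)
  expect_false("hit" %in%
                 screen_transcriptome(tx, c(b1 = bait),
                                      p_below)$transcript_id)

  # monotonicity: stricter cutoff keeps a subset
  p4 <- scoring_params(evalue_cutoff = 1e-4)
  kept4 <- screen_transcriptome(tx, c(b1 = bait), p4)
  expect_true(all(kept4$transcript_id %in% kept$transcript_id))
})

test_that("best-hit confirmation removes decoy-matching candidates", {
  set.seed(5)
  fam <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E"), 80,
                      replace = TRUE), collapse = "")
  decoy <- paste(sample(c("G", "H", "I", "L", "K", "M", "F"), 80,
                        replace = TRUE), collapse = "")
  candidates <- data.frame(
    transcript_id = c("t_fam", "t_dec"),
    protein = c(fam, decoy), stringsAsFactors = FALSE)
  db <- c(FAMREF = fam, JUNK = decoy)
  db_fam <- c(FAMREF = "FAM", JUNK = "")
  res <- best_hit_confirm(candidates, db, db_fam, scoring_params(),
                          k = 2)
  expect_equal(res$confirmed$transcript_id, "t_fam")
  expect_equal(res$confirmed$best_family, "FAM")
  # audit lists k matches per query
  expect_equal(nrow(res$top_hits), 4L)
  expect_error(best_hit_confirm(candidates, character(0), db_fam),
               "empty")
})
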