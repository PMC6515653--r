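test_that("architectures order hits by start, ties by motif id", {
  hits <- data.frame(
    sequence_id = c("s1", "s1", "s2", "s2"),
    motif_id = c("m2", "m1", "m3", "m1"),
    start = c(50L, 10L, 5L, 5L), stop = c(70L, 30L, 25L, 25L),
    stringsAsFactors = FALSE)
  arch <- build_architectures(hits, c(s1 = 100L, s2 = 80L, s3 = 60L))
  expect_equal(arch$s1, c("m1", "m2"))
  expect_equal(arch$s2, c("m1", "m3")) # identical starts: id order
  expect_equal(arch$s3, character(0))  # no hits: empty architecture
  # out-of-bounds hit names the sequence
  bad <- data.frame(sequence_id = "s1", motif_id = "m9",
                    start = 90L, stop = 120L, stringsAsFactors = FALSE)
  expect_error(build_architectures(bad, c(s1 = 100L)), "s1")
  expect_error(build_architectures(hits, c(s1 = 100L)), "unknown")
})

test_that("architecture matching distinguishes exact from prefix", {
  expect_true(architecture_match(c("m1", "m2"), c("m1", "m2"), "exact"))
  expect_true(architecture_match(c("m1", "m2"), c("m1", "m2"),
                                 "prefix_or_equal"))
  expect_true(architecture_match("m1", c("m1", "m2"), "prefix_or_equal"))
  expect_false(architecture_match("m1", c("m1", "m2"), "exact"))
  expect_false(architecture_match(c("m1", "m3"), c("m1", "m2"),
                                  "prefix_or_equal"))
  expect_false(architecture_match(c("m1", "m3"), c("m1", "m2"), "exact"))
})

test_that("motif associations report modal group, percent and exclusivity", {
  hits <- data.frame(
    sequence_id = c("p1", "p2", "p3", "q1", "p1"),
    motif_id = c("mA", "mA", "mA", "mA", "mB"),
    start = 1L, stop = 10L, stringsAsFactors = FALSE)
  grp <- c(p1 = "PMT", p2 = "PMT", p3 = "PMT", q1 = "STP")
  res <- motif_association(hits, grp, key = "clade")
  a <- res[res$motif_id == "mA", ]
  expect_equal(a$modal_group, "PMT")
  expect_equal(a$count, 3L)
  expect_equal(a$percent, 75)
  expect_false(a$exclusive)
  b <- res[res$motif_id == "mB", ]
  expect_true(b$exclusive)
  expect_equal(b$percent, 100)
  expect_error(motif_association(hits, grp[-1], "clade"), "grouping key")
})

test_that("per-group motif counts conserve totals on random tables", {
  set.seed(67)
  for (rep in 1:10) {
    n <- 60
    hits <- data.frame(
      sequence_id = sprintf("s%d", sample(1:15, n, replace = TRUE)),
      motif_id = sprintf("m%d", sample(1:6, n, replace = TRUE)),
      start = 1L, stop = 5L, stringsAsFactors = FALSE)
    grp <- stats::setNames(sample(LETTERS[1:4], 15, replace = TRUE),
                           sprintf("s%d", 1:15))
    res <- motif_association(hits, grp, "clade")
    tab <- attr(res, "by_group")
    # conservation: per-motif group counts sum to total occurrences
    for (m in rownames(tab)) {
      expect_equal(sum(tab[m, ]), sum(hits$motif_id == m))
    }
    # percents over groups sum to 100 per motif
    pct <- 100 * tab / rowSums(tab)
    expect_equal(unname(rowSums(pct)), rep(100, nrow(tab)))
    # modal percent matches the table
    for (r in seq_len(nrow(res))) {
      m <- res$motif_id[r]
      expect_equal(res$count[r], max(tab[m, ]))
    }
  }
})

test_that("orthogroup-clade crosstabs flag sharing in both directions", {
  og <- data.frame(
    sequence_id = c("a1", "a2", "b1", "b2", "c1", "c2", "c3"),
    orthogroup_id = c("OG1", "OG1", "OG1", "OG2", "OG3", "OG4", "OG5"),
    stringsAsFactors = FALSE)
  asg <- data.frame(
    id = c("a1", "a2", "b1", "b2", "c1", "c2", "c3", "z9"),
    clade = c("SUT1", "SUT1", "SUT4", "SUT4", "STP", "STP", "STP",
              "STP"), stringsAsFactors = FALSE)
  res <- orthogroup_clade_crosstab(og, asg)
  # OG1 spans SUT1 and SUT4
  f <- res$orthogroup_flags
  expect_true(f$orthogroup_multi_clade[f$orthogroup_id == "OG1"])
  expect_equal(f$n_clades[f$orthogroup_id == "OG1"], 2L)
  # STP members spread over three orthogroups
  cf <- res$clade_flags
  expect_true(cf$clade_multi_orthogroup[cf$clade == "STP"])
  expect_equal(cf$n_orthogroups[cf$clade == "STP"], 3L)
  # assigned sequence without membership is reported
  expect_equal(res$unmatched, "z9")
  # empty membership: empty table, everything unmatched
  res0 <- orthogroup_clade_crosstab(og[0, ], asg)
  expect_equal(nrow(res0$crosstab), 0L)
  expect_equal(sort(res0$unmatched), sort(asg$id))
})

test_that("crosstab marginals equal direct counts on random tables", {
  set.seed(71)
  for (rep in 1:10) {
    ids <- sprintf("s%d", 1:30)
    og <- data.frame(sequence_id = ids,
                     orthogroup_id = sample(sprintf("OG%d", 1:5), 30,
                                            replace = TRUE),
                     stringsAsFactors = FALSE)
    asg <- data.frame(id = ids,
                      clade = sample(c("PMT", "STP", "INT"), 30,
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
    res <- orthogroup_clade_crosstab(og, asg)
    ct <- res$crosstab
    for (o in unique(og$orthogroup_id)) {
      expect_equal(sum(ct$n[ct$orthogroup_id == o]),
                   sum(og$orthogroup_id == o))
    }
    for (cl in unique(asg$clade)) {
      expect_equal(sum(ct$n[ct$clade == cl]), sum(asg$clade == cl))
    }
  }
})

test_that("orthogroup stage preferences take the modal call with tie rule", {
  og <- data.frame(sequence_id = c("a", "b", "c", "d"),
                   orthogroup_id = c("OG1", "OG1", "OG1", "OG2"),
                   stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      stage = c("6.2", "6.2", "6.1", "3"),
                      stringsAsFactors = FALSE)
  res <- orthogroup_stage_preference(og, calls)
  expect_equal(res$modal_stage[res$orthogroup_id == "OG1"], "6.2")
  # singleton orthogroup inherits its member's stage
  expect_equal(res$modal_stage[res$orthogroup_id == "OG2"], "3")
  # tie goes to the earlier stage and is flagged
  calls2 <- calls
  calls2$stage <- c("6.2", "6.1", "none", "6.2")
  res2 <- orthogroup_stage_preference(og, calls2)
  expect_equal(res2$modal_stage[res2$orthogroup_id == "OG1"], "6.1")
  expect_true(res2$tie[res2$orthogroup_id == "OG1"])
})
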