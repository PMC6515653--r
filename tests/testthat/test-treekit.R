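test_that("p-distances respect the gap handling mode", {
  aln <- c(a = "ACDE", b = "ACDQ")
  D <- p_distance_matrix(aln, "pairwise_deletion")
  expect_equal(D["a", "b"], 0.25)
  expect_equal(diag(D), c(a = 0, b = 0))

  aln2 <- c(a = "AC-E", b = "ACDE")
  expect_equal(p_distance_matrix(aln2, "pairwise_deletion")["a", "b"], 0)
  expect_equal(p_distance_matrix(aln2,
                                 "gaps_as_difference")["a", "b"], 0.25)
  # a pair with no comparable sites names the pair
  aln3 <- c(a = "AC--", b = "--DE", c = "ACDE")
  expect_error(p_distance_matrix(aln3, "pairwise_deletion"), "a.*b")
})

test_that("neighbor joining recovers simple and additive trees", {
  # two taxa: symmetric split convention
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(D2)
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(0.2, 0.2))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))),
               "symmetric")

  # additive 4-leaf matrix from a known tree: exact recovery
  tree <- ape::read.tree(text =
    "((A:0.11,B:0.07):0.05,(C:0.09,D:0.13):0.02);")
  D <- stats::cophenetic(ape::unroot(tree))
  rec <- neighbor_joining(D)
  expect_lt(max(abs(patristic_distances(rec)[rownames(D), colnames(D)] -
                      D)), 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tree), rec), 0,
               ignore_attr = TRUE)
})

test_that("the selected 4-leaf topology minimizes least-squares error", {
  # brute force: OLS branch-length fit for each of the three unrooted
  # 4-leaf topologies, via the path-indicator design matrix
  lsq_fit <- function(D, split) {
    ids <- rownames(D)
    others <- setdiff(ids, split)
    # branches: 4 pendant + 1 internal; path indicators for the 6 pairs
    pairs <- t(utils::combn(ids, 2))
    X <- matrix(0, nrow(pairs), 5,
                dimnames = list(NULL, c(ids, "internal")))
    y <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      X[r, a] <- 1; X[r, b] <- 1
      same_side <- (a %in% split) == (b %in% split)
      if (!same_side) X[r, "internal"] <- 1
      y[r] <- D[a, b]
    }
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  set.seed(13)
  for (rep in 1:10) {
    tree <- ape::rtree(4, br = function(n) stats::runif(n, 0.05, 0.5))
    D <- stats::cophenetic(tree)
    ids <- rownames(D)
    splits <- list(ids[1:2], ids[c(1, 3)], ids[c(1, 4)])
    errs <- vapply(splits, function(s) lsq_fit(D, s), numeric(1))
    rec <- neighbor_joining(D)
    # which split did NJ choose? the pair forming a cherry with ids[1]
    nb <- neighborhood_lengths(rec, ids[1], k = 1)
    partner <- names(nb)[1]
    chosen <- which(vapply(splits, function(s) partner %in% s,
                           logical(1)))
    expect_equal(errs[chosen], min(errs), tolerance = 1e-9)
  }
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    tree <- ape::rtree(n, br = function(x) stats::runif(x, 0.02, 0.4))
    tree <- ape::unroot(tree)
    D <- stats::cophenetic(tree)
    rec <- neighbor_joining(D)
    expect_lt(max(abs(patristic_distances(rec)[rownames(D),
                                               colnames(D)] - D)),
              1e-9)
    expect_equal(ape::dist.topo(tree, rec), 0, ignore_attr = TRUE)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    tree <- ape::unroot(ape::rtree(n, br = function(x)
      stats::runif(x, 0.05, 0.3)))
    D <- stats::cophenetic(tree)
    ours <- neighbor_joining(D)
    apes <- ape::nj(D)
    expect_equal(ape::dist.topo(ours, apes), 0, ignore_attr = TRUE)
  }
})

test_that("negative branch estimates are clamped unless disabled", {
  # a non-additive matrix known to produce a negative NJ estimate
  D <- matrix(c(0, 0.1, 0.6, 0.6,
                0.1, 0, 0.6, 0.6,
                0.6, 0.6, 0, 0.05,
                0.6, 0.6, 0.05, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D, clamp_negative = TRUE)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and saturate on clean signal", {
  # duplicated synapomorphic columns: every split fully supported
  aln <- c(a = paste(rep("AAAA", 10), collapse = ""),
           b = paste(rep("AAAC", 10), collapse = ""),
           c = paste(rep("CCGA", 10), collapse = ""),
           d = paste(rep("CCGC", 10), collapse = ""))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("focal splits with clean synapomorphies get high support", {
  set.seed(29)
  block <- function(ch, n) paste(rep(ch, n), collapse = "")
  # 100 clean columns supporting (a,b)|(c,d) plus 20 noise columns
  noise <- function() paste(sample(c("A", "C", "G", "R"), 20,
                                   replace = TRUE), collapse = "")
  aln <- c(a = paste0(block("A", 100), noise()),
           b = paste0(block("A", 100), noise()),
           c = paste0(block("C", 100), noise()),
           d = paste0(block("C", 100), noise()))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup[!is.na(sup)] >= 95))
})

test_that("rooting places the root on the outgroup edge", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,O:0.5);")
  rooted <- root_tree(tr, "O")
  expect_true(ape::is.rooted(rooted))
  # O hangs directly off the root
  root_node <- length(rooted$tip.label) + 1L
  o_edge <- rooted$edge[rooted$edge[, 2] ==
                          match("O", rooted$tip.label), 1]
  expect_equal(o_edge, root_node)
  expect_error(root_tree(tr, "Z"), "not in tree")
})

test_that("branch neighborhoods match a direct traversal", {
  # cherry: neighborhood of A at k = 1 is exactly B's pendant branch
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.4):0.06);")
  nb <- neighborhood_lengths(tr, "A", k = 1)
  expect_equal(nb, c(B = 0.2))

  set.seed(37)
  for (rep in 1:8) {
    rt <- ape::rtree(10)
    leaf <- sample(rt$tip.label, 1)
    for (k in 1:3) {
      got <- neighborhood_lengths(rt, leaf, k)
      want <- oracle_neighborhood(rt, leaf, k)
      expect_equal(got[order(names(got))], want[order(names(want))])
    }
  }
})
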