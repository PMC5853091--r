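## Fast parameters for unit tests; the full-size benchmark runs in the
## acceptance suite.
fast_params <- list(cv_runs = 5, num_trees = 50, min_leaf = 5)

## two-block matrix with high within-block correlation
block_matrix <- function(n_per = 20, p = 30, seed = 1, strength = 3) {
  set.seed(seed)
  f1 <- rnorm(p); f2 <- -f1
  x <- rbind(
    t(replicate(n_per, strength * f1 + rnorm(p, sd = 0.5))),
    t(replicate(n_per, strength * f2 + rnorm(p, sd = 0.5)))
  )
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per))
  x
}

test_that("bipartition recovers correlation blocks exactly", {
  x <- block_matrix(seed = 2)
  lab <- bipartition(x)
  truth <- rep(1:2, each = 20)
  expect_equal(length(unique(lab)), 2)
  ## same partition up to label switching
  expect_true(all(lab[1:20] == lab[1]) && all(lab[21:40] == lab[21]) &&
                lab[1] != lab[21])
})

test_that("bipartition respects Pearson invariances", {
  x <- block_matrix(seed = 3)
  lab <- bipartition(x)
  ## duplicated sample rows land together
  x2 <- rbind(x, dup = x[1, ])
  lab2 <- bipartition(x2)
  expect_equal(unname(lab2["dup"]), unname(lab2[1]))
  ## affine transform of a row leaves the partition unchanged
  x3 <- x
  x3[5, ] <- 2 * x3[5, ] + 5
  expect_identical(bipartition(x3), lab)
})

test_that("refinement keeps a separable split intact and is deterministic", {
  truth <- small_truth(seed = 4, n_cells = 100, n_genes = 400)
  act <- simulate_regulon_activity(truth, seed = 5)
  sub <- act[truth$cells$group %in% c("G1", "G2"), ]
  init <- bipartition(sub)
  planted <- truth$cells$group[match(rownames(sub), truth$cells$cell_id)]
  ref <- do.call(refine_bipartition, c(list(sub, init, seed = 6),
                                       fast_params[c("cv_runs",
                                                     "num_trees")]))
  expect_equal(ref$status, "ok")
  expect_length(ref$unassigned, 0)
  ## refined labels equal the planted ones up to label switching
  tab <- table(ref$labels, planted[match(names(ref$labels),
                                         rownames(sub))])
  expect_equal(sum(apply(tab, 1, max)), length(ref$labels))
  ## determinism
  ref2 <- do.call(refine_bipartition, c(list(sub, init, seed = 6),
                                        fast_params[c("cv_runs",
                                                      "num_trees")]))
  expect_identical(ref, ref2)
})

test_that("boundary samples earn ambiguous votes and dominate the discards", {
  ## two Gaussian classes plus a few samples whose features are an exact
  ## half-and-half mosaic of the two class profiles (maximally ambiguous)
  vote_gap <- numeric(5)
  boundary_votes <- class_votes <- numeric(0)
  unassigned_is_lowvote <- TRUE
  for (s in 1:5) {
    set.seed(s)
    n_per <- 60; p <- 30
    a <- matrix(rnorm(n_per * p, 1, 1), n_per, p)
    b <- matrix(rnorm(n_per * p, -1, 1), n_per, p)
    mid <- t(vapply(1:4, function(i) {
      sgn <- rep(c(1, -1), length.out = p)[sample.int(p)]
      rnorm(p, sgn, 1)
    }, numeric(p)))
    x <- rbind(a, b, mid)
    rownames(x) <- c(sprintf("a%02d", 1:n_per), sprintf("b%02d", 1:n_per),
                     sprintf("n%d", 1:4))
    init <- rep(c(1, 2, 1), c(n_per, n_per, 4))
    ref <- refine_bipartition(x, init, cv_runs = 10, num_trees = 50,
                              seed = s)
    is_b <- grepl("^n", names(ref$vote_prob))
    boundary_votes <- c(boundary_votes, ref$vote_prob[is_b])
    class_votes <- c(class_votes, ref$vote_prob[!is_b])
    vote_gap[s] <- mean(ref$vote_prob[!is_b]) - mean(ref$vote_prob[is_b])
    ## the retention gate is applied exactly: discarded = vote < 0.55
    expect_setequal(ref$unassigned,
                    names(ref$vote_prob)[ref$vote_prob < 0.55])
  }
  ## ambiguous samples vote well below genuine class members
  expect_true(all(vote_gap > 0.15))
  expect_lt(mean(boundary_votes), 0.7)
  expect_gt(mean(class_votes), 0.85)
})

test_that("raising the retention gate never shrinks the unassigned set", {
  set.seed(7)
  x <- block_matrix(n_per = 30, seed = 7, strength = 1)
  x <- x + matrix(rnorm(length(x), sd = 2), nrow(x))   # noisy split
  init <- rep(1:2, each = 30)
  r_low <- refine_bipartition(x, init, keep_gate = 0.55, cv_runs = 5,
                              num_trees = 50, seed = 8)
  r_high <- refine_bipartition(x, init, keep_gate = 0.7, cv_runs = 5,
                               num_trees = 50, seed = 8)
  if (r_low$status == "ok" && r_high$status == "ok") {
    expect_true(all(r_low$unassigned %in% r_high$unassigned))
  } else {
    succeed("node unsplittable at this noise level; gate ordering vacuous")
  }
})

test_that("recursive clustering recovers four planted groups", {
  truth <- small_truth(seed = 9, n_cells = 200, n_genes = 400)
  act <- simulate_regulon_activity(truth, seed = 10)
  tree <- suppressMessages(recursive_cluster(act, params = fast_params,
                                             seed = 11))
  expect_equal(length(tree$leaves), 4)
  lab <- cluster_labels(tree)[truth$cells$cell_id]
  ok <- !is.na(lab)
  expect_gte(mclust::adjustedRandIndex(lab[ok], truth$cells$group[ok]),
             0.95)
  ## leaves + unassigned partition the input
  all_ids <- c(unlist(tree$leaves), tree$unassigned$sample)
  expect_setequal(all_ids, rownames(act))
  expect_false(anyDuplicated(all_ids) > 0)
  ## reproducibility of the whole tree
  tree2 <- suppressMessages(recursive_cluster(act, params = fast_params,
                                              seed = 11))
  expect_identical(cluster_labels(tree2), cluster_labels(tree))
})

test_that("a homogeneous population yields a single leaf", {
  set.seed(12)
  x <- matrix(rbinom(200 * 20, 1, 0.3), 200, 20)
  rownames(x) <- sprintf("s%03d", 1:200)
  tree <- suppressMessages(recursive_cluster(x, params = fast_params,
                                             seed = 13))
  expect_equal(length(tree$leaves), 1)
  expect_equal(nrow(tree$unassigned), 0)
})

test_that("nested two-level structure reproduces the planted hierarchy", {
  ## super-group A homogeneous; super-group B splits into B1 and B2
  set.seed(14)
  p <- 30
  prob_A  <- rep(c(0.9, 0.1, 0.1), each = p / 3)
  prob_B1 <- rep(c(0.1, 0.9, 0.1), each = p / 3)
  prob_B2 <- rep(c(0.1, 0.9, 0.9), each = p / 3)
  gen <- function(n, pr, tag) {
    m <- matrix(rbinom(n * p, 1, rep(pr, each = n)), n, p)
    rownames(m) <- sprintf("%s%03d", tag, seq_len(n))
    m
  }
  x <- rbind(gen(60, prob_A, "A"), gen(60, prob_B1, "B1x"),
             gen(60, prob_B2, "B2x"))
  tree <- suppressMessages(recursive_cluster(x, params = fast_params,
                                             seed = 15))
  expect_equal(length(tree$leaves), 3)
  lab <- cluster_labels(tree)
  truth_lab <- sub("[0-9]+$", "", names(lab))
  ok <- !is.na(lab)
  expect_gte(mclust::adjustedRandIndex(lab[ok], truth_lab[ok]), 0.95)
  ## hierarchy: the root split separates A from B1 u B2
  root <- tree$nodes[["N"]]
  expect_equal(root$type, "split")
  a_leaf <- unique(lab[grepl("^A", names(lab)) & ok])
  expect_length(a_leaf, 1)
  ## B1 and B2 sit in two distinct leaves different from A's
  b_leaves <- unique(lab[!grepl("^A", names(lab)) & ok])
  expect_length(setdiff(b_leaves, a_leaf), 2)
})
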