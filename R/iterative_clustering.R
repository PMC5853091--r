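## Recursive clustering with random-forest refinement.
##
## Each node: (1) hierarchical bipartition under Pearson-correlation
## distance; (2) fold-wise random-forest feature selection for the genes
## separating the two halves; (3) samples with high out-of-bag vote
## probability for their own class form a training set whose classifier
## relabels the remainder; (4) repeated k-fold cross-validation assigns
## every sample a mean held-out vote probability, and samples below the
## retention gate are discarded as unassigned; (5) recursion into each
## accepted child. Discarded samples are reported, never reassigned.

default_cluster_params <- function() {
  list(train_gate = 0.6, keep_gate = 0.55, cv_runs = 100, cv_folds = 10,
       num_features = 100, num_trees = 500, min_leaf = 10, max_depth = 6,
       split_quality_gate = 0.9, linkage = "average", mode = "binary")
}

#' Two-way hierarchical bipartition under correlation distance
#'
#' Distance between samples i and j is 1 - Pearson r(row_i, row_j);
#' agglomerative clustering (default average linkage) is cut at two
#' clusters. For an expression matrix (`mode = "expression"`), highly
#' variable genes are selected first and the split is computed on them.
#' Samples with zero variance across features (undefined correlation) are
#' attached to the cluster of their nearest Euclidean neighbor with defined
#' correlations, with a message.
#'
#' @param mat samples x features numeric matrix.
#' @param linkage hclust linkage (default "average").
#' @param mode "binary" (use features as-is) or "expression" (select highly
#'   variable genes first; features are genes, values log-normalized).
#' @return integer vector of labels (1/2), named by rownames.
#' @export
bipartition <- function(mat, linkage = "average",
                        mode = c("binary", "expression")) {
  mode <- match.arg(mode)
  stopifnot(nrow(mat) >= 4)
  if (mode == "expression") {
    hvg <- highly_variable_genes(t(mat))
    if (length(hvg) >= 2) mat <- mat[, hvg, drop = FALSE]
  }
  rv <- apply(mat, 1, stats::var)
  degenerate <- which(rv == 0 | is.na(rv))
  ok <- setdiff(seq_len(nrow(mat)), degenerate)
  if (length(ok) < 4) stop_orgsc("fewer than 4 samples with nonzero variance")
  cm <- suppressWarnings(stats::cor(t(mat[ok, , drop = FALSE])))
  cm[is.na(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = linkage)
  lab <- rep(NA_integer_, nrow(mat))
  lab[ok] <- stats::cutree(hc, k = 2)
  if (length(degenerate)) {
    message(length(degenerate),
            " zero-variance sample(s) assigned by nearest neighbor")
    for (i in degenerate) {
      dd <- colSums((t(mat[ok, , drop = FALSE]) - mat[i, ])^2)
      lab[i] <- lab[ok[which.min(dd)]]
    }
  }
  names(lab) <- rownames(mat)
  lab
}

## one ranger fit; x must keep column names for importance extraction
rf_fit <- function(x, y, num_trees, seed, probability = FALSE,
                   importance = "none") {
  ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                 num.threads = 1, probability = probability,
                 importance = importance,
                 respect.unordered.factors = TRUE)
}

#' Refine a bipartition with random forests
#'
#' Implements the three supervised refinement steps around an initial
#' two-way split: fold-wise feature selection by mean impurity importance,
#' vote-probability-gated training-set construction plus relabeling of the
#' remaining samples, and repeated cross-validation with discarding of
#' low-confidence samples.
#'
#' @param mat samples x features matrix.
#' @param init_labels initial two-way labels (vector of 2 distinct values,
#'   aligned with rows).
#' @param train_gate out-of-bag own-class vote probability above which a
#'   sample joins the training set (default 0.6, strict >).
#' @param keep_gate mean cross-validated own-class vote probability below
#'   which a sample is discarded (default 0.55, strict <).
#' @param cv_runs number of repeated cross-validation runs (default 100).
#' @param cv_folds folds per run (default 10).
#' @param num_features number of top features retained (default 100).
#' @param num_trees trees per forest (default 500).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with `status` ("ok" or "unsplittable"), `labels` (final
#'   labels for retained samples, named), `unassigned` (discarded sample
#'   ids), `features`, `vote_prob` (mean CV own-class vote per sample) and
#'   `cv_quality` (mean cross-validated own-class vote over retained
#'   samples, the node's split-quality statistic).
#' @export
refine_bipartition <- function(mat, init_labels, train_gate = 0.6,
                               keep_gate = 0.55, cv_runs = 100,
                               cv_folds = 10, num_features = 100,
                               num_trees = 500, seed = 1) {
  stopifnot(nrow(mat) == length(init_labels))
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  y0 <- factor(init_labels)
  if (nlevels(y0) != 2L) stop_orgsc("init_labels must contain exactly 2 classes")
  n <- nrow(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  unsplit <- function() list(status = "unsplittable", labels = NULL,
                             unassigned = character(0), features = NULL,
                             vote_prob = NULL, cv_quality = NA_real_)

  ## drop constant features (uninformative, and some backends choke)
  keep_f <- which(apply(mat, 2, function(v) any(v != v[1])))
  if (length(keep_f) < 2) return(unsplit())
  mat <- mat[, keep_f, drop = FALSE]

  set.seed(seed_stream(seed, 1))
  ## --- step 2: fold-wise feature selection -------------------------------
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  imp <- numeric(ncol(mat))
  names(imp) <- colnames(mat)
  n_used <- 0L
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (length(unique(y0[tr])) < 2L) next
    fit <- rf_fit(mat[tr, , drop = FALSE], droplevels(y0[tr]), num_trees,
                  seed = seed_stream(seed, 100 + f), importance = "impurity")
    imp <- imp + fit$variable.importance[names(imp)]
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(unsplit())
  features <- names(sort(imp, decreasing = TRUE))[
    seq_len(min(num_features, length(imp)))]
  xm <- mat[, features, drop = FALSE]

  ## --- step 3: vote-gated training set and relabeling --------------------
  oob <- rf_fit(xm, y0, num_trees, seed = seed_stream(seed, 2),
                probability = TRUE)$predictions
  own <- oob[cbind(seq_len(n), match(as.character(y0), colnames(oob)))]
  train <- own > train_gate & !is.na(own)
  if (length(unique(y0[train])) < 2L) return(unsplit())
  clf <- rf_fit(xm[train, , drop = FALSE], droplevels(y0[train]), num_trees,
                seed = seed_stream(seed, 3))
  labels <- as.character(y0)
  if (any(!train)) {
    pred <- predict(clf, xm[!train, , drop = FALSE],
                    num.threads = 1)$predictions
    labels[!train] <- as.character(pred)
  }
  y1 <- factor(labels, levels = levels(y0))
  if (nlevels(droplevels(y1)) < 2L) return(unsplit())

  ## --- step 4: repeated CV and low-confidence discarding -----------------
  vote_sum <- numeric(n)
  vote_n <- numeric(n)
  for (r in seq_len(cv_runs)) {
    set.seed(seed_stream(seed, 1000 + r))
    fr <- sample(rep(seq_len(cv_folds), length.out = n))
    for (f in seq_len(cv_folds)) {
      te <- fr == f
      if (length(unique(y1[!te])) < 2L || !any(te)) next
      fit <- rf_fit(xm[!te, , drop = FALSE], droplevels(y1[!te]), num_trees,
                    seed = seed_stream(seed, 1000 + r * cv_folds + f),
                    probability = TRUE)
      pr <- predict(fit, xm[te, , drop = FALSE],
                    num.threads = 1)$predictions
      own_p <- pr[cbind(seq_len(sum(te)),
                        match(as.character(y1[te]), colnames(pr)))]
      vote_sum[te] <- vote_sum[te] + own_p
      vote_n[te] <- vote_n[te] + 1
    }
  }
  vote_prob <- ifelse(vote_n > 0, vote_sum / vote_n, NA_real_)
  names(vote_prob) <- ids
  discard <- !is.na(vote_prob) & vote_prob < keep_gate
  retained <- which(!discard)
  if (length(unique(y1[retained])) < 2L) return(unsplit())
  ## split quality: mean cross-validated own-class vote over retained
  ## samples; a label set circularly fit to noise plateaus well below the
  ## near-1 votes of a genuine separation
  cv_quality <- mean(vote_prob[retained], na.rm = TRUE)

  out_labels <- as.character(y1[retained])
  names(out_labels) <- ids[retained]
  list(status = "ok", labels = out_labels,
       unassigned = ids[discard], features = features,
       vote_prob = vote_prob, cv_quality = cv_quality)
}

#' Recursive random-forest-refined clustering
#'
#' Applies [bipartition()] plus [refine_bipartition()] at the root and
#' recurses into each resulting class. A branch stops (becomes a leaf)
#' when it holds fewer than `2 * min_leaf` samples, the depth limit is
#' reached, the refinement declares the node unsplittable, or the
#' cross-validated split quality falls below `split_quality_gate`. Samples
#' discarded by the vote-probability gate at an accepted split are recorded
#' as unassigned together with the node where they were dropped. Leaves are
#' numbered in depth-first traversal order.
#'
#' @param mat samples x features matrix (binary regulon activity, cells x
#'   regulons; or cells x genes log-normalized expression with
#'   `params$mode = "expression"`).
#' @param params list of parameters; see `default_cluster_params()` for the
#'   defaults (train_gate 0.6, keep_gate 0.55, cv_runs 100, cv_folds 10,
#'   num_features 100, num_trees 500, min_leaf 10, max_depth 6,
#'   split_quality_gate 0.9, linkage "average", mode "binary").
#' @param seed master seed; per-node seeds are derived deterministically.
#' @return an object of class `orgsc_cluster_tree` with `nodes` (split
#'   records), `leaves` (named list of sample-id vectors), `unassigned`
#'   (data.frame sample/node), `params`, `seed`.
#' @export
recursive_cluster <- function(mat, params = list(), seed = 1) {
  p <- utils::modifyList(default_cluster_params(), params)
  ids <- rownames(mat) %||% sprintf("s%05d", seq_len(nrow(mat)))
  rownames(mat) <- ids
  stopifnot(nrow(mat) >= 2 * p$min_leaf)

  nodes <- list()
  leaves <- list()
  unassigned <- data.frame(sample = character(0), node = character(0),
                           stringsAsFactors = FALSE)
  node_counter <- 0L

  descend <- function(sample_ids, depth, node_id) {
    make_leaf <- function(reason) {
      leaves[[length(leaves) + 1L]] <<- sample_ids
      names(leaves)[length(leaves)] <<- paste0("C", length(leaves))
      nodes[[node_id]] <<- list(node = node_id, type = "leaf",
                                n = length(sample_ids), reason = reason)
    }
    if (length(sample_ids) < 2 * p$min_leaf) {
      make_leaf("min_leaf"); return(invisible())
    }
    if (depth >= p$max_depth) {
      make_leaf("max_depth"); return(invisible())
    }
    sub <- mat[sample_ids, , drop = FALSE]
    init <- tryCatch(bipartition(sub, linkage = p$linkage, mode = p$mode),
                     error = function(e) NULL)
    if (is.null(init) || length(unique(init)) < 2L) {
      make_leaf("unsplittable"); return(invisible())
    }
    node_counter <<- node_counter + 1L
    node_seed <- seed_stream(seed, node_counter)
    ref <- refine_bipartition(sub, init,
                              train_gate = p$train_gate,
                              keep_gate = p$keep_gate,
                              cv_runs = p$cv_runs, cv_folds = p$cv_folds,
                              num_features = p$num_features,
                              num_trees = p$num_trees, seed = node_seed)
    if (ref$status != "ok") {
      make_leaf("unsplittable"); return(invisible())
    }
    if (ref$cv_quality < p$split_quality_gate) {
      make_leaf("split_quality"); return(invisible())
    }
    classes <- sort(unique(ref$labels))
    kids_small <- vapply(classes, function(cl) {
      sum(ref$labels == cl) < p$min_leaf
    }, logical(1))
    if (any(kids_small)) {
      make_leaf("child_min_leaf"); return(invisible())
    }
    ## accepted split
    if (length(ref$unassigned)) {
      unassigned <<- rbind(unassigned,
                           data.frame(sample = ref$unassigned,
                                      node = node_id,
                                      stringsAsFactors = FALSE))
    }
    child_ids <- paste0(node_id, c(".1", ".2"))
    nodes[[node_id]] <<- list(node = node_id, type = "split",
                              n = length(sample_ids),
                              children = child_ids,
                              features = ref$features,
                              vote_prob = ref$vote_prob,
                              cv_quality = ref$cv_quality,
                              seed = node_seed)
    for (i in seq_along(classes)) {
      descend(names(ref$labels)[ref$labels == classes[i]], depth + 1L,
              child_ids[i])
    }
    invisible()
  }

  descend(ids, 0L, "N")
  structure(list(nodes = nodes, leaves = leaves, unassigned = unassigned,
                 params = p, seed = seed, n_samples = length(ids)),
            class = "orgsc_cluster_tree")
}

#' Leaf assignment from a cluster tree
#'
#' @param tree an `orgsc_cluster_tree`.
#' @return named character vector over all input samples: leaf name, or NA
#'   for unassigned samples.
#' @export
cluster_labels <- function(tree) {
  stopifnot(inherits(tree, "orgsc_cluster_tree"))
  out <- character(0)
  for (nm in names(tree$leaves)) {
    v <- rep(nm, length(tree$leaves[[nm]]))
    names(v) <- tree$leaves[[nm]]
    out <- c(out, v)
  }
  if (nrow(tree$unassigned)) {
    v <- rep(NA_character_, nrow(tree$unassigned))
    names(v) <- tree$unassigned$sample
    out <- c(out, v)
  }
  out
}

#' @export
print.orgsc_cluster_tree <- function(x, ...) {
  cat(sprintf(
    "orgsc cluster tree: %d samples -> %d leaves (%d unassigned)\n",
    x$n_samples, length(x$leaves), nrow(x$unassigned)))
  for (nm in names(x$leaves)) {
    cat(sprintf("  %s: %d samples\n", nm, length(x$leaves[[nm]])))
  }
  invisible(x)
}

#' @export
summary.orgsc_cluster_tree <- function(object, ...) {
  splits <- Filter(function(n) n$type == "split", object$nodes)
  cat(sprintf("Leaves: %d; unassigned: %d; accepted splits: %d\n",
              length(object$leaves), nrow(object$unassigned),
              length(splits)))
  for (s in splits) {
    cat(sprintf("  %s: n=%d, CV split quality=%.3f, %d features\n",
                s$node, s$n, s$cv_quality, length(s$features)))
  }
  invisible(object)
}
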