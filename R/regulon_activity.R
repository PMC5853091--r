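## Regulon activity: area-under-recovery-curve (AUC) enrichment of a
## regulon's target set in each cell's expression ranking, binarization of
## the AUC matrix into on/off activity calls, and ranking of
## cluster-specific top transcription factors.

#' Regulon AUC for one cell
#'
#' Genes are ranked by descending expression (ties broken by stable gene
#' order); the recovery curve R(i) counts regulon genes among the top i
#' ranks. The statistic is the area under R over the top
#' `ceiling(top_fraction * n_genes)` ranks, scaled to [0, 1] so that a
#' regulon whose genes fill the top ranks scores 1 and a regulon absent
#' from the window scores 0.
#'
#' Because only the ranking enters, the score is invariant under any
#' strictly monotone transform of the expression values.
#'
#' @param expr_cell named numeric vector: expression of every gene in one
#'   cell.
#' @param regulon a regulon (list with `name`, `targets`).
#' @param top_fraction fraction of the gene universe forming the scoring
#'   window (default 0.05).
#' @return numeric scalar in [0, 1].
#' @export
regulon_auc <- function(expr_cell, regulon, top_fraction = 0.05) {
  genes <- names(expr_cell)
  targets <- intersect(regulon$targets, genes)
  if (!length(targets)) {
    stop_orgsc(sprintf("regulon %s shares no genes with the expression universe",
                       regulon$name %||% "<unnamed>"))
  }
  n <- length(expr_cell)
  w <- ceiling(top_fraction * n)
  ## stable sort: order() is stable, so ties keep gene order
  ord <- order(-expr_cell)
  pos <- match(targets, genes[ord])
  m <- length(targets)
  ## area = sum_i R(i) over i = 1..w; each hit at rank p contributes w-p+1
  hits <- pos[pos <= w]
  area <- sum(w - hits + 1)
  max_area <- if (m >= w) w * (w + 1) / 2 else m * (m + 1) / 2 + (w - m) * m
  area / max_area
}

#' Regulon AUC matrix over all cells
#'
#' @param expr genes x cells normalized expression matrix.
#' @param regulons named list of regulons.
#' @param top_fraction scoring-window fraction (default 0.05).
#' @return regulons x cells numeric matrix of AUC values.
#' @export
auc_matrix <- function(expr, regulons, top_fraction = 0.05) {
  validate_regulons(regulons)
  out <- matrix(0, nrow = length(regulons), ncol = ncol(expr),
                dimnames = list(names(regulons), colnames(expr)))
  genes <- rownames(expr)
  n <- length(genes)
  w <- ceiling(top_fraction * n)
  tgt_idx <- lapply(regulons, function(r) {
    idx <- match(intersect(r$targets, genes), genes)
    if (!length(idx)) {
      stop_orgsc(sprintf("regulon %s shares no genes with the expression universe",
                         r$name %||% "<unnamed>"))
    }
    idx
  })
  for (cc in seq_len(ncol(expr))) {
    ord <- order(-expr[, cc])
    rank_of <- integer(n)
    rank_of[ord] <- seq_len(n)
    for (rr in seq_along(regulons)) {
      pos <- rank_of[tgt_idx[[rr]]]
      m <- length(pos)
      hits <- pos[pos <= w]
      max_area <- if (m >= w) w * (w + 1) / 2 else
        m * (m + 1) / 2 + (w - m) * m
      out[rr, cc] <- sum(w - hits + 1) / max_area
    }
  }
  out
}

#' Binarize a regulon AUC matrix
#'
#' Per regulon, fits a two-component Gaussian mixture to the AUC values
#' across cells and thresholds at the point between the component means
#' where the posterior probability of the upper component crosses 0.5;
#' activity is 1 iff AUC exceeds the threshold. Constant columns give all
#' zeros. If the mixture fit fails (or collapses to one component), the
#' per-regulon `fallback_quantile` of the AUC values is used instead, with
#' a warning.
#'
#' @param auc regulons x cells AUC matrix.
#' @param method "mixture" (default) or "quantile".
#' @param fallback_quantile quantile used by the fallback/quantile scheme.
#' @return list of class `orgsc_binary_regulons`: `activity` (0/1 matrix),
#'   `auc`, `thresholds`, `method_used` (per regulon).
#' @importFrom mclust Mclust mclustBIC
#' @export
binarize <- function(auc, method = c("mixture", "quantile"),
                     fallback_quantile = 0.75) {
  method <- match.arg(method)
  stopifnot(all(auc >= 0 & auc <= 1))
  nr <- nrow(auc)
  thr <- numeric(nr)
  used <- character(nr)
  for (i in seq_len(nr)) {
    x <- auc[i, ]
    if (stats::sd(x) == 0) {
      thr[i] <- Inf          # constant column: never active
      used[i] <- "constant"
      next
    }
    t_i <- NA_real_
    if (method == "mixture") {
      fit <- tryCatch(
        suppressWarnings(Mclust(x, G = 2, modelNames = "V",
                                verbose = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$parameters$mean)) == 2L) {
        mu <- fit$parameters$mean
        pro <- fit$parameters$pro
        sig <- sqrt(fit$parameters$variance$sigmasq)
        if (length(sig) == 1L) sig <- rep(sig, 2)
        lo <- which.min(mu); hi <- which.max(mu)
        grid <- seq(mu[lo], mu[hi], length.out = 512)
        post_hi <- pro[hi] * stats::dnorm(grid, mu[hi], sig[hi]) /
          (pro[lo] * stats::dnorm(grid, mu[lo], sig[lo]) +
             pro[hi] * stats::dnorm(grid, mu[hi], sig[hi]))
        cross <- which(post_hi >= 0.5)
        if (length(cross)) {
          t_i <- grid[cross[1]]
          used[i] <- "mixture"
        }
      }
    }
    if (is.na(t_i)) {
      t_i <- stats::quantile(x, fallback_quantile, names = FALSE)
      if (method == "mixture") {
        warning(sprintf(
          "regulon %s: mixture fit failed; falling back to quantile threshold",
          rownames(auc)[i] %||% i))
        used[i] <- "quantile_fallback"
      } else used[i] <- "quantile"
    }
    thr[i] <- t_i
  }
  activity <- (auc > thr) * 1L
  structure(list(activity = activity, auc = auc, thresholds = thr,
                 method_used = used),
            class = "orgsc_binary_regulons")
}

#' @export
print.orgsc_binary_regulons <- function(x, ...) {
  cat(sprintf("Binary regulon activity: %d regulons x %d cells (%.1f%% active)\n",
              nrow(x$activity), ncol(x$activity), 100 * mean(x$activity)))
  invisible(x)
}

#' Rank cluster-specific top transcription factors
#'
#' Scores each regulon by the difference between its mean binary activity
#' inside the cluster and in the rest of the cells; a larger difference
#' ranks higher. Ties are broken lexicographically by regulon name so the
#' ranking is deterministic.
#'
#' @param binary an `orgsc_binary_regulons` (or a 0/1 regulons x cells
#'   matrix).
#' @param labels cluster assignment per cell (vector aligned with columns).
#' @param cluster the cluster id to profile.
#' @param top_k number of regulons to return (default 10).
#' @return data.frame `regulon`, `score`, ordered by decreasing score.
#' @export
rank_top_tfs <- function(binary, labels, cluster, top_k = 10) {
  act <- if (inherits(binary, "orgsc_binary_regulons")) binary$activity
         else binary
  stopifnot(length(labels) == ncol(act))
  if (!cluster %in% labels) stop_orgsc("cluster not present in labels: ", cluster)
  inside <- labels == cluster
  if (all(inside)) stop_orgsc("cluster covers all cells; no contrast")
  score <- rowMeans(act[, inside, drop = FALSE]) -
    rowMeans(act[, !inside, drop = FALSE])
  nm <- rownames(act) %||% as.character(seq_len(nrow(act)))
  ord <- order(-score, nm)
  utils::head(data.frame(regulon = nm[ord], score = score[ord],
                         row.names = NULL, stringsAsFactors = FALSE), top_k)
}
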