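## One-vs-rest differential expression by ROC "classification power":
## AUC of a single-gene classifier separating one cluster from the rest
## (Mann-Whitney construction, ties counted half), power = 2 * |AUC - 0.5|.

#' ROC classification power of one gene for a cluster
#'
#' AUC is the probability that a random in-cluster cell has a higher value
#' than a random out-of-cluster cell, ties counting one half (the
#' Mann-Whitney U construction via midranks). Power rescales AUC so 0 is
#' random and 1 is perfect in either direction.
#'
#' @param expr_gene numeric vector: one gene's expression across cells.
#' @param in_cluster logical mask, same length.
#' @return named numeric vector `c(auc = , power = )`.
#' @export
roc_power <- function(expr_gene, in_cluster) {
  stopifnot(length(expr_gene) == length(in_cluster))
  n_in <- sum(in_cluster)
  n_out <- sum(!in_cluster)
  if (n_in == 0 || n_out == 0) stop_orgsc("both groups must be non-empty")
  r <- rank(expr_gene)             # midranks handle ties
  u <- sum(r[in_cluster]) - n_in * (n_in + 1) / 2
  auc <- u / (n_in * n_out)
  c(auc = auc, power = 2 * abs(auc - 0.5))
}

#' Find marker genes for one cluster (one vs rest)
#'
#' A gene is selected iff the difference of mean log2-normalized expression
#' between the cluster and the rest is at least `min_log2_diff` in absolute
#' value (log2FC >= 1 corresponds to fold change >= 2 or <= 0.5) and its
#' classification power is at least `min_power`. Results are sorted by
#' power (descending), then |log2 mean difference|, then gene id.
#'
#' @param expr genes x cells log2-normalized expression matrix.
#' @param labels cluster assignment per cell (NA allowed; such cells are
#'   ignored).
#' @param cluster cluster id to contrast against the rest.
#' @param min_log2_diff minimum |mean_in - mean_out| on the log2 scale
#'   (default 1).
#' @param min_power minimum classification power (default 0.4).
#' @param min_pct optional minimum fraction of in-cluster cells expressing
#'   the gene (> 0); default 0 (off).
#' @return data.frame: gene, cluster, auc, power, log2_mean_diff,
#'   direction.
#' @export
find_markers <- function(expr, labels, cluster, min_log2_diff = 1,
                         min_power = 0.4, min_pct = 0) {
  stopifnot(ncol(expr) == length(labels))
  use <- !is.na(labels)
  if (!cluster %in% labels[use]) stop_orgsc("cluster not found: ", cluster)
  if (length(unique(labels[use])) < 2) stop_orgsc("need >= 2 clusters")
  e <- expr[, use, drop = FALSE]
  inside <- labels[use] == cluster
  mean_in <- rowMeans(e[, inside, drop = FALSE])
  mean_out <- rowMeans(e[, !inside, drop = FALSE])
  diff <- mean_in - mean_out
  cand <- which(abs(diff) >= min_log2_diff)
  if (min_pct > 0) {
    pct <- rowMeans(e[, inside, drop = FALSE] > 0)
    cand <- cand[pct[cand] >= min_pct]
  }
  if (!length(cand)) {
    return(data.frame(gene = character(0), cluster = character(0),
                      auc = numeric(0), power = numeric(0),
                      log2_mean_diff = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  rp <- t(vapply(cand, function(g) roc_power(e[g, ], inside), numeric(2)))
  keep <- rp[, "power"] >= min_power
  res <- data.frame(gene = rownames(e)[cand[keep]],
                    cluster = as.character(cluster),
                    auc = rp[keep, "auc"],
                    power = rp[keep, "power"],
                    log2_mean_diff = diff[cand[keep]],
                    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$log2_mean_diff > 0, "up", "down")
  res[order(-res$power, -abs(res$log2_mean_diff), res$gene), , drop = FALSE]
}

#' Find markers for every cluster
#'
#' Applies [find_markers()] one-vs-rest per cluster and binds the results.
#'
#' @inheritParams find_markers
#' @return combined data.frame across clusters.
#' @export
find_all_markers <- function(expr, labels, min_log2_diff = 1,
                             min_power = 0.4, min_pct = 0) {
  cls <- sort(unique(labels[!is.na(labels)]))
  do.call(rbind, c(lapply(cls, function(cl) {
    find_markers(expr, labels, cl, min_log2_diff = min_log2_diff,
                 min_power = min_power, min_pct = min_pct)
  }), list(make.row.names = FALSE)))
}
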