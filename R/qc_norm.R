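## Normalization to log2(TPM/10 + 1), cell/gene filtering, highly variable
## gene selection, and sequencing-saturation analysis by read downsampling.
##
## "TPM" here is UMIs per million per cell: counts are transcript-level
## UMIs, so no gene-length term enters. The /10 rescaling reflects that
## typical cells carry well under one million UMIs; without it each
## molecule would inflate the per-million scale roughly tenfold.

#' Normalize a UMI count matrix to log2(TPM/10 + 1)
#'
#' `value[g, c] = log2(counts[g, c] / total[c] * 1e6 / 10 + 1)`. A value is
#' 0 exactly when the raw count is 0, and the transform is invariant to
#' scaling all of a cell's counts by a constant.
#'
#' @param counts genes x cells matrix of UMI counts.
#' @return genes x cells numeric matrix of normalized expression, with the
#'   normalization recorded in `attr(, "normalization")`.
#' @export
normalize_expression <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    stop_orgsc("cells with zero total counts: ",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  expr <- log2(tpm / 10 + 1)
  attr(expr, "normalization") <- "log2(TPM/10 + 1), TPM = UMIs per million"
  expr
}

#' Filter cells and genes
#'
#' Two-stage filter: (1) cells whose number of detected genes (raw count >=
#' 1) is below `min_genes_per_cell` are removed; (2) genes expressed
#' (normalized value >= `expressed_threshold`) in fewer than
#' `min_cells_per_gene` of the remaining cells are removed. A cell with
#' exactly `min_genes_per_cell` detected genes is kept by default
#' (`cell_boundary = "keep"`); set `cell_boundary = "drop"` to remove it.
#'
#' @param expr normalized expression matrix (from
#'   [normalize_expression()]); aligned with `counts`.
#' @param counts raw UMI count matrix.
#' @param min_genes_per_cell detected-gene threshold (default 2000).
#' @param min_cells_per_gene expressing-cell threshold (default 3).
#' @param expressed_threshold normalized value at or above which a gene
#'   counts as expressed (default 1).
#' @param cell_boundary "keep" or "drop" for cells exactly at
#'   `min_genes_per_cell`.
#' @return list with filtered `expr`, `counts`, and a `report` listing the
#'   removed ids and reasons.
#' @export
filter_cells_genes <- function(expr, counts, min_genes_per_cell = 2000,
                               min_cells_per_gene = 3,
                               expressed_threshold = 1,
                               cell_boundary = c("keep", "drop")) {
  stopifnot(identical(dim(expr), dim(counts)))
  cell_boundary <- match.arg(cell_boundary)
  detected <- colSums(counts >= 1)
  drop_cell <- if (cell_boundary == "keep") {
    detected < min_genes_per_cell
  } else {
    detected <= min_genes_per_cell
  }
  expr2 <- expr[, !drop_cell, drop = FALSE]
  counts2 <- counts[, !drop_cell, drop = FALSE]

  expressing <- rowSums(expr2 >= expressed_threshold)
  drop_gene <- expressing < min_cells_per_gene
  if (all(drop_gene)) {
    warning("all genes removed by the expression filter")
  }
  report <- list(
    removed_cells = data.frame(
      cell_id = colnames(counts)[drop_cell] %||% which(drop_cell),
      detected_genes = detected[drop_cell],
      reason = rep("few_detected_genes", sum(drop_cell)),
      stringsAsFactors = FALSE),
    removed_genes = data.frame(
      gene_id = rownames(counts2)[drop_gene] %||% which(drop_gene),
      expressing_cells = expressing[drop_gene],
      reason = rep("few_expressing_cells", sum(drop_gene)),
      stringsAsFactors = FALSE)
  )
  list(expr = expr2[!drop_gene, , drop = FALSE],
       counts = counts2[!drop_gene, , drop = FALSE],
       report = report)
}

#' Highly variable genes
#'
#' Genes with mean normalized expression above `mean_threshold` and
#' dispersion (variance / mean of normalized expression) above
#' `dispersion_threshold`.
#'
#' @param expr normalized expression matrix.
#' @param mean_threshold mean cutoff (default 1, strict >).
#' @param dispersion_threshold dispersion cutoff (default 1, strict >).
#' @return character vector of gene ids.
#' @export
highly_variable_genes <- function(expr, mean_threshold = 1,
                                  dispersion_threshold = 1) {
  stopifnot(ncol(expr) >= 2)
  mu <- rowMeans(expr)
  v <- apply(expr, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  rownames(expr)[mu > mean_threshold & disp > dispersion_threshold]
}

#' Sequencing-saturation curve by read downsampling
#'
#' Assigns every read a fixed uniform draw and includes it at fraction `f`
#' iff the draw is at most `f`; subsamples are therefore nested and the
#' detected-gene curve is monotone non-decreasing by construction. At each
#' fraction, UMI counting is re-run on the retained reads and a gene counts
#' as detected when its post-deduplication count reaches
#' `detection_min_count` in at least one cell.
#'
#' @param assignments data.frame of accepted reads (`barcode`, `gene`,
#'   `umi`), e.g. from [quantify_strt()].
#' @param fractions fractions in (0, 1]; 1 is always added as reference.
#' @param seed integer seed for the per-read draws.
#' @param detection_min_count minimum post-dedup count (default 1).
#' @return object of class `orgsc_saturation`: data.frame with `fraction`
#'   and `genes_detected`, plus attribute `reference_genes`.
#' @export
saturation_curve <- function(assignments,
                             fractions = seq(0.1, 0.9, by = 0.1),
                             seed = 1, detection_min_count = 1) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop_orgsc("fractions must lie in (0, 1]")
  }
  fractions <- sort(unique(c(fractions, 1)))
  set.seed(seed)
  u <- stats::runif(nrow(assignments))
  detected_at <- function(f) {
    keep <- u <= f
    if (!any(keep)) return(0L)
    m <- count_umis(assignments[keep, , drop = FALSE])
    sum(apply(m, 1, max) >= detection_min_count)
  }
  genes_detected <- vapply(fractions, detected_at, integer(1))
  out <- data.frame(fraction = fractions, genes_detected = genes_detected)
  attr(out, "reference_genes") <- genes_detected[fractions == 1]
  class(out) <- c("orgsc_saturation", "data.frame")
  out
}

#' @export
print.orgsc_saturation <- function(x, ...) {
  cat("Sequencing saturation curve (", attr(x, "reference_genes"),
      " genes at full depth):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
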