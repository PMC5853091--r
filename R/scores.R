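## Gene-set scores: epithelial (E), mesenchymal (M) and stemness (S)
## panels, cell-cycle phase calls from G1/S and G2/M scores, the
## E/M-hybrid-state rule, and the correlation of panel scores with a PC1
## pseudodevelopmental axis.

#' Mean-expression score of a gene panel per cell
#'
#' Arithmetic mean of normalized expression over the panel genes present
#' in the matrix; panel genes absent from the matrix are dropped with a
#' warning (their count is recorded in `attr(, "missing_genes")`).
#'
#' @param expr genes x cells normalized expression matrix.
#' @param panel character vector of gene ids (or a named list entry from
#'   [default_panels()]).
#' @param name panel name used in error messages.
#' @return named numeric vector of per-cell scores.
#' @export
gene_set_score <- function(expr, panel, name = "panel") {
  panel <- unique(unlist(panel, use.names = FALSE))
  present <- intersect(panel, rownames(expr))
  if (!length(present)) {
    stop_orgsc(sprintf("panel '%s' shares no genes with the matrix", name))
  }
  n_missing <- length(panel) - length(present)
  if (n_missing > 0) {
    warning(sprintf("panel '%s': %d gene(s) absent from the matrix dropped",
                    name, n_missing))
  }
  s <- colMeans(expr[present, , drop = FALSE])
  attr(s, "missing_genes") <- n_missing
  s
}

#' Cell-cycle phase from G1/S and G2/M scores
#'
#' A cell is quiescent iff both scores fall below `quiescent_threshold`;
#' otherwise it is proliferative and assigned G2/M iff its G2/M score
#' strictly exceeds its G1/S score, else G1/S (a tie goes to G1/S).
#'
#' @param expr genes x cells normalized expression matrix.
#' @param g1s_panel,g2m_panel gene panels.
#' @param quiescent_threshold score threshold (default 2).
#' @return data.frame: cell_id, g1s_score, g2m_score, phase
#'   ("quiescent" | "G1/S" | "G2/M").
#' @export
cell_cycle_phase <- function(expr, g1s_panel, g2m_panel,
                             quiescent_threshold = 2) {
  g1s <- gene_set_score(expr, g1s_panel, "G1S")
  g2m <- gene_set_score(expr, g2m_panel, "G2M")
  phase <- ifelse(g1s < quiescent_threshold & g2m < quiescent_threshold,
                  "quiescent", ifelse(g2m > g1s, "G2/M", "G1/S"))
  data.frame(cell_id = colnames(expr) %||% seq_along(g1s),
             g1s_score = as.numeric(g1s), g2m_score = as.numeric(g2m),
             phase = phase, stringsAsFactors = FALSE)
}

#' E/M hybrid-state call per cell
#'
#' A cell is in the epithelial/mesenchymal hybrid state iff its normalized
#' expression of both the epithelial marker (default Epcam) and the
#' mesenchymal marker (default Vim) strictly exceeds the threshold
#' (default 2).
#'
#' @param expr genes x cells normalized expression matrix.
#' @param e_gene epithelial marker gene id (default "Epcam").
#' @param m_gene mesenchymal marker gene id (default "Vim").
#' @param threshold expression threshold (default 2, strict >).
#' @return named logical vector per cell.
#' @export
hybrid_state <- function(expr, e_gene = "Epcam", m_gene = "Vim",
                         threshold = 2) {
  for (g in c(e_gene, m_gene)) {
    if (!g %in% rownames(expr)) stop_orgsc("gene absent from matrix: ", g)
  }
  expr[e_gene, ] > threshold & expr[m_gene, ] > threshold
}

#' Panel-score correlation with a PC1 pseudotime proxy
#'
#' Computes PC1 of the centered (not variance-scaled) expression matrix
#' over the given cells, orients it so that its correlation with the
#' per-cell detected-gene count is non-negative (PCA sign is otherwise
#' arbitrary), and returns the Pearson correlation of each panel score
#' with PC1.
#'
#' @param expr genes x cells normalized expression matrix (one cell
#'   group / subset).
#' @param panels named list of gene panels.
#' @return list with `pc1` (named per-cell scores), `scores` (cells x
#'   panels matrix) and `correlations` (named numeric; NA where a score is
#'   constant).
#' @export
score_pseudotime_correlation <- function(expr, panels) {
  stopifnot(ncol(expr) >= 3)
  keep <- apply(expr, 1, stats::var) > 0
  if (sum(keep) < 2) stop_orgsc("need >= 2 variable genes")
  pc <- stats::prcomp(t(expr[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE, rank. = 1)
  pc1 <- pc$x[, 1]
  detected <- colSums(expr > 0)
  orient <- suppressWarnings(stats::cor(pc1, detected))
  if (is.na(orient) || orient == 0) {
    ## degenerate anchor (e.g. every gene detected in every cell): fall
    ## back to fixing the sign of the largest-magnitude gene loading,
    ## which is invariant to cell order
    ld <- pc$rotation[, 1]
    orient <- sign(ld[which.max(abs(ld))])
  }
  if (orient < 0) pc1 <- -pc1
  scores <- vapply(names(panels), function(p) {
    gene_set_score(expr, panels[[p]], p)
  }, numeric(ncol(expr)))
  correlations <- vapply(names(panels), function(p) {
    s <- scores[, p]
    if (stats::sd(s) == 0) NA_real_ else stats::cor(s, pc1)
  }, numeric(1))
  list(pc1 = pc1, scores = scores, correlations = correlations)
}

#' Full per-cell score table
#'
#' Convenience wrapper computing E/M/S scores, cell-cycle phase and the
#' hybrid-state call for every cell.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param panels named list with at least E, M, S, G1S, G2M.
#' @param e_gene,m_gene,hybrid_threshold see [hybrid_state()]; the hybrid
#'   call is NA if either gene is absent.
#' @return data.frame: cell_id, E, M, S, g1s_score, g2m_score, phase,
#'   hybrid.
#' @export
cell_score_table <- function(expr, panels = default_panels(),
                             e_gene = "Epcam", m_gene = "Vim",
                             hybrid_threshold = 2) {
  cc <- cell_cycle_phase(expr, panels$G1S, panels$G2M)
  hyb <- tryCatch(hybrid_state(expr, e_gene, m_gene, hybrid_threshold),
                  error = function(e) rep(NA, ncol(expr)))
  data.frame(cell_id = cc$cell_id,
             E = as.numeric(gene_set_score(expr, panels$E, "E")),
             M = as.numeric(gene_set_score(expr, panels$M, "M")),
             S = as.numeric(gene_set_score(expr, panels$S, "S")),
             g1s_score = cc$g1s_score, g2m_score = cc$g2m_score,
             phase = cc$phase, hybrid = as.logical(hyb),
             stringsAsFactors = FALSE)
}
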