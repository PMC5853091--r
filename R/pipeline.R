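## Pipeline orchestration: simulate -> quantify -> qc (+ saturation) ->
## regulon score -> cluster -> markers -> score, as a configured,
## logged, reproducible run with a checksum manifest.

#' Default pipeline configuration
#'
#' Stage toggles plus every stage parameter, with method defaults:
#' min_genes 2000, min_cells 3, expressed threshold 1, HVG mean > 1 and
#' dispersion > 1, train gate 0.6, keep gate 0.55, 100 runs of 10-fold CV,
#' marker power >= 0.4 and log2FC >= 1, cell-cycle and hybrid thresholds 2,
#' saturation fractions 10-90%. The synthetic stage sizes default to a
#' desk-scale benchmark (400 cells, 500 genes, 4 groups).
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `cluster = list(cv_runs = 20)`).
#' @return nested named list of class `orgsc_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = NULL,
    stages = list(simulate = TRUE, quantify = TRUE, qc = TRUE,
                  saturation = FALSE, regulon_score = TRUE, cluster = TRUE,
                  markers = TRUE, score = TRUE),
    simulate = list(n_cells = 400, n_genes = 500, n_groups = 4,
                    fastq = FALSE, error_rate = 0, duplicate_rate = 0,
                    generator = list()),
    quantify = list(k = 21, rescue = FALSE),
    ## min_genes_per_cell scaled to the 500-gene synthetic universe; the
    ## stage function's own default (2000) applies to genome-scale data
    qc = list(min_genes_per_cell = 200, min_cells_per_gene = 3,
              expressed_threshold = 1),
    saturation = list(fractions = seq(0.1, 0.9, by = 0.1),
                      detection_min_count = 1),
    regulon_score = list(top_fraction = 0.05, binarize_method = "mixture"),
    cluster = list(),
    markers = list(min_log2_diff = 1, min_power = 0.4),
    score = list(hybrid_threshold = 2, quiescent_threshold = 2)
  )
  structure(utils::modifyList(cfg, list(...)), class = "orgsc_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return an `orgsc_config`.
#' @export
read_run_config <- function(path) {
  structure(utils::modifyList(unclass(default_run_config()),
                              yaml::read_yaml(path)),
            class = "orgsc_config")
}

#' @rdname read_run_config
#' @param config an `orgsc_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data (or a
#' provided count matrix), writing each stage's outputs under `outdir` and
#' a `manifest.json` recording parameters, seeds and an md5 checksum of
#' every output file. Reruns with an identical configuration reproduce
#' identical outputs.
#'
#' @param config an `orgsc_config` (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param outdir output directory (overrides `config$outdir`).
#' @return the manifest, invisibly (list with `stages`, `files`,
#'   `checksums`).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- outdir %||% config$outdir %||% tempfile("orgsc_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  st <- config$stages
  manifest <- list(package = "orgsc",
                   version = as.character(utils::packageVersion("orgsc")),
                   seed = seed, config = unclass(config),
                   stages = list())
  log_msg <- function(...) message("[orgsc] ", ...)
  add_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      files = files,
      checksums = as.list(tools::md5sum(files)))
  }

  need <- function(cond, stage, what) {
    if (!cond) {
      stop_orgsc(sprintf("stage '%s' requires %s but it is not available",
                         stage, what))
    }
  }

  counts <- NULL; cells <- NULL; truth <- NULL
  regulons <- NULL; assignments <- NULL

  ## ---- simulate ---------------------------------------------------------
  if (isTRUE(st$simulate)) {
    log_msg("simulate")
    sp <- config$simulate
    gcfg <- do.call(generator_config, sp$generator %||% list())
    truth <- generate_truth_model(sp$n_cells, sp$n_genes, sp$n_groups,
                                  config = gcfg,
                                  seed = seed_stream(seed, 11))
    sim <- simulate_counts(truth, seed = seed_stream(seed, 12))
    regulons <- truth$regulons
    d <- file.path(outdir, "simulate")
    dir.create(d, showWarnings = FALSE)
    files <- character(0)
    fq <- NULL; ref <- NULL; wl <- NULL
    if (isTRUE(sp$fastq)) {
      ref <- make_toy_reference(rownames(sim$counts),
                                seed = seed_stream(seed, 13))
      wl <- generate_whitelist(ncol(sim$counts),
                               seed = seed_stream(seed, 14))
      fq <- simulate_fastq(sim$counts, ref, wl,
                           error_rate = sp$error_rate,
                           duplicate_rate = sp$duplicate_rate,
                           seed = seed_stream(seed, 15), dir = d)
      fa <- file.path(d, "reference.fasta")
      write_reference_fasta(ref, fa)
      files <- c(files, fq$r1, fq$r2, fq$whitelist_file, fa)
    } else {
      counts <- sim$counts
      write_counts_mtx(counts, file.path(d, "counts"))
      files <- c(files, file.path(d, "counts",
                                  c("matrix.mtx", "genes.tsv",
                                    "barcodes.tsv")))
    }
    cells <- sim$cells
    utils::write.table(cells, file.path(d, "truth_cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_regulons(regulons, file.path(d, "regulons.tsv"))
    files <- c(files, file.path(d, c("truth_cells.tsv", "regulons.tsv")))
    add_stage("simulate", files)

    ## ---- quantify (only meaningful when FASTQ was simulated) ------------
    if (isTRUE(st$quantify) && isTRUE(sp$fastq)) {
      log_msg("quantify")
      q <- quantify_strt(fq$r1, fq$r2, wl, ref, k = config$quantify$k,
                         rescue = config$quantify$rescue)
      counts <- q$counts
      colnames(counts) <- colnames(sim$counts)[match(colnames(counts), wl)]
      assignments <- q$assignments
      dq <- file.path(outdir, "quantify")
      dir.create(dq, showWarnings = FALSE)
      write_counts_mtx(counts, file.path(dq, "counts"))
      jsonlite::write_json(as.list(q$log),
                           file.path(dq, "quantify_log.json"),
                           auto_unbox = TRUE)
      add_stage("quantify",
                c(file.path(dq, "counts", c("matrix.mtx", "genes.tsv",
                                            "barcodes.tsv")),
                  file.path(dq, "quantify_log.json")))
    }
  }

  ## ---- qc ---------------------------------------------------------------
  expr <- NULL
  if (isTRUE(st$qc)) {
    need(!is.null(counts), "qc", "a count matrix (enable 'simulate' or supply one)")
    log_msg("qc")
    qp <- config$qc
    expr0 <- normalize_expression(counts)
    filt <- filter_cells_genes(expr0, counts,
                               min_genes_per_cell = qp$min_genes_per_cell,
                               min_cells_per_gene = qp$min_cells_per_gene,
                               expressed_threshold = qp$expressed_threshold)
    expr <- filt$expr
    d <- file.path(outdir, "qc")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(
      data.frame(gene = rownames(expr), round(expr, 4),
                 check.names = FALSE),
      file.path(d, "expression.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(filt$report, file.path(d, "filter_report.json"),
                         auto_unbox = TRUE)
    add_stage("qc", file.path(d, c("expression.tsv", "filter_report.json")))
  }

  ## ---- saturation -------------------------------------------------------
  if (isTRUE(st$saturation)) {
    need(!is.null(assignments), "saturation",
         "a read-to-gene assignment stream (enable FASTQ simulation)")
    log_msg("saturation")
    sat <- saturation_curve(assignments,
                            fractions = config$saturation$fractions,
                            seed = seed_stream(seed, 21),
                            detection_min_count =
                              config$saturation$detection_min_count)
    d <- file.path(outdir, "saturation")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(as.data.frame(sat), file.path(d, "saturation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("saturation", file.path(d, "saturation.tsv"))
  }

  ## ---- regulon score ----------------------------------------------------
  binreg <- NULL
  if (isTRUE(st$regulon_score)) {
    need(!is.null(expr), "regulon_score", "a normalized expression matrix")
    need(!is.null(regulons), "regulon_score", "regulon definitions")
    log_msg("regulon score")
    regs <- Filter(function(r) any(r$targets %in% rownames(expr)), regulons)
    aucm <- auc_matrix(expr, regs,
                       top_fraction = config$regulon_score$top_fraction)
    binreg <- binarize(aucm, method = config$regulon_score$binarize_method)
    d <- file.path(outdir, "regulon")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(
      data.frame(regulon = rownames(aucm), round(aucm, 4),
                 check.names = FALSE),
      file.path(d, "auc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(regulon = rownames(binreg$activity), binreg$activity,
                 check.names = FALSE),
      file.path(d, "binary_activity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    add_stage("regulon_score",
              file.path(d, c("auc.tsv", "binary_activity.tsv")))
  }

  ## ---- cluster ----------------------------------------------------------
  labels <- NULL
  if (isTRUE(st$cluster)) {
    need(!is.null(binreg) || !is.null(expr), "cluster",
         "a regulon or expression matrix")
    log_msg("cluster")
    m <- if (!is.null(binreg)) t(binreg$activity) else t(expr)
    cp <- config$cluster
    if (is.null(binreg)) cp$mode <- "expression"
    tree <- recursive_cluster(m, params = cp, seed = seed_stream(seed, 31))
    labels <- cluster_labels(tree)
    d <- file.path(outdir, "cluster")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(
      data.frame(cell_id = names(labels), leaf = unname(labels)),
      file.path(d, "leaf_assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    tree_json <- lapply(tree$nodes, function(nd) {
      nd$vote_prob <- if (!is.null(nd$vote_prob))
        round(unname(nd$vote_prob), 4)
      nd
    })
    jsonlite::write_json(list(params = tree$params, nodes = tree_json,
                              leaves = tree$leaves,
                              unassigned = tree$unassigned),
                         file.path(d, "tree.json"), auto_unbox = TRUE)
    add_stage("cluster",
              file.path(d, c("leaf_assignment.tsv", "tree.json")))
  }

  ## ---- markers ----------------------------------------------------------
  if (isTRUE(st$markers)) {
    need(!is.null(expr), "markers", "a normalized expression matrix")
    need(!is.null(labels), "markers", "cluster labels")
    log_msg("markers")
    lab <- labels[colnames(expr)]
    mk <- find_all_markers(expr, lab,
                           min_log2_diff = config$markers$min_log2_diff,
                           min_power = config$markers$min_power)
    d <- file.path(outdir, "markers")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(mk, file.path(d, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("markers", file.path(d, "markers.tsv"))
  }

  ## ---- score ------------------------------------------------------------
  if (isTRUE(st$score)) {
    need(!is.null(expr), "score", "a normalized expression matrix")
    log_msg("score")
    panels <- if (!is.null(truth)) truth$panels else default_panels()
    tab <- data.frame(cell_id = colnames(expr))
    for (p in names(panels)) {
      sc <- tryCatch(gene_set_score(expr, panels[[p]], p),
                     error = function(e) rep(NA_real_, ncol(expr)))
      tab[[p]] <- round(as.numeric(sc), 4)
    }
    d <- file.path(outdir, "score")
    dir.create(d, showWarnings = FALSE)
    utils::write.table(tab, file.path(d, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("score", file.path(d, "scores.tsv"))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$outdir <- outdir
  invisible(manifest)
}
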