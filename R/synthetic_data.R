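## Synthetic data with planted, known structure: truth models, UMI count
## matrices, toy reference transcriptomes and paired-end STRT-style FASTQ.
## Every downstream stage (quantification, QC, regulon scoring, clustering,
## markers, scores) can be validated against the planted ground truth.

#' Generator settings for synthetic single-cell data
#'
#' Collects the tunable knobs of the synthetic-data generator. Defaults are
#' chosen to emulate a multiplexed STRT-style UMI experiment at desk scale:
#' negative-binomial counts with moderate overdispersion, log-normal library
#' sizes, a handful of strong marker genes per group, transcription-factor
#' regulons whose targets are co-upregulated in designated groups, and gene
#' panels whose mean expression drifts monotonically along a latent
#' pseudotime.
#'
#' @param markers_per_group number of marker genes planted per major group.
#' @param marker_fold fold-effect (> 1) of a marker gene in its group.
#' @param subclusters_per_group number of nested subclusters per group
#'   (recycled across groups).
#' @param subcluster_markers_per_group markers distinguishing subclusters.
#' @param subcluster_fold fold-effect of subcluster markers.
#' @param regulons_per_group regulons planted per group (each active in
#'   exactly that group).
#' @param regulon_size genes per regulon target set (TF included).
#' @param regulon_fold fold-effect of regulon targets in active groups.
#' @param panel_size genes per score panel (E, M, S, G1S, G2M).
#' @param panel_baseline_boost multiplier on the baseline abundance of panel
#'   genes so panel scores sit well above the noise floor.
#' @param gradient_slopes named numeric: per-unit-pseudotime change of panel
#'   gene abundance on the log2 scale (negative = decreasing).
#' @param pseudotime_program_genes number of genes in the broad
#'   developmental program driven by pseudotime (disjoint from markers,
#'   regulons and panels). This program is what makes the first principal
#'   component of a cell group track its latent developmental time, as in
#'   real developmental data.
#' @param pseudotime_program_slope absolute per-unit-pseudotime log2 slope
#'   of program genes.
#' @param pseudotime_program_up_frac fraction of program genes that switch
#'   on (rather than off) with pseudotime; above 0.5 the per-cell
#'   detected-gene count rises along developmental time, which anchors the
#'   PC1 orientation convention used in scoring.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson counts.
#' @param library_size_mean expected total UMIs per cell.
#' @param library_size_cv coefficient of variation of (log-normal) library
#'   sizes.
#' @param baseline_sdlog spread (sdlog) of per-gene log-normal baseline
#'   abundances.
#' @return a list of class `orgsc_generator_config`.
#' @export
generator_config <- function(markers_per_group = 5,
                             marker_fold = 8,
                             subclusters_per_group = 1,
                             subcluster_markers_per_group = 3,
                             subcluster_fold = 4,
                             regulons_per_group = 5,
                             regulon_size = 10,
                             regulon_fold = 4,
                             panel_size = 8,
                             panel_baseline_boost = 4,
                             gradient_slopes = c(E = -2, M = -2, S = -2,
                                                 G1S = 0, G2M = 0),
                             pseudotime_program_genes = 100,
                             pseudotime_program_slope = 4,
                             pseudotime_program_up_frac = 0.6,
                             dispersion = 0.2,
                             library_size_mean = 20000,
                             library_size_cv = 0.4,
                             baseline_sdlog = 1) {
  assert_that(marker_fold > 1, "marker_fold must be > 1")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  assert_that(library_size_mean >= 1, "library_size_mean must be >= 1")
  structure(list(
    markers_per_group = markers_per_group,
    marker_fold = marker_fold,
    subclusters_per_group = subclusters_per_group,
    subcluster_markers_per_group = subcluster_markers_per_group,
    subcluster_fold = subcluster_fold,
    regulons_per_group = regulons_per_group,
    regulon_size = regulon_size,
    regulon_fold = regulon_fold,
    panel_size = panel_size,
    panel_baseline_boost = panel_baseline_boost,
    gradient_slopes = gradient_slopes,
    pseudotime_program_genes = pseudotime_program_genes,
    pseudotime_program_slope = pseudotime_program_slope,
    pseudotime_program_up_frac = pseudotime_program_up_frac,
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    baseline_sdlog = baseline_sdlog
  ), class = "orgsc_generator_config")
}

#' Generate a ground-truth model for synthetic single-cell data
#'
#' Plants a known structure over `n_cells` cells and `n_genes` genes:
#' `n_groups` major groups (optionally with nested subclusters), disjoint
#' marker-gene sets with stated fold-effects, TF regulons active in
#' designated groups, score-panel gene sets with pseudotime gradients, a
#' log-normal library size per cell and a log-normal baseline abundance per
#' gene. Pseudotime is uniform on [0, 1] within each group.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param n_groups number of major groups (>= 2).
#' @param config a [generator_config()].
#' @param seed integer seed; identical seeds give identical models.
#' @return an object of class `orgsc_truth` with fields `cells` (data.frame:
#'   cell_id, group, subcluster, pseudotime, library_size), `gene_ids`,
#'   `baseline`, `marker_genes`, `subcluster_markers`, `regulons`, `panels`,
#'   `gradient_slopes` and `config`.
#' @export
generate_truth_model <- function(n_cells, n_genes, n_groups,
                                 config = generator_config(), seed = 1) {
  assert_that(n_groups >= 2, "n_groups must be >= 2")
  cfg <- config
  set.seed(seed)

  panels <- c("E", "M", "S", "G1S", "G2M")
  n_sub <- rep_len(cfg$subclusters_per_group, n_groups)
  needed <- n_groups * cfg$markers_per_group +
    sum(pmax(n_sub - 1L, 0L) > 0L) * 0L +
    sum(ifelse(n_sub > 1L, n_sub * cfg$subcluster_markers_per_group, 0L)) +
    n_groups * cfg$regulons_per_group * cfg$regulon_size +
    length(panels) * cfg$panel_size +
    cfg$pseudotime_program_genes
  if (needed > n_genes) {
    stop_orgsc(sprintf(
      "generator config requires %d distinct structural genes but n_genes = %d",
      needed, n_genes))
  }

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  pool <- gene_ids
  take <- function(k) {
    g <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    g
  }

  groups <- paste0("G", seq_len(n_groups))
  marker_genes <- lapply(groups, function(g) take(cfg$markers_per_group))
  names(marker_genes) <- groups

  subcluster_markers <- list()
  for (gi in seq_len(n_groups)) {
    if (n_sub[gi] > 1L) {
      for (si in seq_len(n_sub[gi])) {
        subcluster_markers[[paste0(groups[gi], ".", si)]] <-
          take(cfg$subcluster_markers_per_group)
      }
    }
  }

  regulons <- list()
  for (gi in seq_len(n_groups)) {
    for (ri in seq_len(cfg$regulons_per_group)) {
      targets <- take(cfg$regulon_size)
      nm <- sprintf("reg_%s_%d", groups[gi], ri)
      regulons[[nm]] <- list(name = nm, tf = targets[1],
                             targets = targets, active_groups = groups[gi])
    }
  }

  panel_sets <- lapply(panels, function(p) take(cfg$panel_size))
  names(panel_sets) <- panels

  ## broad developmental program: genes switching on (or off) with
  ## pseudotime, mostly on, so PC1 of a group tracks developmental time
  ## and detected-gene count rises along it
  program_genes <- take(cfg$pseudotime_program_genes)
  n_up <- round(cfg$pseudotime_program_up_frac *
                  cfg$pseudotime_program_genes)
  program_slopes <- rep(c(cfg$pseudotime_program_slope,
                          -cfg$pseudotime_program_slope),
                        c(n_up, cfg$pseudotime_program_genes - n_up))
  names(program_slopes) <- program_genes

  ## cells: groups as equal as possible, subclusters round-robin within group
  group_of <- rep(groups, length.out = n_cells)
  group_of <- sort(group_of)
  sub_of <- character(n_cells)
  for (gi in seq_len(n_groups)) {
    idx <- which(group_of == groups[gi])
    sub_of[idx] <- paste0(groups[gi], ".",
                          rep(seq_len(n_sub[gi]), length.out = length(idx)))
  }
  pseudotime <- stats::runif(n_cells)

  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  meanlog <- log(cfg$library_size_mean) - sdlog^2 / 2
  lib <- pmax(1L, as.integer(round(stats::rlnorm(n_cells, meanlog, sdlog))))

  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = cfg$baseline_sdlog)
  names(baseline) <- gene_ids
  baseline[unlist(panel_sets)] <- baseline[unlist(panel_sets)] *
    cfg$panel_baseline_boost

  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    group = group_of,
    subcluster = sub_of,
    pseudotime = pseudotime,
    library_size = lib,
    stringsAsFactors = FALSE
  )

  structure(list(
    cells = cells,
    gene_ids = gene_ids,
    baseline = baseline,
    marker_genes = marker_genes,
    subcluster_markers = subcluster_markers,
    regulons = regulons,
    panels = panel_sets,
    gradient_slopes = cfg$gradient_slopes,
    program_slopes = program_slopes,
    config = cfg,
    seed = seed
  ), class = "orgsc_truth")
}

#' @export
print.orgsc_truth <- function(x, ...) {
  cat(sprintf(
    "orgsc truth model: %d cells, %d genes, %d groups, %d regulons, %d panels\n",
    nrow(x$cells), length(x$gene_ids), length(unique(x$cells$group)),
    length(x$regulons), length(x$panels)))
  invisible(x)
}

## Per-cell relative abundance matrix (genes x cells), columns sum to 1.
truth_relative_abundance <- function(truth) {
  cfg <- truth$config
  n_genes <- length(truth$gene_ids)
  n_cells <- nrow(truth$cells)
  rel <- matrix(truth$baseline, nrow = n_genes, ncol = n_cells,
                dimnames = list(truth$gene_ids, truth$cells$cell_id))
  grp <- truth$cells$group
  for (g in names(truth$marker_genes)) {
    rel[truth$marker_genes[[g]], grp == g] <-
      rel[truth$marker_genes[[g]], grp == g] * cfg$marker_fold
  }
  sub <- truth$cells$subcluster
  for (s in names(truth$subcluster_markers)) {
    if (any(sub == s)) {
      rel[truth$subcluster_markers[[s]], sub == s] <-
        rel[truth$subcluster_markers[[s]], sub == s] * cfg$subcluster_fold
    }
  }
  for (r in truth$regulons) {
    on <- grp %in% r$active_groups
    if (any(on)) {
      rel[r$targets, on] <- rel[r$targets, on] * cfg$regulon_fold
    }
  }
  t_pc <- truth$cells$pseudotime
  if (length(truth$program_slopes)) {
    ## up-genes (s > 0) rise towards their baseline, reached at t = 1;
    ## down-genes (s < 0) fall away from baseline; this keeps the per-cell
    ## abundance denominator nearly constant along pseudotime
    s_pr <- truth$program_slopes
    rel[names(s_pr), ] <- rel[names(s_pr), , drop = FALSE] *
      2^(outer(s_pr, t_pc) - pmax(s_pr, 0))
  }
  for (p in names(truth$panels)) {
    s <- if (p %in% names(truth$gradient_slopes))
      truth$gradient_slopes[[p]] else 0
    if (s != 0) {
      mult <- 2^(s * t_pc)
      rel[truth$panels[[p]], ] <-
        rel[truth$panels[[p]], , drop = FALSE] *
        matrix(mult, nrow = length(truth$panels[[p]]), ncol = n_cells,
               byrow = TRUE)
    }
  }
  sweep(rel, 2, colSums(rel), "/")
}

#' Simulate a UMI count matrix from a truth model
#'
#' Draws `counts[g, c]` from a negative binomial with mean
#' `library_size[c] * p(g, c)` where `p(g, c)` multiplies the gene baseline
#' by the cell's marker, regulon and pseudotime-gradient effects and
#' renormalizes per cell; the dispersion comes from the generator config
#' (variance = mu + dispersion * mu^2).
#'
#' @param truth an `orgsc_truth` from [generate_truth_model()].
#' @param seed integer seed.
#' @return a list with `counts` (genes x cells integer matrix) and `cells`
#'   (the truth's cell metadata).
#' @export
simulate_counts <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "orgsc_truth"))
  set.seed(seed)
  rel <- truth_relative_abundance(truth)
  mu <- sweep(rel, 2, truth$cells$library_size, "*")
  disp <- truth$config$dispersion
  n <- length(mu)
  counts <- if (disp > 0) {
    stats::rnbinom(n, size = 1 / disp, mu = as.vector(mu))
  } else {
    stats::rpois(n, lambda = as.vector(mu))
  }
  counts <- matrix(as.integer(counts), nrow = nrow(mu), ncol = ncol(mu),
                   dimnames = dimnames(mu))
  list(counts = counts, cells = truth$cells)
}

#' Simulate a binary regulon activity matrix with planted group structure
#'
#' Emulates the output of regulon scoring plus binarization directly: each
#' regulon is "on" with probability `p_active` in cells of its active groups
#' and `p_inactive` elsewhere. Used to exercise clustering on a
#' regulon-style binary matrix with known labels.
#'
#' @param truth an `orgsc_truth`.
#' @param p_active Bernoulli rate in active groups.
#' @param p_inactive Bernoulli rate elsewhere.
#' @param seed integer seed.
#' @return cells x regulons binary matrix (dimnames set).
#' @export
simulate_regulon_activity <- function(truth, p_active = 0.9,
                                      p_inactive = 0.05, seed = 1) {
  stopifnot(inherits(truth, "orgsc_truth"))
  set.seed(seed)
  n_cells <- nrow(truth$cells)
  regs <- truth$regulons
  act <- matrix(0L, nrow = n_cells, ncol = length(regs),
                dimnames = list(truth$cells$cell_id, names(regs)))
  for (j in seq_along(regs)) {
    p <- ifelse(truth$cells$group %in% regs[[j]]$active_groups,
                p_active, p_inactive)
    act[, j] <- stats::rbinom(n_cells, 1L, p)
  }
  act
}

#' Generate a toy reference transcriptome
#'
#' Random transcripts, one per gene, constructed so that no k-mer of length
#' `k` is shared between two transcripts (uniqueness is checked and
#' offending transcripts are redrawn), which makes exact k-mer gene
#' assignment unambiguous.
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @param length transcript length in nt (>= 200).
#' @param k k-mer size used for the uniqueness guarantee.
#' @param seed integer seed.
#' @return an object of class `orgsc_reference`: list with `gene_ids` and
#'   `sequences` (named character vector).
#' @export
make_toy_reference <- function(gene_ids, length = 250, k = 21, seed = 1) {
  assert_that(length >= 200, "transcript length must be >= 200 nt")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  set.seed(seed)
  n <- base::length(gene_ids)
  seqs <- random_dna(n, length)
  for (iter in 1:50) {
    km <- lapply(seqs, function(s) {
      substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))
    })
    all_km <- unlist(km, use.names = FALSE)
    dup_km <- unique(all_km[duplicated(all_km)])
    if (!base::length(dup_km)) break
    bad <- which(vapply(km, function(x) any(x %in% dup_km), logical(1)))
    seqs[bad] <- random_dna(base::length(bad), length)
  }
  names(seqs) <- gene_ids
  structure(list(gene_ids = gene_ids, sequences = seqs),
            class = "orgsc_reference")
}

#' Generate a cell barcode whitelist
#'
#' Random fixed-length barcodes with a guaranteed minimum pairwise Hamming
#' distance, so that exact matching (and optional Hamming-1 rescue) is
#' unambiguous.
#'
#' @param n number of barcodes.
#' @param length barcode length (nt).
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of barcodes.
#' @export
generate_whitelist <- function(n, length = 8, min_dist = 3, seed = 1) {
  set.seed(seed)
  out <- character(0)
  tries <- 0L
  while (base::length(out) < n) {
    cand <- random_dna(1, length)
    tries <- tries + 1L
    if (tries > 100000L) stop_orgsc("could not build whitelist; relax min_dist")
    if (!base::length(out) ||
        all(hamming_dist(rep(cand, base::length(out)), out) >= min_dist)) {
      out <- c(out, cand)
    }
  }
  out
}

#' Default STRT read-2 layout
#'
#' Cell barcode at positions 1-8 and UMI at positions 9-16 of read 2 (the
#' sequenced orientation of a barcode-RT primer carrying an 8-nt cell
#' barcode followed by an 8-nt UMI and an oligo-dT stretch); offsets are
#' configurable because sequenced coordinates vary by protocol revision.
#'
#' @param bc_start,bc_len barcode start (1-based) and length.
#' @param umi_start,umi_len UMI start (1-based) and length.
#' @return a list of class `orgsc_layout`.
#' @export
read_layout <- function(bc_start = 1, bc_len = 8, umi_start = 9, umi_len = 8) {
  structure(list(bc_start = bc_start, bc_len = bc_len,
                 umi_start = umi_start, umi_len = umi_len),
            class = "orgsc_layout")
}

## Default template-switch oligo as it appears at the 5' end of read 1
## (DNA form of the TSO, riboguanosines read as G).
DEFAULT_TSO <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"

#' Simulate paired-end STRT FASTQ files from planted counts
#'
#' For each unit of `counts[g, c]` one molecule with a distinct 8-nt UMI is
#' created (UMIs drawn without replacement within each gene-cell pair, so
#' the planted count equals the number of distinct UMIs exactly). Each
#' molecule emits one read pair: read 2 carries barcode + UMI + poly-T; read
#' 1 carries the TSO, a uniformly positioned transcript fragment, and a
#' poly-A tail. A configurable fraction of extra pairs are PCR duplicates
#' (re-emitting an existing molecule), substitution errors hit fragment
#' bases at `error_rate` per base, and a fraction `n_read_rate` of reads get
#' 15% of fragment bases replaced by N.
#'
#' @param counts genes x cells integer matrix (rownames = gene ids,
#'   colnames = cell ids).
#' @param reference an `orgsc_reference`; every counted gene must be present.
#' @param whitelist barcodes, one per cell (in column order of `counts`).
#' @param layout an [read_layout()]; widths must match the whitelist.
#' @param error_rate per-base substitution probability on the fragment.
#' @param duplicate_rate fraction of emitted pairs that are PCR duplicates.
#' @param n_read_rate fraction of reads degraded with >10% N bases.
#' @param fragment_len transcript fragment length carried by read 1.
#' @param read2_len total read-2 length (poly-T padded).
#' @param seed integer seed; identical seeds give byte-identical FASTQ.
#' @param dir output directory (created if needed).
#' @return list with `r1`, `r2` (FASTQ paths), `whitelist_file`,
#'   `whitelist`, and `molecules` (data.frame gene/cell/umi).
#' @export
simulate_fastq <- function(counts, reference, whitelist,
                           layout = read_layout(),
                           error_rate = 0, duplicate_rate = 0,
                           n_read_rate = 0, fragment_len = 80,
                           read2_len = 50, seed = 1,
                           dir = tempfile("orgsc_fastq_")) {
  stopifnot(inherits(reference, "orgsc_reference"))
  if (length(whitelist) < ncol(counts)) {
    stop_orgsc("whitelist smaller than the number of cells")
  }
  if (any(nchar(whitelist) != layout$bc_len)) {
    stop_orgsc("layout error: whitelist barcode length does not match layout bc_len")
  }
  missing_genes <- setdiff(rownames(counts), reference$gene_ids)
  if (length(missing_genes)) {
    stop_orgsc("genes absent from reference: ",
               paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  set.seed(seed)
  whitelist <- whitelist[seq_len(ncol(counts))]

  nz <- which(counts > 0, arr.ind = TRUE)
  n_mol <- sum(counts[nz])
  gene_idx <- rep(nz[, 1], counts[nz])
  cell_idx <- rep(nz[, 2], counts[nz])
  ## distinct UMIs within each (gene, cell): sample integers without
  ## replacement from the 4^8 UMI space
  key <- paste(gene_idx, cell_idx, sep = "_")
  umi_int <- integer(n_mol)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    umi_int[idx] <- sample.int(65536L, length(idx), replace = FALSE) - 1L
  }
  umi <- int_to_dna(umi_int, 8L)

  molecules <- data.frame(
    gene = rownames(counts)[gene_idx],
    cell = colnames(counts)[cell_idx],
    umi = umi,
    stringsAsFactors = FALSE
  )

  ## PCR duplicates: re-emit existing molecules
  emit <- seq_len(n_mol)
  if (duplicate_rate > 0 && n_mol > 0) {
    n_dup <- round(duplicate_rate / (1 - duplicate_rate) * n_mol)
    emit <- c(emit, sample.int(n_mol, n_dup, replace = TRUE))
  }
  n_reads <- length(emit)
  em <- molecules[emit, , drop = FALSE]
  bc <- whitelist[match(em$cell, colnames(counts))]

  ## read 2: poly-T template with barcode and UMI spliced in
  span <- max(layout$bc_start + layout$bc_len,
              layout$umi_start + layout$umi_len) - 1L
  if (read2_len < span) {
    stop_orgsc("layout error: read2_len shorter than barcode+UMI span")
  }
  r2 <- rep(strrep("T", read2_len), n_reads)
  substr(r2, layout$bc_start, layout$bc_start + layout$bc_len - 1L) <- bc
  substr(r2, layout$umi_start, layout$umi_start + layout$umi_len - 1L) <- em$umi

  ## read 1: TSO + fragment + polyA
  tx <- reference$sequences[em$gene]
  tx_len <- nchar(tx)
  frag_len <- pmin(fragment_len, tx_len)
  start <- 1L + floor(stats::runif(n_reads) * (tx_len - frag_len + 1L))
  frag <- substr(tx, start, start + frag_len - 1L)

  if (error_rate > 0) {
    frag <- vapply(frag, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(ch)) < error_rate
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(DNA_ALPHABET, b), 1)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (n_read_rate > 0) {
    degrade <- stats::runif(n_reads) < n_read_rate
    frag[degrade] <- vapply(frag[degrade], function(s) {
      ch <- strsplit(s, "")[[1]]
      k <- ceiling(0.15 * length(ch))
      ch[sample.int(length(ch), k)] <- "N"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  r1 <- paste0(DEFAULT_TSO, frag, strrep("A", 25))

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("read%07d %s:%s", seq_len(n_reads), em$gene, em$cell)
  r1_path <- file.path(dir, "reads_R1.fastq")
  r2_path <- file.path(dir, "reads_R2.fastq")
  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)
  wl_path <- file.path(dir, "whitelist.txt")
  writeLines(whitelist, wl_path)

  list(r1 = r1_path, r2 = r2_path, whitelist_file = wl_path,
       whitelist = whitelist, molecules = molecules)
}
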