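test_that("truth model plants the requested group structure deterministically", {
  truth <- generate_truth_model(400, 500, 4, seed = 1)
  expect_length(unique(truth$cells$group), 4)
  expect_setequal(unique(truth$cells$group), paste0("G", 1:4))
  ## labels partition cells
  expect_equal(nrow(truth$cells), 400)
  expect_false(anyDuplicated(truth$cells$cell_id) > 0)
  ## pseudotime in [0, 1]
  expect_true(all(truth$cells$pseudotime >= 0 & truth$cells$pseudotime <= 1))
  ## at least one regulon active per group
  active <- unlist(lapply(truth$regulons, `[[`, "active_groups"))
  expect_setequal(unique(active), paste0("G", 1:4))
  ## every regulon's TF is a member of its own target set
  for (r in truth$regulons) expect_true(r$tf %in% r$targets)
  ## library sizes >= 1
  expect_true(all(truth$cells$library_size >= 1))
  ## determinism
  expect_identical(truth, generate_truth_model(400, 500, 4, seed = 1))
  expect_false(identical(truth$cells$pseudotime,
                         generate_truth_model(400, 500, 4,
                                              seed = 2)$cells$pseudotime))
})

test_that("structural gene allocation is disjoint", {
  truth <- generate_truth_model(200, 500, 3, seed = 7)
  sets <- c(truth$marker_genes,
            lapply(truth$regulons, `[[`, "targets"),
            truth$panels,
            list(program = names(truth$program_slopes)))
  all_genes <- unlist(sets)
  expect_false(anyDuplicated(all_genes) > 0)
})

test_that("a config demanding more structural genes than available errors", {
  cfg <- generator_config(markers_per_group = 4, regulons_per_group = 0,
                          panel_size = 0, pseudotime_program_genes = 0)
  expect_error(generate_truth_model(50, 10, 5, config = cfg, seed = 1),
               "structural genes")
})

test_that("simulated counts match negative-binomial moments for planted markers", {
  ## marker fold-effect 8, dispersion 0.2, 100 cells/group: the empirical
  ## in-group / out-group mean ratio over replicate simulations should sit
  ## near the planted fold (renormalization shrinks it slightly)
  truth <- generate_truth_model(
    200, 300, 2,
    config = generator_config(markers_per_group = 2, marker_fold = 8,
                              dispersion = 0.2),
    seed = 3)
  g1 <- truth$cells$group == "G1"
  ratios <- replicate(20, {
    cnt <- simulate_counts(truth, seed = sample.int(1e6, 1))$counts
    m <- truth$marker_genes$G1
    mean(rowMeans(cnt[m, g1, drop = FALSE])) /
      mean(rowMeans(cnt[m, !g1, drop = FALSE]))
  })
  expect_true(mean(ratios) >= 6 && mean(ratios) <= 10)
})

test_that("without planted effects the group means are symmetric", {
  cfg <- generator_config(markers_per_group = 0, regulons_per_group = 0,
                          subcluster_markers_per_group = 0, panel_size = 0,
                          pseudotime_program_genes = 0,
                          gradient_slopes = c(E = 0),
                          library_size_cv = 0, dispersion = 0.2)
  truth <- generate_truth_model(400, 100, 2, config = cfg, seed = 5)
  cnt <- simulate_counts(truth, seed = 6)$counts
  g1 <- truth$cells$group == "G1"
  m1 <- rowMeans(cnt[, g1]); m2 <- rowMeans(cnt[, !g1])
  ## log-ratio of group means centered at 0 within sampling error
  lr <- log2((m1 + 0.5) / (m2 + 0.5))
  expect_lt(abs(mean(lr)), 3 * stats::sd(lr) / sqrt(length(lr)))
})

test_that("total counts per cell track the planted library size", {
  truth <- generate_truth_model(300, 300, 2, seed = 11)
  cnt <- simulate_counts(truth, seed = 12)$counts
  ratio <- colSums(cnt) / truth$cells$library_size
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("toy reference transcripts share no assignment k-mers", {
  ref <- make_toy_reference(sprintf("g%02d", 1:20), length = 250, k = 21,
                            seed = 2)
  km <- unlist(lapply(ref$sequences, function(s) {
    substring(s, 1:(nchar(s) - 20), 21:nchar(s))
  }))
  expect_false(anyDuplicated(km) > 0)
  expect_true(all(nchar(ref$sequences) >= 200))
})

test_that("FASTQ emission gives one distinct UMI per planted count unit", {
  sc <- small_fastq_scenario(seed = 21)
  mol <- sc$fq$molecules
  tab <- table(paste(mol$gene, mol$cell))
  nz <- which(sc$counts > 0, arr.ind = TRUE)
  key <- paste(rownames(sc$counts)[nz[, 1]], colnames(sc$counts)[nz[, 2]])
  expect_identical(as.integer(tab[key]), as.integer(sc$counts[nz]))
  ## UMIs distinct within each (gene, cell)
  expect_false(anyDuplicated(mol) > 0)
})

test_that("PCR duplicates reuse molecules and do not change distinct-UMI counts", {
  sc <- small_fastq_scenario(seed = 31, duplicate_rate = 0.5)
  q <- quantify_strt(sc$fq$r1, sc$fq$r2, sc$wl, sc$ref)
  rec <- align_counts(q$counts, sc$counts, sc$wl)
  expect_identical_matrix(rec, sc$counts)
  ## more read pairs than molecules were emitted
  expect_gt(unname(q$log["input_pairs"]), nrow(sc$fq$molecules))
})

test_that("FASTQ generation is byte-identical for identical seeds", {
  sc1 <- small_fastq_scenario(seed = 41)
  sc2 <- small_fastq_scenario(seed = 41)
  expect_identical(readLines(sc1$fq$r1), readLines(sc2$fq$r1))
  expect_identical(readLines(sc1$fq$r2), readLines(sc2$fq$r2))
})

test_that("inconsistent layout and whitelist widths raise a layout error", {
  sc <- small_fastq_scenario(seed = 51)
  wrong_width <- generate_whitelist(ncol(sc$counts), length = 6, seed = 1)
  expect_error(simulate_fastq(sc$counts, sc$ref, wrong_width, seed = 1),
               "layout")
})

test_that("planted regulon activity separates active from inactive groups", {
  truth <- small_truth(seed = 61)
  act <- simulate_regulon_activity(truth, seed = 62)
  for (r in truth$regulons) {
    on <- truth$cells$group %in% r$active_groups
    expect_gt(mean(act[on, r$name]), mean(act[!on, r$name]))
  }
})
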