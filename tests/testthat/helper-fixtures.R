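## Shared fixtures, built in code at test time.

## small truth + counts used by several suites
small_truth <- function(seed = 1, n_cells = 120, n_genes = 400,
                        n_groups = 4, ...) {
  generate_truth_model(n_cells, n_genes, n_groups,
                       config = generator_config(...), seed = seed)
}

## a tiny quantification scenario: truth, counts, reference, whitelist
small_fastq_scenario <- function(seed = 1, n_cells = 12, n_genes = 50,
                                 lib = 150, ...) {
  truth <- generate_truth_model(
    n_cells, n_genes, 2,
    config = generator_config(markers_per_group = 2, regulons_per_group = 1,
                              regulon_size = 3, panel_size = 2,
                              pseudotime_program_genes = 5,
                              library_size_mean = lib),
    seed = seed)
  sim <- simulate_counts(truth, seed = seed + 1)
  ref <- make_toy_reference(rownames(sim$counts), seed = seed + 2)
  wl <- generate_whitelist(n_cells, seed = seed + 3)
  fq <- simulate_fastq(sim$counts, ref, wl, seed = seed + 4, ...)
  list(truth = truth, counts = sim$counts, ref = ref, wl = wl, fq = fq)
}

## align a quantified matrix (whitelist columns) back to planted cell ids
align_counts <- function(recovered, planted, whitelist) {
  colnames(recovered) <- colnames(planted)[match(colnames(recovered),
                                                 whitelist)]
  recovered[rownames(planted), colnames(planted)]
}

expect_identical_matrix <- function(a, b) {
  expect_identical(unname(as.matrix(a)), unname(as.matrix(b)))
}
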