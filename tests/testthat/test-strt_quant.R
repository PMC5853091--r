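test_that("barcode and UMI are read off the layout", {
  wl <- c("ACGTACGT", "TTTTCCCC")
  r2 <- paste0("ACGTACGT", "TTTTAAAA", strrep("T", 30))
  out <- extract_barcode_umi(r2, read_layout(), wl)
  expect_equal(out$barcode, "ACGTACGT")
  expect_equal(out$umi, "TTTTAAAA")
  expect_equal(out$reject_reason, "")
})

test_that("barcode rejection and Hamming-1 rescue follow the tie rule", {
  wl <- c("AAAAAAAA", "CCCCCCCC", "AAAATAAA")
  mk <- function(bc) paste0(bc, "GGGGGGGG", strrep("T", 20))
  ## unmatched without rescue
  out <- extract_barcode_umi(mk("AAAAAAAT"), read_layout(), wl)
  expect_equal(out$reject_reason, "barcode_unmatched")
  ## distance 1 from a unique entry: rescued
  out <- extract_barcode_umi(mk("AAACAAAA"), read_layout(), wl[1:2],
                             rescue = TRUE)
  expect_equal(out$barcode, "AAAAAAAA")
  ## equidistant from two entries: ambiguous rejection
  ## (AAAATAAA is distance 1 from both AAAAAAAA and AAAATAAA? use a true tie)
  out <- extract_barcode_umi(mk("AAAACAAA"), read_layout(),
                             c("AAAACAAT", "AAAACATA"), rescue = TRUE)
  expect_equal(out$reject_reason, "barcode_ambiguous")
  ## too-short read
  out <- extract_barcode_umi("ACGT", read_layout(), wl)
  expect_equal(out$reject_reason, "too_short")
})

test_that("read-1 trimming removes TSO prefix and polyA tail", {
  insert <- paste(rep(c("A", "C", "G", "T"), 12), collapse = "")  # 48 nt
  r1 <- paste0(orgsc:::DEFAULT_TSO, insert, strrep("A", 25))
  out <- trim_and_filter_read1(r1)
  expect_equal(out$seq, insert)
  expect_equal(out$reject_reason, "")
  ## no TSO, no polyA: untouched
  out2 <- trim_and_filter_read1(insert)
  expect_equal(out2$seq, insert)
})

test_that("reads with excess N or adapter contamination are rejected", {
  base <- strrep("ACGT", 15)
  ## 15% N
  n_read <- paste0(strrep("N", 9), substr(base, 10, 60))
  expect_equal(trim_and_filter_read1(n_read)$reject_reason, "low_quality")
  ## adapter substring
  bad <- paste0(substr(base, 1, 20), orgsc:::DEFAULT_ADAPTERS[["QP2"]],
                substr(base, 21, 40))
  expect_equal(trim_and_filter_read1(bad)$reject_reason, "adapter")
  ## too short after trimming
  short <- paste0("ACGTGC", strrep("A", 30))
  expect_equal(trim_and_filter_read1(short)$reject_reason, "too_short")
})

test_that("k-mer majority vote assigns exact and slightly mutated reads", {
  ref <- make_toy_reference(c("gA", "gB", "gC"), length = 250, seed = 3)
  idx <- build_kmer_index(ref, k = 21)
  frag <- substr(ref$sequences["gB"], 40, 119)  # exact 80-nt substring
  expect_equal(assign_gene(frag, idx), "gB")
  ## random sequence absent from the reference
  set.seed(4)
  rnd <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  expect_true(is.na(assign_gene(rnd, idx)))
  ## two substitutions in 80 nt leave a majority of intact 21-mers
  mutated <- frag
  substr(mutated, 10, 10) <- if (substr(frag, 10, 10) == "A") "C" else "A"
  substr(mutated, 60, 60) <- if (substr(frag, 60, 60) == "G") "T" else "G"
  expect_equal(assign_gene(mutated, idx), "gB")
  ## empty reference is a configuration error
  expect_error(build_kmer_index(structure(list(gene_ids = character(0),
                                               sequences = character(0)),
                                          class = "orgsc_reference")),
               "empty")
})

test_that("UMI deduplication is exact-string and scoped per gene", {
  a <- data.frame(barcode = c("c1", "c1", "c1"),
                  gene = c("g1", "g1", "g1"),
                  umi = c("U1", "U1", "U2"))
  m <- count_umis(a)
  expect_equal(m["g1", "c1"], 2L)
  ## same UMI on two genes counts once for each
  b <- data.frame(barcode = c("c1", "c1"), gene = c("g1", "g2"),
                  umi = c("U1", "U1"))
  m2 <- count_umis(b)
  expect_equal(unname(m2[, "c1"]), c(1L, 1L))
})

test_that("count_umis equals the distinct-set-cardinality oracle on random triples", {
  set.seed(42)
  n <- 10000
  a <- data.frame(barcode = sample(sprintf("c%02d", 1:20), n, TRUE),
                  gene = sample(sprintf("g%03d", 1:50), n, TRUE),
                  umi = sample(sprintf("U%03d", 1:200), n, TRUE),
                  stringsAsFactors = FALSE)
  m <- count_umis(a)
  ## independent oracle: per (gene, cell) cardinality of the UMI set
  oracle <- tapply(a$umi, list(a$gene, a$barcode),
                   function(u) length(unique(u)))
  oracle[is.na(oracle)] <- 0
  oracle <- oracle[rownames(m), colnames(m)]
  expect_equal(unname(m), unname(oracle), ignore_attr = TRUE)
  ## permutation invariance
  perm <- a[sample.int(n), ]
  expect_identical_matrix(count_umis(perm), m)
})

test_that("quantification reproduces planted counts at zero error rate", {
  sc <- small_fastq_scenario(seed = 71)
  q <- quantify_strt(sc$fq$r1, sc$fq$r2, sc$wl, sc$ref)
  rec <- align_counts(q$counts, sc$counts, sc$wl)
  expect_identical_matrix(rec, sc$counts)
  ## conservation: matrix total never exceeds input pairs; equality holds
  ## here because nothing was rejected or duplicated
  expect_equal(sum(q$counts), unname(q$log["input_pairs"]))
})

test_that("quantification accepts a FASTA path as reference", {
  sc <- small_fastq_scenario(seed = 81)
  fa <- tempfile(fileext = ".fasta")
  write_reference_fasta(sc$ref, fa)
  q <- quantify_strt(sc$fq$r1, sc$fq$r2, sc$wl, fa)
  rec <- align_counts(q$counts, sc$counts, sc$wl)
  expect_identical_matrix(rec, sc$counts)
})

test_that("substitution errors and degraded reads reduce but do not corrupt counts", {
  sc <- small_fastq_scenario(seed = 91, error_rate = 0.01, n_read_rate = 0.2)
  q <- quantify_strt(sc$fq$r1, sc$fq$r2, sc$wl, sc$ref)
  rec <- align_counts(q$counts, sc$counts, sc$wl)
  ## never overcounts
  expect_true(all(rec <= sc$counts))
  ## degraded reads show up in the rejection log
  expect_gt(unname(q$log["low_quality"]), 0)
})
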