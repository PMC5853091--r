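## STRT quantification: demultiplex read 2 by cell barcode, extract the UMI,
## trim and filter read 1 (TSO prefix, poly-A tail, N fraction, adapter
## contamination), assign reads to genes by unique k-mer majority vote
## against a toy reference, and count distinct UMIs per gene per cell.

## Adapter contamination defaults: the ISPCR amplification oligo and the
## library PCR primer, both of which can read through into the insert.
DEFAULT_ADAPTERS <- c(ISPCR = "AAGCAGTGGTATCAACGCAGAGT",
                      QP2 = "CAAGCAGAAGACGGCATACGA")

#' Extract cell barcode and UMI from read 2
#'
#' Vectorized over reads. The barcode must match the whitelist exactly;
#' optionally a barcode at Hamming distance 1 from a *unique* whitelist
#' entry is rescued (ties reject as ambiguous). Reads shorter than the
#' barcode+UMI span are rejected.
#'
#' @param read2_seq character vector of read-2 sequences.
#' @param layout an [read_layout()].
#' @param whitelist character vector of valid barcodes.
#' @param rescue logical; rescue barcodes at unique Hamming distance 1
#'   (default FALSE).
#' @return data.frame with columns `barcode`, `umi` (NA where rejected) and
#'   `reject_reason` ("" for accepted reads; otherwise "too_short",
#'   "barcode_unmatched" or "barcode_ambiguous").
#' @export
extract_barcode_umi <- function(read2_seq, layout = read_layout(),
                                whitelist, rescue = FALSE) {
  n <- length(read2_seq)
  span <- max(layout$bc_start + layout$bc_len,
              layout$umi_start + layout$umi_len) - 1L
  bc <- substr(read2_seq, layout$bc_start, layout$bc_start + layout$bc_len - 1L)
  umi <- substr(read2_seq, layout$umi_start,
                layout$umi_start + layout$umi_len - 1L)
  reason <- character(n)
  too_short <- nchar(read2_seq) < span
  reason[too_short] <- "too_short"

  hit <- bc %in% whitelist
  if (rescue) {
    miss <- which(!hit & !too_short)
    if (length(miss)) {
      ubad <- unique(bc[miss])
      ## substitution-only edit distance against the whitelist
      d <- utils::adist(ubad, whitelist,
                        costs = list(ins = 100, del = 100, sub = 1))
      n1 <- rowSums(d == 1)
      fix <- ifelse(n1 == 1L, whitelist[apply(d, 1, which.min)],
                    NA_character_)
      names(fix) <- ubad
      amb_bc <- ubad[n1 > 1L]
      orig <- bc[miss]
      rescued <- fix[orig]
      bc[miss[!is.na(rescued)]] <- rescued[!is.na(rescued)]
      hit[miss[!is.na(rescued)]] <- TRUE
      reason[miss[orig %in% amb_bc]] <- "barcode_ambiguous"
    }
  }
  reason[!hit & !too_short & reason == ""] <- "barcode_unmatched"
  rejected <- reason != ""
  data.frame(barcode = ifelse(rejected, NA_character_, bc),
             umi = ifelse(rejected, NA_character_, umi),
             reject_reason = reason,
             stringsAsFactors = FALSE)
}

## longest suffix-of-tso == prefix-of-read overlap, vectorized over reads
tso_trim <- function(seqs, tso, min_overlap = 10) {
  tlen <- nchar(tso)
  trim <- integer(length(seqs))
  for (ov in seq(min(tlen, max(nchar(seqs))), min_overlap)) {
    cand <- trim == 0L & nchar(seqs) >= ov
    if (!any(cand)) next
    tso_suffix <- substr(tso, tlen - ov + 1L, tlen)
    match <- cand & substr(seqs, 1L, ov) == tso_suffix
    trim[match] <- ov
  }
  substr(seqs, trim + 1L, nchar(seqs))
}

## length of trailing poly-A run allowing up to `mism` non-A bases
## (a non-A may not be the terminal base); returns run length per read
polya_run_length <- function(seqs, mism = 1L) {
  vapply(seqs, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    if (!length(ch) || ch[1] != "A") return(0L)
    bad <- 0L
    run <- 0L
    best <- 0L
    for (i in seq_along(ch)) {
      if (ch[i] == "A") {
        run <- i
        best <- run
      } else {
        bad <- bad + 1L
        if (bad > mism) break
      }
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

#' Trim and filter read 1
#'
#' Removes a TSO prefix (longest suffix-prefix overlap of at least
#' `min_tso_overlap` bases), then a trailing poly-A run of at least
#' `min_polya` bases (one internal mismatch allowed), then rejects reads
#' whose N fraction exceeds `max_n_frac`, that contain an adapter
#' substring, or that are shorter than `min_len` after trimming.
#'
#' @param read1_seq character vector of read-1 sequences.
#' @param tso TSO sequence expected as a read prefix.
#' @param adapters character vector of adapter sequences treated as
#'   contamination when found in the trimmed read.
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.10).
#' @param min_len minimum insert length after trimming (default 30).
#' @param min_tso_overlap minimum TSO suffix-prefix overlap to trim.
#' @param min_polya minimum trailing poly-A run length to trim.
#' @return data.frame with `seq` (trimmed; NA where rejected) and
#'   `reject_reason` ("" | "low_quality" | "adapter" | "too_short").
#' @export
trim_and_filter_read1 <- function(read1_seq, tso = DEFAULT_TSO,
                                  adapters = DEFAULT_ADAPTERS,
                                  max_n_frac = 0.10, min_len = 30,
                                  min_tso_overlap = 10, min_polya = 10) {
  s <- tso_trim(read1_seq, tso, min_tso_overlap)
  run <- polya_run_length(s)
  cut <- ifelse(run >= min_polya, run, 0L)
  s <- substr(s, 1L, nchar(s) - cut)

  n_frac <- (nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))) /
    pmax(nchar(s), 1L)
  reason <- character(length(s))
  reason[n_frac > max_n_frac] <- "low_quality"
  if (length(adapters)) {
    contaminated <- Reduce(`|`, lapply(adapters, function(a) {
      grepl(a, s, fixed = TRUE)
    }))
    reason[reason == "" & contaminated] <- "adapter"
  }
  reason[reason == "" & nchar(s) < min_len] <- "too_short"
  data.frame(seq = ifelse(reason == "", s, NA_character_),
             reject_reason = reason, stringsAsFactors = FALSE)
}

#' Build a unique k-mer index over a toy reference
#'
#' Indexes every k-mer occurring in exactly one transcript; k-mers shared
#' between transcripts are dropped so a hit is unambiguous evidence.
#'
#' @param reference an `orgsc_reference`.
#' @param k k-mer size (default 21).
#' @return an object of class `orgsc_kmer_index`.
#' @export
build_kmer_index <- function(reference, k = 21) {
  stopifnot(inherits(reference, "orgsc_reference"))
  if (!length(reference$gene_ids)) stop_orgsc("empty reference")
  km <- lapply(reference$sequences, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))
  })
  kmer <- unlist(km, use.names = FALSE)
  gene <- rep(seq_along(km), lengths(km))
  dup <- kmer[duplicated(kmer)]
  keep <- !(kmer %in% dup)
  structure(list(kmers = kmer[keep], gene_idx = gene[keep],
                 gene_ids = reference$gene_ids, k = k),
            class = "orgsc_kmer_index")
}

#' Assign reads to genes by k-mer majority vote
#'
#' Every k-mer of the read votes for the gene owning it in the unique-k-mer
#' index; the gene with the most votes wins. Zero hits, or two or more
#' genes tied at the top count, give `NA` (unassigned).
#'
#' @param seqs character vector of trimmed read sequences.
#' @param index an [build_kmer_index()] result.
#' @return character vector of gene ids (NA = unassigned).
#' @export
assign_gene <- function(seqs, index) {
  stopifnot(inherits(index, "orgsc_kmer_index"))
  k <- index$k
  n <- length(seqs)
  out <- rep(NA_character_, n)
  ok <- which(nchar(seqs) >= k)
  if (!length(ok)) return(out)
  sub <- seqs[ok]
  nk <- nchar(sub) - k + 1L
  ## vectorize k-mer extraction by offset rather than by read
  max_nk <- max(nk)
  km_by_off <- lapply(seq_len(max_nk), function(off) {
    valid <- which(nk >= off)
    list(read = valid, kmer = substr(sub[valid], off, off + k - 1L))
  })
  read_idx <- unlist(lapply(km_by_off, `[[`, "read"), use.names = FALSE)
  kmers <- unlist(lapply(km_by_off, `[[`, "kmer"), use.names = FALSE)
  hit <- match(kmers, index$kmers)
  has <- !is.na(hit)
  if (!any(has)) return(out)
  dt <- data.table::data.table(read = read_idx[has],
                               gene = index$gene_idx[hit[has]])
  votes <- dt[, .N, by = c("read", "gene")]
  data.table::setorderv(votes, c("read", "N"), c(1L, -1L))
  top <- votes[, {
    if (.N >= 2L && N[1L] == N[2L]) list(gene = NA_integer_)
    else list(gene = gene[1L])
  }, by = "read"]
  out[ok[top$read]] <- ifelse(is.na(top$gene), NA_character_,
                              index$gene_ids[top$gene])
  out
}

#' Count distinct UMIs per gene per cell
#'
#' Deduplication is exact-string and scoped per gene: within one (gene,
#' cell) pair, identical UMI strings count once; the same UMI on two genes
#' counts once for each.
#'
#' @param assignments data.frame with columns `barcode`, `gene`, `umi`.
#' @param gene_ids optional gene universe for the row order of the result.
#' @param cell_barcodes optional barcode universe for the column order.
#' @return genes x cells integer matrix of distinct-UMI counts.
#' @export
count_umis <- function(assignments, gene_ids = NULL, cell_barcodes = NULL) {
  a <- assignments[!is.na(assignments$gene) & !is.na(assignments$barcode), ,
                   drop = FALSE]
  dt <- data.table::data.table(barcode = a$barcode, gene = a$gene,
                               umi = a$umi)
  dt <- unique(dt, by = c("barcode", "gene", "umi"))
  cnt <- dt[, .N, by = c("gene", "barcode")]
  gene_ids <- gene_ids %||% sort(unique(cnt$gene))
  cell_barcodes <- cell_barcodes %||% sort(unique(cnt$barcode))
  m <- matrix(0L, nrow = length(gene_ids), ncol = length(cell_barcodes),
              dimnames = list(gene_ids, cell_barcodes))
  gi <- match(cnt$gene, gene_ids)
  ci <- match(cnt$barcode, cell_barcodes)
  keep <- !is.na(gi) & !is.na(ci)
  m[cbind(gi[keep], ci[keep])] <- cnt$N[keep]
  m
}

#' Quantify paired STRT FASTQ files into a UMI count matrix
#'
#' Full quantification path: barcode/UMI extraction from read 2, read-1
#' trimming and filtering, unique-k-mer gene assignment, and distinct-UMI
#' counting. Rejection counts at every stage are returned as a log.
#'
#' @param r1,r2 FASTQ paths for read 1 (cDNA) and read 2 (barcode+UMI).
#' @param whitelist character vector of valid cell barcodes.
#' @param reference an `orgsc_reference` (or a path to a FASTA file).
#' @param layout an [read_layout()].
#' @param k k-mer size for gene assignment.
#' @param rescue rescue Hamming-1 barcodes (default FALSE).
#' @param ... further arguments to [trim_and_filter_read1()].
#' @return list with `counts` (genes x cells integer matrix over the full
#'   whitelist and reference gene universe), `assignments` (accepted
#'   barcode/gene/umi triples) and `log` (named rejection counts).
#' @export
quantify_strt <- function(r1, r2, whitelist, reference,
                          layout = read_layout(), k = 21,
                          rescue = FALSE, ...) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_reference_fasta(reference)
  }
  fq1 <- read_fastq(r1)
  fq2 <- read_fastq(r2)
  stopifnot(length(fq1$seqs) == length(fq2$seqs))

  bcumi <- extract_barcode_umi(fq2$seqs, layout, whitelist, rescue = rescue)
  trim <- trim_and_filter_read1(fq1$seqs, ...)
  index <- build_kmer_index(reference, k = k)

  ok <- bcumi$reject_reason == "" & trim$reject_reason == ""
  gene <- rep(NA_character_, length(ok))
  gene[ok] <- assign_gene(trim$seq[ok], index)

  assignments <- data.frame(barcode = bcumi$barcode[ok & !is.na(gene)],
                            gene = gene[ok & !is.na(gene)],
                            umi = bcumi$umi[ok & !is.na(gene)],
                            stringsAsFactors = FALSE)
  counts <- count_umis(assignments, gene_ids = reference$gene_ids,
                       cell_barcodes = whitelist)
  log <- c(input_pairs = length(ok),
           table(bcumi$reject_reason[bcumi$reject_reason != ""]),
           table(trim$reject_reason[trim$reject_reason != ""]),
           unassigned_gene = sum(ok & is.na(gene)),
           accepted = nrow(assignments))
  list(counts = counts, assignments = assignments, log = log)
}
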