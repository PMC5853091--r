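## File-format glue: FASTQ/FASTA through Biostrings, sparse count matrices
## through MatrixMarket (Matrix::readMM/writeMM) with row/column TSVs,
## regulon and panel tables as TSV.

#' Write sequences as FASTQ (Phred+33, constant quality)
#' @param ids record identifiers.
#' @param seqs DNA sequences.
#' @param path output file.
#' @param qual quality character applied to every base (default "I").
#' @keywords internal
write_fastq <- function(ids, seqs, path, qual = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep(qual, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into sequences and qualities
#' @param path FASTQ file (optionally gzipped).
#' @return list with `ids`, `seqs`, `quals` (character vectors).
#' @export
read_fastq <- function(path) {
  ## suppress the benign "metadata columns dropped" warning
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(ids = names(x),
       seqs = as.character(x),
       quals = as.character(Biostrings::quality(x)))
}

#' Write a toy reference as FASTA
#' @param reference an `orgsc_reference`.
#' @param path output FASTA file.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference transcriptome from FASTA
#' @param path FASTA file; one record per gene, record name = gene id.
#' @return an `orgsc_reference`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  names(seqs) <- ids
  structure(list(gene_ids = ids, sequences = seqs),
            class = "orgsc_reference")
}

#' Write a count matrix as MatrixMarket MTX plus row/column TSVs
#'
#' @param counts genes x cells matrix (dense or sparse) with dimnames.
#' @param dir output directory; files `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` are written inside.
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param dir directory containing matrix.mtx, genes.tsv, barcodes.tsv.
#' @return genes x cells integer matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Read regulon definitions from TSV or JSON
#'
#' TSV format: columns `regulon`, `tf`, `target` (one target per row). JSON
#' format: array of objects with fields `name`, `tf`, `targets`, optional
#' `active_groups`. The TF is added to its own target set if absent.
#'
#' @param path file path (.tsv/.txt or .json).
#' @return named list of regulons (`name`, `tf`, `targets`).
#' @export
read_regulons <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    regs <- lapply(seq_len(nrow(raw)), function(i) {
      list(name = raw$name[i], tf = raw$tf[i],
           targets = union(raw$tf[i], raw$targets[[i]]))
    })
    names(regs) <- raw$name
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("regulon", "tf", "target") %in% names(tab)))
    regs <- lapply(split(tab, tab$regulon), function(d) {
      list(name = d$regulon[1], tf = d$tf[1],
           targets = union(d$tf[1], d$target))
    })
  }
  validate_regulons(regs)
  regs
}

#' Write regulons as TSV
#' @param regulons named list of regulons.
#' @param path output TSV.
#' @export
write_regulons <- function(regulons, path) {
  tab <- do.call(rbind, lapply(regulons, function(r) {
    data.frame(regulon = r$name, tf = r$tf, target = r$targets,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_regulons <- function(regulons) {
  for (r in regulons) {
    assert_that(length(r$targets) > 0,
                sprintf("regulon %s has an empty target set", r$name))
    assert_that(r$tf %in% r$targets,
                sprintf("regulon %s: TF %s not in its own target set",
                        r$name, r$tf))
  }
  invisible(TRUE)
}

#' Read score panels from TSV
#'
#' Format: columns `panel`, `gene`; one gene per row.
#' @param path TSV file.
#' @return named list of gene-id vectors.
#' @export
read_panels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("panel", "gene") %in% names(tab)))
  lapply(split(tab$gene, tab$panel), unique)
}

#' Write score panels as TSV
#' @param panels named list of gene-id vectors.
#' @param path output TSV.
#' @export
write_panels <- function(panels, path) {
  tab <- data.frame(panel = rep(names(panels), lengths(panels)),
                    gene = unlist(panels, use.names = FALSE),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default E/M/S and cell-cycle score panels
#'
#' Returns the gene panels shipped with the package
#' (`inst/extdata/panels_default.tsv`): epithelial (E-cadherin, tight- and
#' adherens-junction components, claudins, occludin, cytokeratins, type IV
#' collagen), mesenchymal (vimentin, FSP-1, alpha-SMA, fibronectin,
#' N-cadherin, type I/III collagens), a stemness panel drawn from the "stem
#' cell population maintenance" GO term, and the widely used core G1/S (43
#' genes) and G2/M (54 genes) cell-cycle sets, in mouse symbol case. The
#' panels are editable data, not assertions about any particular study's
#' exact lists.
#'
#' @return named list of gene-id vectors (E, M, S, G1S, G2M).
#' @export
default_panels <- function() {
  read_panels(system.file("extdata", "panels_default.tsv",
                          package = "orgsc", mustWork = TRUE))
}
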