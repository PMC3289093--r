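# Readers and writers for the pipeline's external formats. Sequence formats
# go through Biostrings; tables are plain TSV with headers.

#' Write DNA sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (phred+33)
#' @param reads Reads tibble (`read_id`, `sequence`, `quality`).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file (phred+33) into a reads tibble
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble::tibble(read_id = names(x),
                 sequence = as.character(x),
                 quality = as.character(Biostrings::quality(x)))
}

#' Write a tibble as TSV
#' @param x A data frame.
#' @param path Output file.
#' @export
write_tsv_file <- function(x, path) {
  drop <- vapply(x, is.list, logical(1))
  utils::write.table(x[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input file.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write DE results in the published table layout
#'
#' Columns mirror the RPKM-ratio tables: unigene id, reference (white) and
#' test (green) RPKM, their ratio, p, q and the call.
#'
#' @param de Tibble from [call_de()].
#' @param path Output file.
#' @export
write_de_tsv <- function(de, path) {
  out <- tibble::tibble(unigene_id = de$unigene_id,
                        rpkm_white = de$rpkm_ref,
                        rpkm_green = de$rpkm_test,
                        ratio = de$fold,
                        p = de$p, q = de$q, call = de$call)
  write_tsv_file(out, path)
}

#' Write a truth ledger to a pair of TSV files
#' @param truth Truth ledger list (`genes`, `reads`).
#' @param gene_path,read_path Output files.
#' @export
write_truth_tsv <- function(truth, gene_path, read_path) {
  write_tsv_file(truth$genes, gene_path)
  write_tsv_file(truth$reads, read_path)
  invisible(c(gene_path, read_path))
}
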