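## Plain-text I/O. All tables are tab-separated with a header row; matrices
## carry transcript ids in the first column. Writers use fixed formatting so
## identical inputs give byte-identical files.

#' Write a tab-separated table
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a count matrix as TSV
#'
#' First column `transcript`, remaining columns one per sample.
#'
#' @param counts numeric matrix with transcript rownames and sample colnames.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(transcript = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix from TSV
#'
#' @param path input path (first column transcript id, header = sample ids).
#' @return numeric matrix, transcripts x samples.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Write a genome as wrapped FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}
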