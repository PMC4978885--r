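#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file (gzip allowed).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a reads data frame
#'
#' @param path path to a FASTQ file (Phred+33; gzip allowed).
#' @param species optional species label attached to every read.
#' @return data.frame with columns `read_id`, `bases`, `qualities`.
#' @export
read_fastq <- function(path, species = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    bases = toupper(as.character(x)),
    qualities = as.character(S4Vectors::mcols(x)$qualities),
    species = species,
    stringsAsFactors = FALSE
  )
}

#' Write a reads data frame to FASTQ
#'
#' Reads without quality strings are written at a uniform placeholder
#' quality of Q40.
#'
#' @param reads data.frame with `read_id`, `bases` and optionally
#'   `qualities`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  check_reads_df(reads)
  qual <- reads$qualities
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(reads$bases[miss]),
                       function(n) strrep(rawToChar(as.raw(40L + 33L)), n),
                       character(1))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
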