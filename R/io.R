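#' Read a FASTQ file into a tibble
#'
#' Reads 4-line FASTQ records with Sanger/Phred+33 qualities. Other quality
#' dialects are rejected.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return a tibble with columns `id`, `seq`, `qual` (quality as a +33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- tibble(
    id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
  # validates +33 range
  purrr::walk(out$qual, qual_to_int)
  check_reads_tbl(out)
}

#' Write a read tibble to FASTQ
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads_tbl(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs a tibble with columns `id` and `seq`, or a named character
#'   vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                   seq = unname(seqs))
  }
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
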