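#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers: quality strings <-> integer score vectors
qual_to_int <- function(q) {
  v <- utf8ToInt(q) - 33L
  if (any(v < 0L | v > 60L)) {
    abort("quality string is not Sanger/Phred+33 encoded")
  }
  v
}

int_to_qual <- function(v) intToUtf8(v + 33L)

# sum of character mismatches between two equal-length int-coded strings
hamming_int <- function(a, b) sum(a != b)

check_reads_tbl <- function(reads, need_qual = TRUE) {
  if (!is.data.frame(reads)) abort("`reads` must be a data frame")
  need <- c("id", "seq", if (need_qual) "qual")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    abort(paste0("`reads` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (need_qual && any(nchar(reads$qual) != nchar(reads$seq))) {
    abort("malformed read: quality and sequence lengths differ")
  }
  if (any(nchar(reads$seq) == 0)) abort("malformed read: empty sequence")
  invisible(reads)
}

# seeded uniform integer in [lo, hi]
runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

random_dna <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}
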