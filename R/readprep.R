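#' Trimming parameters for Ribo-seq read cleanup
#'
#' Parameter bundle for [trim_read()]/[trim_reads()]. The defaults mirror the
#' single-end defaults commonly used for adapter/quality trimming of
#' ribosome-protected fragments: a 4-base sliding window at mean Q15, leading
#' and trailing base quality 3, and a 20-nt minimum length.
#'
#' @param adapters character vector of adapter sequences to clip from read
#'   3' ends (default: Illumina TruSeq adapter).
#' @param window_len sliding-window width in bases.
#' @param window_minq minimum mean Phred quality of a window; the read is
#'   truncated at the start of the first failing window.
#' @param leading_q leading bases with quality below this are removed.
#' @param trailing_q trailing bases with quality below this are removed.
#' @param min_len reads shorter than this after trimming are discarded.
#' @return an object of class `trim_params`.
#' @export
trim_params <- function(adapters = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                        window_len = 4L, window_minq = 15, leading_q = 3L,
                        trailing_q = 3L, min_len = 20L) {
  stopifnot(window_len >= 1, window_minq >= 0, leading_q >= 0,
            trailing_q >= 0, min_len >= 1, length(adapters) >= 1)
  structure(list(adapters = toupper(adapters),
                 adapter_ints = lapply(toupper(adapters), utf8ToInt),
                 window_len = as.integer(window_len),
                 window_minq = window_minq,
                 leading_q = as.integer(leading_q),
                 trailing_q = as.integer(trailing_q),
                 min_len = as.integer(min_len)),
            class = "trim_params")
}

# one pass of the 4-step trimming rule on int-coded seq + int quals;
# returns list(seq_int, qual_int) or NULL when discarded
trim_pass <- function(s, q, params) {
  n <- length(s)
  # (1) adapter clip: leftmost position whose suffix matches an adapter
  # prefix of length >= 7 with <= 1 mismatch
  clip <- n
  for (a in params$adapter_ints) {
    if (clip < 7) break
    last_start <- clip - 7L            # 0-based start of a length-7 suffix
    p <- 0L
    while (p <= last_start) {
      cl <- min(length(a), clip - p)
      if (sum(s[(p + 1L):(p + cl)] != a[1:cl]) <= 1L) {
        clip <- p
        break
      }
      p <- p + 1L
    }
  }
  if (clip < n) {
    s <- s[seq_len(clip)]
    q <- q[seq_len(clip)]
    n <- clip
  }
  if (n == 0L) return(NULL)
  # (2) leading / trailing low-quality bases
  lo <- 1L
  while (lo <= n && q[lo] < params$leading_q) lo <- lo + 1L
  hi <- n
  while (hi >= lo && q[hi] < params$trailing_q) hi <- hi - 1L
  if (hi < lo) return(NULL)
  s <- s[lo:hi]
  q <- q[lo:hi]
  n <- length(s)
  # (3) sliding window from the 5' end
  wl <- params$window_len
  if (n >= wl) {
    cs <- cumsum(c(0, q))
    means <- (cs[(wl + 1L):(n + 1L)] - cs[1:(n - wl + 1L)]) / wl
    bad <- which(means < params$window_minq)
    if (length(bad) > 0) {
      keep <- bad[1] - 1L              # truncate at the failing window's start
      if (keep == 0L) return(NULL)
      s <- s[seq_len(keep)]
      q <- q[seq_len(keep)]
    }
  }
  # (4) length filter
  if (length(s) < params$min_len) return(NULL)
  list(s = s, q = q)
}

#' Trim a single Ribo-seq read
#'
#' Applies, in order: adapter clipping (leftmost read suffix matching an
#' adapter prefix of length >= 7 with at most 1 mismatch), removal of
#' low-quality leading/trailing bases, 5'-to-3' sliding-window quality
#' truncation, and a minimum-length filter. The pass is iterated to a
#' fixpoint so that trimming is idempotent. The quality string is trimmed in
#' lockstep with the sequence.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param qual Phred+33 quality string, same length as `seq`.
#' @param params a [trim_params()] object.
#' @return a list with elements `seq` and `qual`, or `NULL` if the read is
#'   discarded.
#' @export
#' @examples
#' r <- trim_read("ACGTACGTAGATCGGAAGAGCACA", strrep("I", 24),
#'                trim_params(min_len = 5))
#' r$seq
trim_read <- function(seq, qual, params = trim_params()) {
  if (nchar(seq) != nchar(qual)) {
    abort("malformed read: quality and sequence lengths differ")
  }
  if (nchar(seq) == 0) abort("malformed read: empty sequence")
  s <- utf8ToInt(toupper(seq))
  q <- qual_to_int(qual)
  repeat {
    res <- trim_pass(s, q, params)
    if (is.null(res)) return(NULL)
    if (length(res$s) == length(s)) break
    s <- res$s
    q <- res$q
  }
  list(seq = intToUtf8(res$s), qual = int_to_qual(res$q))
}

#' Trim a table of Ribo-seq reads
#'
#' Vectorised [trim_read()]: trims every read and drops discarded ones,
#' preserving input order.
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param params a [trim_params()] object.
#' @param quiet suppress the per-stage log line.
#' @return the trimmed reads tibble (a subset of the input rows, with
#'   shortened `seq`/`qual`).
#' @export
trim_reads <- function(reads, params = trim_params(), quiet = FALSE) {
  check_reads_tbl(reads)
  trimmed <- purrr::map2(reads$seq, reads$qual, trim_read, params = params)
  keep <- !purrr::map_lgl(trimmed, is.null)
  out <- reads[keep, , drop = FALSE]
  out$seq <- purrr::map_chr(trimmed[keep], "seq")
  out$qual <- purrr::map_chr(trimmed[keep], "qual")
  if (!quiet) {
    message(sprintf("[trim] reads in=%d out=%d", nrow(reads), nrow(out)))
  }
  as_tibble(out)
}

#' Filter reads by full-length alignment to a reference
#'
#' Drops (or keeps) reads that have at least one gap-free full-length
#' placement on the reference or its reverse complement with at most
#' `max_mismatch` substitutions. With `max_mismatch = 2` and
#' `keep_matching = FALSE` this is the rRNA-depletion step; with
#' `max_mismatch = 0` it removes reads perfectly explained by the linear
#' genome, so that only reads *not* perfectly aligned to the genome survive
#' as the final unique Ribo-seq read set.
#'
#' @param reads tibble with columns `id`, `seq` (and optionally `qual`).
#' @param ref reference sequence: a single string, a named character vector
#'   of sequences, or a prebuilt [build_index()] object. Multiple sequences
#'   are concatenated with an N spacer so no read can align across records.
#' @param max_mismatch maximum substitutions for a placement to count.
#' @param keep_matching if `FALSE` (default) matching reads are removed; if
#'   `TRUE` only matching reads are kept.
#' @param k seed length for the internal index; defaults to the largest
#'   value compatible with the pigeonhole sensitivity guarantee for the
#'   shortest read (capped at 12).
#' @param quiet suppress the per-stage log line.
#' @return the surviving reads, a subsequence of the input.
#' @export
filter_by_reference <- function(reads, ref, max_mismatch = 0L,
                                keep_matching = FALSE, k = NULL,
                                quiet = FALSE) {
  check_reads_tbl(reads, need_qual = FALSE)
  if (nrow(reads) == 0) return(reads)
  if (!inherits(ref, "ref_index")) {
    if (length(ref) == 0 || all(nchar(ref) == 0)) abort("empty reference")
    refseq <- paste(ref, collapse = strrep("N", 60))
    if (is.null(k)) {
      k <- max(1L, min(12L, floor(min(nchar(reads$seq)) / (max_mismatch + 1))))
    }
    ref <- build_index(refseq, k = k)
  }
  hit <- purrr::map_lgl(reads$seq, function(s) {
    nrow(align_read(s, ref, max_mismatch = max_mismatch, find_any = TRUE)) > 0
  })
  out <- if (keep_matching) reads[hit, , drop = FALSE] else reads[!hit, , drop = FALSE]
  if (!quiet) {
    message(sprintf("[filter mm<=%d] reads in=%d out=%d", max_mismatch,
                    nrow(reads), nrow(out)))
  }
  as_tibble(out)
}
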