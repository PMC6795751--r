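# shared fixtures and independent oracles

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_reads <- function(seqs, ids = NULL, qual_char = "I") {
  tibble::tibble(
    id = ids %||% sprintf("r%03d", seq_along(seqs)),
    seq = seqs,
    qual = strrep(qual_char, nchar(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

`%p%` <- paste0

int_to_qual_test <- function(v) intToUtf8(v + 33L)

runif_int_test <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

# independent gap-free alignment oracle: Biostrings Hamming scan over every
# offset of both strands, excluding windows that touch N
oracle_align <- function(seq, ref, max_mismatch) {
  m <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else riboloop::revcomp(seq)
    mp <- Biostrings::matchPattern(q, ref, max.mismatch = max_mismatch,
                                   with.indels = FALSE, fixed = TRUE)
    for (s1 in BiocGenerics::start(mp)) {
      win <- substr(ref, s1, s1 + m - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      mm <- sum(strsplit(win, "")[[1]] != strsplit(q, "")[[1]])
      if (mm > max_mismatch) next   # matchPattern counts N leniently; recheck
      hits[[length(hits) + 1L]] <- tibble::tibble(
        start = s1 - 1L, end = s1 - 1L + m, strand = strand,
        mismatches = as.integer(mm))
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), mismatches = integer(0)))
  }
  dplyr::arrange(dplyr::distinct(out), start, strand)
}

# brute-force enumeration of the k-mers of all rotations of a circular
# sequence (oracle for the doubled-unit rotation property)
circular_kmers <- function(seq, k) {
  L <- nchar(seq)
  rot <- vapply(0:(L - 1L), function(r) {
    paste0(substr(seq, r + 1L, L), substr(seq, 1, r))
  }, character(1))
  unique(unlist(lapply(rot, function(s) substr(s, 1, k))))
}

# tiny deterministic pipeline bundle on disk; returns list(cfg, bundle, dir)
make_pipeline_fixture <- function(seed = 11, out = tempfile("run"), ...) {
  b <- simulate_dataset(sim_config(seed = seed, ...))
  d <- tempfile("bundle")
  write_sim_bundle(b, d)
  cfg <- pipeline_config(
    reads_fastq = file.path(d, "reads.fastq"),
    circ_fasta = file.path(d, "circs.fa"),
    out_dir = out,
    rrna_fasta = file.path(d, "rrna.fa"),
    genome_fasta = file.path(d, "genome.fa"),
    train_pos_fasta = file.path(d, "train_coding.fa"),
    train_neg_fasta = file.path(d, "train_noncoding.fa"),
    seed = seed)
  list(cfg = cfg, bundle = b, dir = d)
}
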