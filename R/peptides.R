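#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; codons are read from `seq[frame..]` (0-based
#' frame in 0/1/2), the trailing partial codon is dropped, stop codons are
#' rendered `*`, and any codon containing N translates to `X`.
#'
#' @param seq nucleotide string.
#' @param frame 0, 1 or 2.
#' @return amino-acid string (possibly empty).
#' @export
#' @examples
#' translate_frame("ATGAAATAA", 0)   # "MK*"
#' translate_frame("ATGAAATAA", 1)   # "*N"
translate_frame <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  n <- nchar(seq) - frame
  n_codons <- n %/% 3L
  if (n_codons < 1) return("")
  sub <- substr(seq, frame + 1L, frame + 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# maximal stop-free runs of an aa string: tibble(aa_start, aa_end) 0-based
# half-open in aa coordinates, plus the run strings
stop_free_runs <- function(aa) {
  if (nchar(aa) == 0) {
    return(tibble(aa_start = integer(0), aa_end = integer(0),
                  aa_seq = character(0)))
  }
  chunks <- strsplit(aa, "*", fixed = TRUE)[[1]]
  lens <- nchar(chunks)
  starts <- cumsum(c(0L, lens[-length(lens)] + 1L))
  keep <- lens > 0
  tibble(aa_start = starts[keep], aa_end = starts[keep] + lens[keep],
         aa_seq = chunks[keep])
}

#' Predict the translated peptide of one RMRJ
#'
#' Start-codon-independent peptide calling: in each reading frame the
#' translation is split at stop codons into maximal stop-free amino-acid
#' runs; runs whose nucleotide interval covers the junction (at least one
#' base on each side) and whose length is at least `min_aa` are candidates,
#' and the longest is returned (ties broken by lowest frame, then leftmost).
#' No ATG is required anywhere, reflecting that circRNA translation is often
#' not initiated at a canonical start codon.
#'
#' @param seq the RMRJ nucleotide sequence.
#' @param junction_offset 0-based position of the back-splice junction
#'   within `seq` (the junction lies between `junction_offset - 1` and
#'   `junction_offset`).
#' @param min_aa minimum peptide length in amino acids (default 10).
#' @return one-row tibble with `frame`, `nt_start`, `nt_end` (0-based
#'   half-open within `seq`), `aa_seq`, `spans_junction`; or a zero-row
#'   tibble if no qualifying run exists.
#' @export
predict_peptide <- function(seq, junction_offset, min_aa = 10L) {
  stopifnot(min_aa >= 1)
  empty <- tibble(frame = integer(0), nt_start = integer(0),
                  nt_end = integer(0), aa_seq = character(0),
                  spans_junction = logical(0))
  cand <- purrr::map(0:2, function(f) {
    runs <- stop_free_runs(translate_frame(seq, f))
    if (nrow(runs) == 0) return(NULL)
    runs |>
      mutate(frame = f,
             nt_start = f + 3L * .data$aa_start,
             nt_end = f + 3L * .data$aa_end) |>
      filter(nchar(.data$aa_seq) >= min_aa,
             .data$nt_start <= junction_offset - 1L,
             .data$nt_end >= junction_offset + 1L)
  })
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) return(empty)
  cand |>
    arrange(dplyr::desc(nchar(.data$aa_seq)), .data$frame, .data$nt_start) |>
    slice(1) |>
    mutate(spans_junction = TRUE) |>
    select("frame", "nt_start", "nt_end", "aa_seq", "spans_junction")
}

#' Predict translated peptides for a set of RMRJs
#'
#' Applies [predict_peptide()] to each RMRJ. When the virtual genome is
#' supplied, layout and circRNA-space coordinates of each call are added:
#' `circ_frame` is the reading frame relative to the doubled circRNA unit
#' and `unit_start`/`unit_end` the peptide interval in doubled-unit
#' coordinates (0-based; positions at or beyond the monomer length L lie
#' past the back-splice junction).
#'
#' @param rmrjs tibble from [compute_rmrjs()] (or
#'   [simulate_junction_coverage()]).
#' @param min_aa minimum peptide length.
#' @param vg optional [build_virtual_genome()] object for coordinate
#'   conversion; requires `rmrjs$start` to be layout coordinates.
#' @return tibble with one row per RMRJ that yields a call: `circ_id`,
#'   `nmj`, `frame`, `nt_start`, `nt_end`, `aa_seq`, `spans_junction`, plus
#'   unit coordinates when `vg` is given.
#' @export
predict_peptides <- function(rmrjs, min_aa = 10L, vg = NULL) {
  calls <- purrr::map(seq_len(nrow(rmrjs)), function(i) {
    p <- predict_peptide(rmrjs$seq[i], rmrjs$junction_offset[i],
                         min_aa = min_aa)
    if (nrow(p) == 0) return(NULL)
    p$circ_id <- rmrjs$circ_id[i]
    p$nmj <- if ("nmj" %in% names(rmrjs)) rmrjs$nmj[i] else NA_integer_
    if (!is.null(vg)) {
      u <- vg$units[match(rmrjs$circ_id[i], vg$units$circ_id), ]
      p$unit_start <- rmrjs$start[i] + p$nt_start - u$offset
      p$unit_end <- rmrjs$start[i] + p$nt_end - u$offset
      p$circ_frame <- p$unit_start %% 3L
    }
    p
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble(circ_id = character(0), nmj = integer(0),
                  frame = integer(0), nt_start = integer(0),
                  nt_end = integer(0), aa_seq = character(0),
                  spans_junction = logical(0))
    return(out)
  }
  select(out, "circ_id", "nmj", dplyr::everything())
}

#' Write peptide calls as FASTA and TSV
#'
#' FASTA headers carry `circ_id|frame|interval|NMJ`, the pipeline's final
#' record of translated circRNAs and their products.
#'
#' @param peptides tibble from [predict_peptides()].
#' @param fasta_path output FASTA of amino-acid sequences.
#' @param tsv_path optional TSV summary.
#' @return `fasta_path`, invisibly.
#' @export
write_peptides <- function(peptides, fasta_path, tsv_path = NULL) {
  ids <- sprintf("%s|frame%d|%d-%d|NMJ%d", peptides$circ_id, peptides$frame,
                 peptides$nt_start, peptides$nt_end, peptides$nmj)
  x <- Biostrings::AAStringSet(peptides$aa_seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(peptides), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}
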