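#' Build an exact-seed k-mer index of a reference
#'
#' Records every position of every N-free k-mer of the reference. Used by the
#' gap-free seed-and-verify aligner ([align_read()]) and the reference
#' filters in read preparation.
#'
#' @param ref reference nucleotide string (may contain N runs, e.g. the
#'   virtual-genome spacers; k-mers overlapping N are not indexed).
#' @param k seed length, 1-32. For full sensitivity at `m` mismatches, reads
#'   must be at least `(m + 1) * k` long.
#' @return an object of class `ref_index`.
#' @export
#' @examples
#' idx <- build_index("ACGTACGT", k = 4)
build_index <- function(ref, k = 12L) {
  k <- as.integer(k)
  if (length(ref) != 1 || is.na(ref) || nchar(ref) == 0) abort("empty reference")
  if (k < 1 || k > 32) abort("seed length k must be in 1..32")
  ref <- toupper(ref)
  n <- nchar(ref)
  if (k > n) abort("seed length k exceeds reference length")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  table <- new.env(parent = emptyenv())
  if (any(ok)) {
    list2env(split(starts[ok] - 1L, kmers[ok]), envir = table)  # 0-based starts
  }
  structure(list(ref = ref, ref_int = utf8ToInt(ref), n = n, k = k,
                 table = table),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> reference %d nt, k=%d, %d distinct seeds\n",
              x$n, x$k, length(ls(x$table))))
  invisible(x)
}

# candidate diagonal offsets for one oriented query (int-coded), via
# pigeonhole chunking: max_mismatch+1 disjoint chunks, each looked up by its
# leading k-mer
seed_candidates <- function(qchr, m, index, max_mismatch) {
  k <- index$k
  nchunks <- min(max_mismatch + 1L, m %/% k)
  if (nchunks < 1L) return(integer(0))
  bounds <- floor(m * (0:nchunks) / nchunks)
  cand <- integer(0)
  for (i in seq_len(nchunks)) {
    b <- bounds[i]                       # 0-based chunk start
    kmer <- substr(qchr, b + 1L, b + k)
    pos <- index$table[[kmer]]
    if (!is.null(pos)) cand <- c(cand, pos - b)
  }
  unique(cand[cand >= 0L & cand + m <= index$n])
}

#' Align a read gap-free to an indexed reference
#'
#' Finds all gap-free full-length placements of the read on the reference
#' (both strands) with at most `max_mismatch` substitutions, using pigeonhole
#' seeding: the read is partitioned into `max_mismatch + 1` disjoint chunks,
#' each chunk's leading k-mer is looked up exactly, and every candidate
#' diagonal is verified end-to-end. Placements overlapping any N base of the
#' reference are invalid (this is what confines virtual-genome alignments
#' within one circRNA unit). When the read is at least `(max_mismatch+1) * k`
#' long the pigeonhole argument guarantees that no placement within the
#' mismatch budget is missed.
#'
#' @param seq read sequence (a single string).
#' @param index a [build_index()] object.
#' @param max_mismatch maximum substitutions (default 2).
#' @param find_any stop at the first placement found (used by the read
#'   filters, where only existence matters).
#' @return tibble with columns `start`, `end` (0-based half-open layout
#'   interval, `end - start` = read length), `strand` ("+"/"-") and
#'   `mismatches`, sorted by (start, strand). For a "-" placement the
#'   reverse complement of the read matches the reference forward strand.
#' @export
align_read <- function(seq, index, max_mismatch = 2L, find_any = FALSE) {
  stopifnot(inherits(index, "ref_index"))
  seq <- toupper(seq)
  m <- nchar(seq)
  if (m < index$k) {
    warn(sprintf("read shorter than seed length %d: skipped", index$k))
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  Nint <- utf8ToInt("N")
  hits <- list(); hn <- 0L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else revcomp(seq)
    qi <- utf8ToInt(q)
    for (s in seed_candidates(q, m, index, max_mismatch)) {
      win <- index$ref_int[(s + 1L):(s + m)]
      if (any(win == Nint)) next
      mm <- sum(win != qi)
      if (mm <= max_mismatch) {
        hn <- hn + 1L
        hits[[hn]] <- c(s, strand_code = (strand == "-"), mm)
        if (find_any) break
      }
    }
    if (find_any && hn > 0L) break
  }
  if (hn == 0L) {
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  h <- do.call(rbind, hits)
  out <- tibble(start = as.integer(h[, 1]), end = as.integer(h[, 1]) + m,
                strand = ifelse(h[, 2] == 1, "-", "+"),
                mismatches = as.integer(h[, 3]))
  out <- distinct(out)
  arrange(out, .data$start, .data$strand)
}

#' Align a table of reads to an indexed reference
#'
#' @param reads tibble with columns `id` and `seq`.
#' @param index a [build_index()] object.
#' @param max_mismatch maximum substitutions per placement.
#' @return tibble of placements with a leading `read_id` column (see
#'   [align_read()]); reads without any placement contribute no rows.
#' @export
align_reads <- function(reads, index, max_mismatch = 2L) {
  check_reads_tbl(reads, need_qual = FALSE)
  res <- purrr::map(seq_len(nrow(reads)), function(i) {
    a <- align_read(reads$seq[i], index, max_mismatch = max_mismatch)
    if (nrow(a) > 0) a$read_id <- reads$id[i]
    a
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  mismatches = integer(0)))
  }
  select(out, "read_id", "start", "end", "strand", "mismatches")
}

#' Does an alignment span a back-splice junction?
#'
#' True iff the placement has at least `min_overhang` bases on each side of
#' the junction boundary J (which lies between layout positions J-1 and J).
#'
#' @param start,end 0-based half-open placement interval(s); vectorised.
#' @param junction layout coordinate(s) J of the junction.
#' @param min_overhang minimum bases required on each side (default 1).
#' @return logical vector.
#' @export
spans_junction <- function(start, end, junction, min_overhang = 1L) {
  stopifnot(min_overhang >= 1)
  start <= junction - min_overhang & end >= junction + min_overhang
}

#' Resolve placements to circRNA units
#'
#' Assigns each placement to the circRNA unit it falls in, discards reads
#' whose placements hit two or more distinct units (ambiguous between
#' circRNAs), and collapses the tandem-duplication shadow inside a unit: a
#' read matching entirely within one monomer copy appears at both `s` and
#' `s + L`; the junction-spanning placement is kept if one exists (it is
#' unique in the doubled unit), otherwise the leftmost.
#'
#' @param alns placement tibble from [align_reads()].
#' @param vg a [build_virtual_genome()] object.
#' @param min_overhang junction overhang used to identify spanning
#'   placements.
#' @return tibble with at most one row per read: `read_id`, `circ_id`,
#'   `start`, `end`, `strand`, `mismatches`, `spans` (logical).
#' @export
assign_to_units <- function(alns, vg, min_overhang = 1L) {
  stopifnot(inherits(vg, "virtual_genome"))
  if (nrow(alns) == 0) {
    return(tibble(read_id = character(0), circ_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0),
                  spans = logical(0)))
  }
  u <- vg$units
  ui <- findInterval(alns$start, u$offset)
  # gap-free N-excluding alignments cannot touch a spacer, so each placement
  # lies fully within its unit; assert rather than assume
  stopifnot(all(alns$start >= u$offset[ui]),
            all(alns$end <= u$offset[ui] + 2L * u$length[ui]))
  alns <- mutate(alns,
                 circ_id = u$circ_id[ui],
                 spans = spans_junction(.data$start, .data$end,
                                        u$junction[ui], min_overhang))
  alns |>
    group_by(.data$read_id) |>
    filter(n_distinct(.data$circ_id) == 1L) |>
    arrange(dplyr::desc(.data$spans), .data$start, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("read_id", "circ_id", "start", "end", "strand", "mismatches",
           "spans") |>
    arrange(.data$read_id)
}

#' Extract junction-covered regions (RMRJs)
#'
#' For each circRNA, collects the junction-spanning placements; their count
#' is the NMJ (number of mapped Ribo-seq reads on the junction). If NMJ is
#' strictly greater than `nmj_min` (default 3, i.e. at least 4 reads) the
#' merged interval `[min start, max end)` of those placements is emitted as
#' the circRNA's RMRJ together with its extracted sequence.
#'
#' @param placements per-read placements from [assign_to_units()].
#' @param vg a [build_virtual_genome()] object.
#' @param nmj_min NMJ threshold; an RMRJ needs NMJ > `nmj_min`.
#' @param min_overhang junction overhang for spanning placements.
#' @param plus_strand_only count only "+"-strand placements toward NMJ.
#' @param dedupe drop duplicate placements (same circRNA, interval and
#'   strand) before counting, as a PCR-duplicate guard. Default `FALSE`.
#' @return tibble sorted by `circ_id`: `circ_id`, `start`, `end` (layout
#'   interval), `nmj`, `junction_offset` (0-based junction position within
#'   `seq`), `seq`.
#' @export
compute_rmrjs <- function(placements, vg, nmj_min = 3L, min_overhang = 1L,
                          plus_strand_only = FALSE, dedupe = FALSE) {
  stopifnot(inherits(vg, "virtual_genome"))
  empty <- tibble(circ_id = character(0), start = integer(0),
                  end = integer(0), nmj = integer(0),
                  junction_offset = integer(0), seq = character(0))
  if (nrow(placements) == 0) return(empty)
  u <- vg$units
  sp <- placements
  if (!"spans" %in% names(sp)) {
    ui <- findInterval(sp$start, u$offset)
    sp$spans <- spans_junction(sp$start, sp$end, u$junction[ui], min_overhang)
  }
  sp <- filter(sp, .data$spans)
  if (plus_strand_only) sp <- filter(sp, .data$strand == "+")
  if (dedupe) sp <- distinct(sp, .data$circ_id, .data$start, .data$end,
                             .data$strand, .keep_all = TRUE)
  if (nrow(sp) == 0) return(empty)
  merged <- sp |>
    group_by(.data$circ_id) |>
    summarise(start = min(.data$start), end = max(.data$end), nmj = n(),
              .groups = "drop") |>
    filter(.data$nmj > nmj_min)
  if (nrow(merged) == 0) return(empty)
  out <- merged |>
    left_join(select(u, "circ_id", "junction"), by = "circ_id") |>
    mutate(junction_offset = .data$junction - .data$start,
           seq = substring(vg$layout, .data$start + 1L, .data$end)) |>
    select("circ_id", "start", "end", "nmj", "junction_offset", "seq") |>
    arrange(.data$circ_id)
  if (any(grepl("N", out$seq, fixed = TRUE))) {
    abort("internal error: RMRJ sequence contains N")
  }
  out
}

#' Write RMRJs as FASTA and TSV
#'
#' @param rmrjs tibble from [compute_rmrjs()].
#' @param fasta_path output FASTA of RMRJ sequences.
#' @param tsv_path optional TSV with coordinates and NMJ counts.
#' @return `fasta_path`, invisibly.
#' @export
write_rmrjs <- function(rmrjs, fasta_path, tsv_path = NULL) {
  write_fasta(tibble(id = rmrjs$circ_id, seq = rmrjs$seq), fasta_path)
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(select(rmrjs, -"seq")), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Export placements as SAM
#'
#' Minimal single-end SAM against the virtual genome (or any reference):
#' 1-based POS, flag 0/16 for strand, `<len>M` CIGAR and an NM tag.
#'
#' @param placements tibble with `read_id`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @param reads tibble with `id`, `seq` (and optionally `qual`).
#' @param ref_name reference record name.
#' @param ref_len reference length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, reads, ref_name, ref_len, path) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len)))
  if (nrow(placements) > 0) {
    idx <- match(placements$read_id, reads$id)
    seqs <- reads$seq[idx]
    quals <- if ("qual" %in% names(reads)) reads$qual[idx] else
      strrep("I", nchar(seqs))
    neg <- placements$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    quals[neg] <- purrr::map_chr(strsplit(quals[neg], ""),
                                 ~ paste(rev(.x), collapse = ""))
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
      placements$read_id, ifelse(neg, 16L, 0L), ref_name,
      placements$start + 1L, placements$end - placements$start,
      seqs, quals, placements$mismatches))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import placements from a SAM file
#'
#' Accepts externally produced alignments against the virtual genome as an
#' alternative to the built-in aligner. Only gap-free primary records
#' (CIGAR `<len>M`) are imported; others are skipped with a warning.
#'
#' @param path SAM file path.
#' @return placement tibble compatible with [assign_to_units()].
#' @export
read_placements_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  mismatches = integer(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- purrr::map_int(f, ~ as.integer(.x[2]))
  cigar <- purrr::map_chr(f, 6)
  ok <- grepl("^[0-9]+M$", cigar) & bitwAnd(flag, 4L) == 0L
  if (any(!ok)) warn(sprintf("skipped %d non-gap-free/unmapped SAM records",
                             sum(!ok)))
  f <- f[ok]; flag <- flag[ok]
  nm <- purrr::map_int(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag) > 0) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  })
  start <- purrr::map_int(f, ~ as.integer(.x[4])) - 1L
  len <- as.integer(sub("M$", "", purrr::map_chr(f, 6)))
  tibble(read_id = purrr::map_chr(f, 1), start = start, end = start + len,
         strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"), mismatches = nm)
}
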