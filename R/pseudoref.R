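#' Build a junction-centered virtual genome
#'
#' Concatenates each candidate circRNA in tandem (exactly two copies), so the
#' back-splice junction of every circRNA lies at the midpoint of its unit,
#' and separates consecutive units by a run of `spacer` N bases. Because each
#' unit contains two full copies of the monomer, every junction-spanning read
#' of a circular transcript has a contiguous gap-free placement inside the
#' unit, and the N spacers prevent any alignment from bridging two circRNAs.
#'
#' @param circs candidate circRNAs: a tibble with columns `circ_id` and
#'   `seq`, or a named character vector of sequences.
#' @param spacer number of N bases between consecutive units (default 100,
#'   comfortably longer than ribosome-protected fragments, which are
#'   generally shorter than 50 bp).
#' @return an object of class `virtual_genome`: a list with `layout` (the
#'   reference string), `spacer`, and `units`, a tibble with one row per
#'   circRNA: `circ_id`, `length` (monomer length L), `offset` (0-based start
#'   of the unit in the layout) and `junction` (0-based layout index J such
#'   that the back-splice junction lies between positions J-1 and J;
#'   J = offset + L).
#' @export
#' @examples
#' vg <- build_virtual_genome(c(A = "ACGTAC", B = "GGGGCCCC"), spacer = 4)
#' vg$units
build_virtual_genome <- function(circs, spacer = 100L) {
  if (is.character(circs)) {
    circs <- tibble(circ_id = names(circs) %||% paste0("circ", seq_along(circs)),
                    seq = unname(circs))
  }
  if (!all(c("circ_id", "seq") %in% names(circs))) {
    abort("`circs` needs columns `circ_id` and `seq`")
  }
  if (nrow(circs) == 0) abort("empty circRNA list")
  if (anyDuplicated(circs$circ_id)) abort("duplicate circRNA ids")
  if (any(nchar(circs$seq) < 1)) abort("circRNA with empty sequence")
  spacer <- as.integer(spacer)
  if (spacer < 50L) {
    warn("spacer is shorter than the usual RPF length upper bound (50 nt)")
  }
  seqs <- toupper(circs$seq)
  if (any(grepl(strrep("N", max(spacer, 1L)), seqs, fixed = TRUE))) {
    abort("circRNA sequence contains an N-run at least as long as the spacer")
  }
  L <- nchar(seqs)
  offset <- cumsum(c(0L, head(2L * L + spacer, -1)))
  units <- tibble(circ_id = circs$circ_id, length = L,
                  offset = offset, junction = offset + L)
  layout <- paste(paste0(seqs, seqs), collapse = strrep("N", spacer))
  structure(list(layout = layout, spacer = spacer, units = units),
            class = "virtual_genome")
}

#' @export
print.virtual_genome <- function(x, ...) {
  cat(sprintf("<virtual_genome> %d circRNA unit(s), layout %d nt, spacer %d N\n",
              nrow(x$units), nchar(x$layout), x$spacer))
  print(x$units, ...)
  invisible(x)
}

#' Map layout positions back to circRNA coordinates
#'
#' Inverse of the virtual-genome layout: a layout position inside unit i maps
#' to `(circ_id_i, (pos - offset_i) mod L_i)`; positions inside an N spacer
#' map to `NA`.
#'
#' @param vg a [build_virtual_genome()] object.
#' @param pos integer vector of 0-based layout positions.
#' @return tibble with columns `pos`, `circ_id` (NA in spacers) and
#'   `mono_pos` (0-based position on the circRNA monomer, NA in spacers).
#' @export
locate_layout <- function(vg, pos) {
  stopifnot(inherits(vg, "virtual_genome"))
  pos <- as.integer(pos)
  if (any(pos < 0 | pos >= nchar(vg$layout))) {
    abort("layout position out of range")
  }
  i <- findInterval(pos, vg$units$offset)
  in_unit <- pos < vg$units$offset[i] + 2L * vg$units$length[i]
  tibble(
    pos = pos,
    circ_id = ifelse(in_unit, vg$units$circ_id[i], NA_character_),
    mono_pos = ifelse(in_unit,
                      (pos - vg$units$offset[i]) %% vg$units$length[i],
                      NA_integer_)
  )
}

#' Write a virtual genome to FASTA plus junction/unit tables
#'
#' @param vg a [build_virtual_genome()] object.
#' @param fasta_path output FASTA path.
#' @param bed_path optional BED path for junctions (0-based, each junction as
#'   a 1-bp feature `[J-1, J)`).
#' @param units_path optional TSV path for the unit map.
#' @param per_unit write one FASTA record per circRNA unit instead of a
#'   single record for the whole layout.
#' @return `fasta_path`, invisibly.
#' @export
write_virtual_genome <- function(vg, fasta_path, bed_path = NULL,
                                 units_path = NULL, per_unit = FALSE) {
  stopifnot(inherits(vg, "virtual_genome"))
  if (per_unit) {
    u <- vg$units
    recs <- substring(vg$layout, u$offset + 1L, u$offset + 2L * u$length)
    write_fasta(tibble(id = u$circ_id, seq = recs), fasta_path)
    chrom <- u$circ_id
    jstart <- u$length - 1L
  } else {
    write_fasta(c(virtual_genome = vg$layout), fasta_path)
    chrom <- rep("virtual_genome", nrow(vg$units))
    jstart <- vg$units$junction - 1L
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = chrom, start = jstart, end = jstart + 1L,
                      name = vg$units$circ_id)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(units_path)) {
    write.table(as.data.frame(vg$units), units_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
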