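test_that("build_index records every N-free k-mer with all positions", {
  idx <- build_index("ACGTACGT", k = 4)
  expect_equal(sort(idx$table[["ACGT"]]), c(0L, 4L))
  expect_equal(idx$table[["CGTA"]], 1L)
  idxN <- build_index("NNNN", k = 2)
  expect_equal(length(ls(idxN$table)), 0)
  expect_error(build_index("", 4), "empty")
  expect_error(build_index("ACG", 4), "exceeds")
  expect_error(build_index("ACGT", 0), "1..32")
})

test_that("align_read finds exact placements and respects the mismatch budget", {
  idx <- build_index("ACGTACGTACGT", k = 4)
  hits <- align_read("GTAC", idx, max_mismatch = 0)
  plus <- dplyr::filter(hits, strand == "+")
  expect_equal(plus$start, c(2L, 6L))
  expect_equal(plus$end - plus$start, c(4L, 4L))
  # GTAC is its own reverse complement, so "-" placements mirror "+"
  expect_equal(dplyr::filter(hits, strand == "-")$start, c(2L, 6L))

  none <- align_read("GGGG", build_index(strrep("A", 40), k = 4),
                     max_mismatch = 1)
  expect_equal(nrow(none), 0)

  expect_warning(short <- align_read("AC", idx, max_mismatch = 0), "shorter")
  expect_equal(nrow(short), 0)
})

test_that("align_read equals the brute-force Hamming oracle on random instances", {
  set.seed(21)
  for (i in 1:60) {
    ref <- rand_dna(sample(100:800, 1))
    mm <- sample(0:2, 1)
    len <- sample(20:50, 1)
    k <- max(1L, min(12L, len %/% (mm + 1L)))
    idx <- build_index(ref, k = k)
    read <- if (runif(1) < 0.6) {
      s <- sample(nchar(ref) - len, 1)
      x <- substr(ref, s, s + len - 1)
      nmut <- sample(0:mm, 1)
      for (p in sample(len, nmut)) {
        substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(x, p, p)), 1)
      }
      if (runif(1) < 0.5) revcomp(x) else x
    } else {
      rand_dna(len)
    }
    got <- align_read(read, idx, max_mismatch = mm)
    want <- oracle_align(read, ref, mm)
    expect_identical(as.data.frame(got), as.data.frame(want))
  }
})

test_that("alignments never overlap spacer N bases", {
  set.seed(22)
  vg <- build_virtual_genome(c(a = rand_dna(80), b = rand_dna(90)), spacer = 60)
  idx <- build_index(vg$layout, k = 6)
  # a read straddling the unit/spacer boundary has no valid placement
  probe <- substr(vg$layout, 150, 179)   # crosses into the N run
  expect_true(grepl("N", probe))
  expect_equal(nrow(align_read(gsub("N", "A", probe), idx, max_mismatch = 2)), 0)
})

test_that("spans_junction needs min_overhang bases on both sides", {
  expect_true(spans_junction(4L, 10L, 6L, 1L))
  expect_false(spans_junction(6L, 12L, 6L, 1L))   # starts at the junction
  expect_false(spans_junction(4L, 10L, 6L, 5L))
  expect_false(spans_junction(0L, 6L, 6L, 1L))    # ends at the junction
})

test_that("assign_to_units collapses shadows and discards cross-unit reads", {
  vg <- suppressWarnings(
    build_virtual_genome(c(A = "ACGTAC", B = "GGGGCCCC"), spacer = 10))
  idx <- build_index(vg$layout, k = 2)

  # monomer interior read [1,5): shadow placements at 1 and 7, neither spans
  r1 <- align_reads(make_reads("CGTA", "shadow"), idx, max_mismatch = 0)
  expect_setequal(dplyr::filter(r1, strand == "+")$start, c(1L, 7L))
  p1 <- assign_to_units(r1, vg)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$start, 1L)
  expect_false(p1$spans)

  # junction-spanning read [4,10): unique placement, kept
  r2 <- align_reads(make_reads("ACACGT", "span"), idx, max_mismatch = 0)
  p2 <- assign_to_units(r2, vg)
  expect_equal(p2$start, 4L)
  expect_true(p2$spans)

  # read matching two distinct units is ambiguous and dropped
  vg2 <- suppressWarnings(build_virtual_genome(
    c(A = "AAAATTTTCCC", B = "CCAAAATTTTGG"), spacer = 10))
  idx2 <- build_index(vg2$layout, k = 3)
  r3 <- align_reads(make_reads("AAAATTTT", "ambig"), idx2, max_mismatch = 0)
  expect_gt(dplyr::n_distinct(
    assign_to_units(r3[0, ], vg2)$circ_id), -1)  # empty input tolerated
  expect_equal(nrow(assign_to_units(r3, vg2)), 0)
})

test_that("spanning placements are preferred over leftmost shadows", {
  # read = junction-crossing rotation; also matches shifted inside the unit
  vg <- suppressWarnings(
    build_virtual_genome(c(A = "ACGTACGTACGT"), spacer = 10))  # L = 12
  idx <- build_index(vg$layout, k = 4)
  r <- align_reads(make_reads("GTACGTAC", "rot"), idx, max_mismatch = 0)
  expect_gt(nrow(r), 1)
  p <- assign_to_units(r, vg)
  expect_equal(nrow(p), 1)
  expect_true(p$spans)
  expect_true(p$start <= 11 && p$end >= 13)
})

test_that("RMRJ forms only above the NMJ threshold and merges intervals", {
  set.seed(23)
  mono <- rand_dna(120)
  vg <- build_virtual_genome(c(circ = mono), spacer = 100)
  idx <- build_index(vg$layout, k = 8)
  J <- 120L
  mk_span <- function(n, tag) {
    starts <- seq(J - 28L, J - 4L, length.out = n) |> round()
    make_reads(substring(vg$layout, starts + 1L, starts + 30L),
               sprintf("%s%02d", tag, seq_len(n)))
  }
  place <- function(reads) {
    assign_to_units(align_reads(reads, idx, max_mismatch = 2), vg)
  }
  expect_equal(nrow(compute_rmrjs(place(mk_span(3, "a")), vg, nmj_min = 3)), 0)
  rm4 <- compute_rmrjs(place(mk_span(4, "b")), vg, nmj_min = 3)
  expect_equal(nrow(rm4), 1)
  expect_equal(rm4$nmj, 4L)
  # interval is the union of the spanning placements and contains J
  expect_equal(rm4$start, J - 28L)
  expect_equal(rm4$end, J - 4L + 30L)
  expect_equal(rm4$junction_offset, 28L)
  expect_identical(rm4$seq,
                   substr(vg$layout, rm4$start + 1L, rm4$end))
  expect_false(grepl("N", rm4$seq))
})

test_that("NMJ is monotone in read depth: adding reads never removes an RMRJ", {
  set.seed(24)
  mono <- rand_dna(150)
  vg <- build_virtual_genome(c(c1 = mono), spacer = 100)
  idx <- build_index(vg$layout, k = 8)
  J <- 150L
  starts <- runif_int_test(12, J - 25L, J - 5L)
  reads <- make_reads(substring(vg$layout, starts + 1L, starts + 28L))
  place <- function(rr) assign_to_units(align_reads(rr, idx, 2), vg)
  for (n in 5:12) {
    r_small <- compute_rmrjs(place(reads[1:(n - 1), ]), vg)
    r_big <- compute_rmrjs(place(reads[1:n, ]), vg)
    expect_true(all(r_small$circ_id %in% r_big$circ_id))
    if (nrow(r_small) == 1) expect_gte(r_big$nmj, r_small$nmj)
  }
})

test_that("SAM export/import round-trips placements", {
  set.seed(25)
  vg <- build_virtual_genome(c(A = rand_dna(100)), spacer = 100)
  idx <- build_index(vg$layout, k = 8)
  starts <- c(10L, 50L, 90L)
  seqs <- substring(vg$layout, starts + 1L, starts + 25L)
  seqs[2] <- revcomp(seqs[2])
  reads <- make_reads(seqs)
  alns <- align_reads(reads, idx, max_mismatch = 0)
  p <- assign_to_units(alns, vg)
  sam <- tempfile(fileext = ".sam")
  write_sam(p, reads, "virtual_genome", nchar(vg$layout), sam)
  back <- read_placements_sam(sam)
  expect_equal(nrow(back), nrow(p))
  expect_setequal(back$start, p$start)
  expect_setequal(back$strand, p$strand)
  expect_true(all(back$mismatches == 0L))
})
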