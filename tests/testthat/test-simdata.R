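test_that("simulated bundles are byte-deterministic given the seed", {
  b1 <- simulate_dataset(sim_config(seed = 5))
  b2 <- simulate_dataset(sim_config(seed = 5))
  expect_identical(b1$circs, b2$circs)
  expect_identical(b1$reads, b2$reads)
  expect_identical(b1$train_pos, b2$train_pos)
  expect_identical(b1$truth, b2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_bundle(b1, d1); write_sim_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  b3 <- simulate_dataset(sim_config(seed = 6))
  expect_false(identical(b1$reads$seq, b3$reads$seq))
})

test_that("every truth-table claim verifies against the emitted records", {
  cfg <- sim_config(seed = 8, adapter_fraction = 0,
                    rrna_read_fraction = 0.15, linear_read_fraction = 0.1)
  b <- simulate_dataset(cfg)
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    mono <- b$circs$seq[b$circs$circ_id == tr$circ_id]
    expect_equal(nchar(mono), tr$length)
    doubled <- paste0(mono, mono)
    jr <- b$reads[grepl(paste0("^", tr$circ_id, "_jr"), b$reads$id), ]
    if (tr$translated) {
      # planted run: stop-free in its frame, flanked by in-frame stops
      run <- substr(doubled, tr$orf_start + 1, tr$orf_start + tr$orf_len)
      expect_false(grepl("*", translate_frame(run, 0), fixed = TRUE))
      expect_equal(substr(doubled, tr$orf_start - 2, tr$orf_start), "TAA")
      expect_equal(substr(doubled, tr$orf_start + tr$orf_len + 1,
                          tr$orf_start + tr$orf_len + 3), "TAA")
      expect_equal(tr$orf_frame, tr$orf_start %% 3)
      # junction reads exist, match the doubled unit and span the junction
      expect_equal(nrow(jr), tr$expected_junction_reads)
      for (r in jr$seq) {
        s <- as.integer(regexpr(r, doubled, fixed = TRUE)) - 1L
        expect_gte(s, 0)
        expect_lte(s, tr$length - 1L)
        expect_gte(s + nchar(r), tr$length + 1L)
      }
    } else {
      expect_equal(nrow(jr), 0)
      mr <- b$reads[grepl(paste0("^", tr$circ_id, "_mr"), b$reads$id), ]
      for (r in mr$seq) {
        expect_true(grepl(r, mono, fixed = TRUE))   # monomer, non-spanning
      }
    }
  }
  # contaminants come from the declared references
  rr <- b$reads[grepl("^rrna", b$reads$id), ]
  expect_gt(nrow(rr), 0)
  lin <- b$reads[grepl("^linear", b$reads$id), ]
  expect_true(all(vapply(lin$seq, function(s) {
    grepl(s, b$genome, fixed = TRUE) || grepl(revcomp(s), b$genome, fixed = TRUE)
  }, logical(1))))
})

test_that("infeasible planted-run geometry is an input error", {
  expect_error(
    simulate_dataset(sim_config(seed = 1, circ_len_range = c(60L, 60L),
                                orf_len_range = c(60L, 60L))),
    "infeasible")
})

test_that("order-0 chains reproduce a degenerate alphabet and seeds fix output", {
  m0 <- markov_fit(strrep("A", 200), order = 0)
  out <- markov_emulate(m0, 5, seed = 3)
  expect_true(all(grepl("^A+$", out)))
  e1 <- markov_emulate(markov_fit(c("ACGTACGGT", "TTGACCA"), 1), 10, seed = 9)
  e2 <- markov_emulate(markov_fit(c("ACGTACGGT", "TTGACCA"), 1), 10, seed = 9)
  expect_identical(e1, e2)
  expect_error(markov_fit(character(0)), "empty")
})

test_that("order-1 emission converges to the training dinucleotide table", {
  set.seed(45)
  train <- rand_dna(6000)
  fit <- markov_fit(train, order = 1)
  out <- markov_emulate(fit, 400, lengths = 2500, seed = 10)  # 1e6 bases
  difreq <- function(seqs) {
    di <- unlist(lapply(seqs, function(s) {
      substring(s, 1:(nchar(s) - 1), 2:nchar(s))
    }))
    tab <- table(factor(di, levels = as.vector(outer(c("A","C","G","T"),
                                                     c("A","C","G","T"),
                                                     paste0))))
    tab / sum(tab)
  }
  l1 <- sum(abs(difreq(train) - difreq(out)))
  expect_lt(l1, 0.02)
  # emitted lengths honor the requested length model
  expect_true(all(nchar(out) == 2500))
})

test_that("lengths default to the empirical training distribution", {
  set.seed(46)
  train <- replicate(30, rand_dna(sample(c(120L, 480L), 1)))
  out <- markov_emulate(markov_fit(train, 1), 60, seed = 2)
  expect_true(all(nchar(out) %in% c(120L, 480L)))
})

test_that("junction coverage records are internally consistent RMRJs", {
  set.seed(47)
  seqs <- setNames(replicate(20, rand_dna(sample(150:400, 1))),
                   sprintf("n%02d", 1:20))
  cov <- simulate_junction_coverage(seqs, depth = 6, seed = 1)
  L <- unname(nchar(seqs))
  expect_equal(cov$nmj, rep(6L, 20))
  expect_true(all(cov$start <= L - 1))          # >= 1 nt overhang each side
  expect_true(all(cov$end >= L + 1))
  expect_equal(cov$junction_offset, L - cov$start)
  expect_identical(cov$seq, substring(paste0(seqs, seqs),
                                      cov$start + 1, cov$end))
  expect_identical(simulate_junction_coverage(seqs, depth = 6, seed = 1), cov)
})

test_that("synthetic coding circRNAs carry centered junction-crossing runs", {
  set.seed(48)
  cc <- simulate_coding_circs(20)
  expect_true(all(cc$orf_start < cc$length))               # starts in copy 1
  expect_true(all(cc$orf_start + cc$orf_len > cc$length))  # crosses junction
  expect_true(all(cc$orf_len %% 3 == 0))
  # the junction motif sits across every junction
  motif <- paste(coding_grammar()$junction_motif, collapse = "")
  for (i in seq_len(nrow(cc))) {
    doubled <- paste0(cc$seq[i], cc$seq[i])
    local <- substr(doubled, cc$length[i] - 5, cc$length[i] + 9)
    expect_equal(local, motif)
  }
})
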