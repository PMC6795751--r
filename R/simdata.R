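#' The codon grammar used for synthetic coding sequence
#'
#' The generator's model of coding sequence is a stylised codon grammar:
#' every coding region draws its own restricted codon vocabulary
#' (`cycle_len` distinct sense codons, arranged in a random cycle) and
#' follows the cycle with probability `p_follow` per codon, otherwise
#' jumping to a uniform draw from its vocabulary. This is codon-usage and
#' codon-pair bias pushed to the point where short
#' ribosome-footprint-sized fragments are unambiguously coding-like: the
#' repeated codon-pair transitions produce the heavy recurrent word-network
#' edges that the classifier's thresholded features detect (a purely
#' topological signature, independent of which codons a region happens to
#' use), while an order-1 nucleotide Markov null fitted to such sequences
#' cannot reproduce the in-frame structure. Because each region has its own
#' vocabulary and cycle, different coding regions are globally distinct, so
#' short reads do not cross-map between circRNAs. The fixed
#' `junction_motif` (five codons, CTA GAT | AAC CTA AAG, junction between
#' the second and third) is written across every planted back-splice
#' junction: its boundaries place a TAG stop 2 nt 5' of the junction and a
#' TAA stop 7 nt 3' of it in the +1 frame, and a TAA stop directly across
#' the junction in the +2 frame, so the planted frame is always the unique
#' longest junction-covering stop-free run.
#'
#' @return a list with `codon_pool` (all sense codons), `cycle_len`,
#'   `p_follow`, and `junction_motif`.
#' @export
coding_grammar <- function() {
  bases <- c("A", "C", "G", "T")
  pool <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
  list(codon_pool = pool, cycle_len = 6L, p_follow = 0.9,
       junction_motif = c("CTA", "GAT", "AAC", "CTA", "AAG"))
}

# sample ncod codons: a fresh random codon cycle per call, followed with
# probability p_follow. Every cycle contains the junction-motif codons (so
# the motif is in-vocabulary for every coding region) plus region-specific
# codons, in a random cyclic order: regions share words but not word order,
# which keeps short reads from cross-mapping between coding regions.
sample_codon_run <- function(ncod, grammar = coding_grammar()) {
  core <- unique(grammar$junction_motif)
  extra <- sample(setdiff(grammar$codon_pool, core),
                  max(0L, grammar$cycle_len - length(core)))
  cyc <- sample(c(core, extra))
  succ <- setNames(cyc[c(2:length(cyc), 1L)], cyc)
  out <- character(ncod)
  out[1] <- sample(cyc, 1)
  for (i in seq_len(ncod)[-1]) {
    out[i] <- if (runif(1) < grammar$p_follow) {
      succ[[out[i - 1]]]
    } else {
      sample(cyc, 1)
    }
  }
  out
}

#' Generate synthetic coding sequences
#'
#' Concatenates codons sampled from the [coding_grammar()] and trims to the
#' target length; lengths are drawn uniformly from `len_range`. The result
#' is stop-free in frame 0.
#'
#' @param n number of sequences.
#' @param len_range `c(min, max)` sequence length in nt.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return named character vector of sequences.
#' @export
simulate_coding_seqs <- function(n, len_range = c(200L, 800L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grammar <- coding_grammar()
  lens <- runif_int(n, len_range[1], len_range[2])
  seqs <- purrr::map_chr(lens, function(L) {
    substr(paste(sample_codon_run(ceiling(L / 3), grammar), collapse = ""),
           1, L)
  })
  setNames(seqs, sprintf("coding%04d", seq_len(n)))
}

#' Generate synthetic coding circRNA sequences
#'
#' Each sequence is a random circRNA monomer carrying a planted
#' junction-crossing stop-free codon run (the [coding_grammar()] model)
#' centered on the back-splice junction, flanked by in-frame stop codons —
#' the same construction [simulate_dataset()] uses for its translated
#' circRNAs, and the positive training material for the classifier.
#'
#' @param n number of circRNAs.
#' @param circ_len_range monomer length range (nt).
#' @param orf_len_range planted run length range (nt).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return tibble with `circ_id`, `seq`, `length`, `orf_start` (0-based in
#'   doubled-unit coordinates), `orf_len`, `orf_frame`.
#' @export
simulate_coding_circs <- function(n, circ_len_range = c(200L, 800L),
                                  orf_len_range = c(60L, 300L),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    L <- runif_int(1, circ_len_range[1], circ_len_range[2])
    pl <- plant_orf(L, orf_len_range)
    tibble(circ_id = sprintf("codingcirc%04d", i), seq = pl$seq,
           length = L, orf_start = pl$orf_start, orf_len = pl$orf_len,
           orf_frame = pl$orf_start %% 3L)
  })
}

#' Generate uniform-random nucleotide sequences
#'
#' @inheritParams simulate_coding_seqs
#' @param base_probs sampling probabilities for A, C, G, T.
#' @return named character vector of sequences.
#' @export
simulate_random_seqs <- function(n, len_range = c(200L, 800L),
                                 base_probs = rep(0.25, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- runif_int(n, len_range[1], len_range[2])
  seqs <- purrr::map_chr(lens, random_dna, probs = base_probs)
  setNames(seqs, sprintf("random%04d", seq_len(n)))
}

#' Fit a visible order-k Markov chain to training sequences
#'
#' Estimates context -> next-base transition frequencies with pseudo-count 1
#' smoothing, the empirical distribution of initial contexts, and the
#' empirical length distribution. Emulates a null-sequence generator that
#' preserves the low-order sequence characteristics (nucleotide and
#' near-neighbour frequencies) of its training set.
#'
#' @param seqs character vector of training sequences (A/C/G/T; other
#'   letters are dropped).
#' @param order chain order, >= 0 (default 1).
#' @return an object of class `markov_model`.
#' @export
markov_fit <- function(seqs, order = 1L) {
  seqs <- as_seq_vector(seqs)
  if (length(seqs) == 0) abort("empty training set")
  order <- as.integer(order)
  stopifnot(order >= 0)
  bases <- c("A", "C", "G", "T")
  nctx <- 4L^order
  trans <- matrix(0, nrow = nctx, ncol = 4)
  init <- rep(0, nctx)
  lens <- integer(0)
  for (s in seqs) {
    v <- match(strsplit(toupper(s), "")[[1]], bases)
    v <- v[!is.na(v)]
    if (length(v) < order + 1L) next
    lens <- c(lens, length(v))
    if (order == 0L) {
      tab <- tabulate(v, 4)
      trans[1, ] <- trans[1, ] + tab
      next
    }
    # context code at position t (for emitting base t): bases t-order..t-1
    pw <- 4L^((order - 1L):0)
    ctx <- rep(0L, length(v) - order)
    for (j in seq_len(order)) {
      ctx <- ctx + (v[j:(length(v) - order + j - 1L)] - 1L) * pw[j]
    }
    ctx <- ctx + 1L
    nxt <- v[(order + 1L):length(v)]
    for (k in seq_along(ctx)) trans[ctx[k], nxt[k]] <- trans[ctx[k], nxt[k]] + 1
    init[ctx[1]] <- init[ctx[1]] + 1
  }
  if (length(lens) == 0) {
    abort("training sequences too short to estimate transitions")
  }
  # pseudo-count smoothing only where a context was never observed, so a
  # degenerate training set (e.g. poly-A) reproduces exactly
  unseen <- rowSums(trans) == 0
  trans[unseen, ] <- 1
  if (sum(init) == 0) init[] <- 1
  structure(list(order = order,
                 trans = trans / rowSums(trans),
                 init = init / sum(init),
                 lengths = lens),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> order %d, fitted on %d sequence(s), mean length %.0f\n",
              x$order, length(x$lengths), mean(x$lengths)))
  invisible(x)
}

#' Emit null sequences from a Markov chain
#'
#' Generates `n` sequences from a fitted (or freshly fitted) visible Markov
#' chain; lengths are drawn from the empirical training length distribution
#' unless given. Deterministic per seed. As `n` grows, the transition
#' frequencies of the emitted ensemble converge to the training frequencies.
#'
#' @param train a [markov_fit()] model, or training sequences to fit.
#' @param n number of sequences to emit.
#' @param order chain order (only used when `train` is raw sequences).
#' @param lengths optional integer vector of output lengths (recycled).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return named character vector of `n` sequences.
#' @export
markov_emulate <- function(train, n, order = 1L, lengths = NULL, seed = NULL) {
  fit <- if (inherits(train, "markov_model")) train else
    markov_fit(train, order = order)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ord <- fit$order
  lens <- if (is.null(lengths)) {
    sample(fit$lengths, n, replace = TRUE)
  } else {
    rep_len(as.integer(lengths), n)
  }
  lens <- pmax(lens, ord)
  maxlen <- max(lens)
  out_mat <- matrix(0L, nrow = n, ncol = maxlen)
  cum <- t(apply(fit$trans, 1, cumsum))
  if (ord > 0L) {
    ctx <- sample.int(length(fit$init), n, replace = TRUE, prob = fit$init)
    # decode initial context into the first `ord` bases (big-endian)
    c0 <- ctx - 1L
    for (j in ord:1) {
      out_mat[, j] <- c0 %% 4L + 1L
      c0 <- c0 %/% 4L
    }
  } else {
    ctx <- rep(1L, n)
  }
  drop_pow <- 4L^(ord - 1L)
  for (t in (ord + 1L):maxlen) {
    if (t > maxlen) break
    act <- which(lens >= t)
    if (length(act) == 0) break
    u <- runif(length(act))
    cm <- cum[ctx[act], , drop = FALSE]
    b <- 1L + (u > cm[, 1]) + (u > cm[, 2]) + (u > cm[, 3])
    out_mat[cbind(act, t)] <- b
    if (ord > 0L) {
      ctx[act] <- ((ctx[act] - 1L) %% drop_pow) * 4L + (b - 1L) + 1L
    }
  }
  seqs <- purrr::map_chr(seq_len(n), function(i) {
    paste(bases[out_mat[i, seq_len(lens[i])]], collapse = "")
  })
  setNames(seqs, sprintf("null%05d", seq_len(n)))
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic fixture generator: numbers
#' and lengths of candidate circRNAs, the planted junction-crossing coding
#' region, ribosome-protected-fragment read lengths (25-35 nt, mirroring
#' that RPFs are generally shorter than 50 bp), junction read depth, and
#' contamination/artifact rates.
#'
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param n_circ_translated,n_circ_untranslated numbers of circRNAs with and
#'   without a planted translated region.
#' @param circ_len_range circRNA monomer length range in nt.
#' @param orf_len_range planted junction-crossing coding-run length range in
#'   nt (multiples of 3 are drawn from within it).
#' @param reads_per_translated_junction junction-spanning reads planted per
#'   translated circRNA.
#' @param reads_per_untranslated_circ non-spanning reads per untranslated
#'   circRNA.
#' @param read_len_range RPF insert length range.
#' @param rrna_read_fraction,linear_read_fraction fractions of the total
#'   read set drawn from the rRNA reference and the linear genome.
#' @param adapter_fraction fraction of reads with 3' adapter read-through.
#' @param adapter adapter sequence appended to that fraction.
#' @param raw_read_len sequencer read length for adapter read-through reads.
#' @param qual_mean,qual_decay base-quality model: Phred score at the first
#'   cycle and linear per-cycle decay.
#' @param genome_len,rrna_len lengths of the synthetic linear genome and
#'   rRNA references.
#' @param n_train_pos,n_train_neg training-set sizes (coding / noncoding).
#' @param train_len_range training transcript length range.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_circ_translated = 5L, n_circ_untranslated = 5L,
                       circ_len_range = c(200L, 800L),
                       orf_len_range = c(60L, 300L),
                       reads_per_translated_junction = 8L,
                       reads_per_untranslated_circ = 8L,
                       read_len_range = c(25L, 35L),
                       rrna_read_fraction = 0.1,
                       linear_read_fraction = 0.1,
                       adapter_fraction = 0.3,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       raw_read_len = 50L,
                       qual_mean = 36, qual_decay = 0.15,
                       genome_len = 20000L, rrna_len = 3000L,
                       n_train_pos = 200L, n_train_neg = 200L,
                       train_len_range = c(200L, 800L)) {
  cfg <- as.list(environment())
  fr <- c(rrna_read_fraction, linear_read_fraction, adapter_fraction)
  if (any(fr < 0 | fr > 1) || rrna_read_fraction + linear_read_fraction > 1) {
    abort("read fractions must lie in [0,1] and rRNA+linear must sum to <= 1")
  }
  stopifnot(n_circ_translated >= 0, n_circ_untranslated >= 0,
            reads_per_translated_junction >= 0,
            circ_len_range[1] >= 50, orf_len_range[1] >= 24,
            read_len_range[1] >= 15)
  structure(cfg, class = "sim_config")
}

# Phred qualities for one read: linear decay plus noise, clamped
sim_quals <- function(len, mean, decay) {
  q <- round(mean - decay * (seq_len(len) - 1L) + rnorm(len, 0, 1.5))
  int_to_qual(pmin(pmax(q, 2L), 40L))
}

# plant a junction-crossing stop-free codon run into a random monomer.
# The run is centered on the junction (codon-aligned) so junction-local
# read windows fall inside it, and the fixed junction motif guarantees
# off-frame stops on both sides. Returns list(seq, orf_start (doubled
# coords), orf_len).
plant_orf <- function(L, orf_len_range, grammar = coding_grammar()) {
  if (L - 10L < orf_len_range[1]) {
    abort("infeasible geometry: planted coding run longer than circRNA allows")
  }
  m_max <- min(orf_len_range[2], L - 10L)
  m <- 3L * runif_int(1, ceiling(orf_len_range[1] / 3), m_max %/% 3L)
  jc <- m %/% 6L                    # junction sits after run codon jc (~middle)
  a <- 3L * jc                      # nt of the run 5' of the junction
  s0 <- L - a                       # run start in doubled-unit coordinates
  mono <- strsplit(random_dna(L), "")[[1]]
  cods <- sample_codon_run(m %/% 3L, grammar)
  cods[(jc - 1L):(jc + 3L)] <- grammar$junction_motif
  orf_chars <- strsplit(paste(cods, collapse = ""), "")[[1]]
  mono[(s0 + 0:(m - 1L)) %% L + 1L] <- orf_chars
  mono[(s0 - 3L + 0:2) %% L + 1L] <- c("T", "A", "A")   # in-frame 5' stop
  mono[(s0 + m + 0:2) %% L + 1L] <- c("T", "A", "A")    # in-frame 3' stop
  list(seq = paste(mono, collapse = ""), orf_start = s0, orf_len = m)
}

#' Simulate a complete benchmark fixture bundle
#'
#' Generates, deterministically per seed: a random linear genome and rRNA
#' reference; candidate circRNAs, a configured number of which carry a
#' planted junction-crossing stop-free codon run with coding-like codon
#' usage; Ribo-seq reads (junction-spanning reads for translated circRNAs,
#' non-spanning reads for untranslated ones, rRNA- and genome-derived
#' contaminants, 3' adapter read-through on a configured fraction); training
#' FASTA material (coding transcripts and order-1 Markov noncoding
#' sequences fitted to them); and a truth table tying every claim to the
#' emitted records.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `sim_bundle`: list with `genome`, `rrna`
#'   (strings), `circs`, `reads`, `truth` (tibbles), `train_pos`,
#'   `train_neg` (named character vectors) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- random_dna(cfg$genome_len)
  rrna <- random_dna(cfg$rrna_len)

  n_t <- cfg$n_circ_translated
  n_u <- cfg$n_circ_untranslated
  circ_rows <- list()
  truth_rows <- list()
  read_rows <- list()
  for (i in seq_len(n_t)) {
    id <- sprintf("circT%02d", i)
    L <- runif_int(1, cfg$circ_len_range[1], cfg$circ_len_range[2])
    pl <- plant_orf(L, cfg$orf_len_range)
    circ_rows[[id]] <- tibble(circ_id = id, seq = pl$seq)
    truth_rows[[id]] <- tibble(
      circ_id = id, translated = TRUE, length = L,
      orf_start = pl$orf_start, orf_len = pl$orf_len,
      orf_frame = pl$orf_start %% 3L,
      expected_junction_reads = cfg$reads_per_translated_junction)
    doubled <- paste0(pl$seq, pl$seq)
    d <- cfg$reads_per_translated_junction
    if (d > 0) {
      lens <- runif_int(d, cfg$read_len_range[1], cfg$read_len_range[2])
      starts <- runif_int(d, L - lens + 1L, L - 1L)     # spanning, >=1 nt overhang
      read_rows[[id]] <- tibble(
        id = sprintf("%s_jr%02d", id, seq_len(d)),
        seq = substring(doubled, starts + 1L, starts + lens),
        source = "junction")
    }
  }
  for (i in seq_len(n_u)) {
    id <- sprintf("circU%02d", i)
    L <- runif_int(1, cfg$circ_len_range[1], cfg$circ_len_range[2])
    s <- random_dna(L)
    circ_rows[[id]] <- tibble(circ_id = id, seq = s)
    truth_rows[[id]] <- tibble(
      circ_id = id, translated = FALSE, length = L,
      orf_start = NA_integer_, orf_len = NA_integer_,
      orf_frame = NA_integer_, expected_junction_reads = 0L)
    d <- cfg$reads_per_untranslated_circ
    if (d > 0) {
      lens <- runif_int(d, cfg$read_len_range[1], cfg$read_len_range[2])
      starts <- runif_int(d, 0L, L - lens)              # within the monomer
      read_rows[[id]] <- tibble(
        id = sprintf("%s_mr%02d", id, seq_len(d)),
        seq = substring(s, starts + 1L, starts + lens),
        source = "monomer")
    }
  }
  reads <- bind_rows(read_rows)
  n_signal <- nrow(reads)

  # contaminants sized so the configured fractions refer to the total set
  denom <- 1 - cfg$rrna_read_fraction - cfg$linear_read_fraction
  total <- if (denom > 0) round(n_signal / denom) else n_signal
  n_rrna <- round(total * cfg$rrna_read_fraction)
  n_lin <- round(total * cfg$linear_read_fraction)
  sample_sub <- function(ref, n, tag) {
    if (n == 0) {
      return(tibble(id = character(0), seq = character(0),
                    source = character(0)))
    }
    lens <- runif_int(n, cfg$read_len_range[1], cfg$read_len_range[2])
    starts <- runif_int(n, 0L, nchar(ref) - lens)
    tibble(id = sprintf("%s_%04d", tag, seq_len(n)),
           seq = substring(ref, starts + 1L, starts + lens),
           source = tag)
  }
  rr <- sample_sub(rrna, n_rrna, "rrna")
  if (nrow(rr) > 0) {
    # a third of rRNA reads carry one substitution; still within the
    # 2-mismatch depletion budget
    mut <- runif(nrow(rr)) < 1 / 3
    rr$seq[mut] <- purrr::map_chr(rr$seq[mut], function(s) {
      p <- runif_int(1, 1L, nchar(s))
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      s
    })
  }
  lin <- sample_sub(genome, n_lin, "linear")
  if (nrow(lin) > 0) {
    flip <- runif(nrow(lin)) < 0.5
    lin$seq[flip] <- revcomp(lin$seq[flip])
  }
  reads <- bind_rows(reads, rr, lin)

  # adapter read-through on a fraction of reads, then base qualities
  with_adapter <- runif(nrow(reads)) < cfg$adapter_fraction
  reads$seq[with_adapter] <- substr(
    paste0(reads$seq[with_adapter], cfg$adapter), 1L, cfg$raw_read_len)
  reads$qual <- purrr::map_chr(nchar(reads$seq), sim_quals,
                               mean = cfg$qual_mean, decay = cfg$qual_decay)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]

  # positive training material mirrors the translated circRNAs (circRNA
  # sequences with a planted junction-crossing coding run); negatives are
  # order-1 Markov sequences fitted to the positives, i.e. composition-
  # matched noncoding stand-ins
  tp <- simulate_coding_circs(cfg$n_train_pos, cfg$train_len_range,
                              cfg$orf_len_range)
  train_pos <- setNames(tp$seq, tp$circ_id)
  train_neg <- markov_emulate(markov_fit(train_pos, order = 1L),
                              cfg$n_train_neg)
  names(train_neg) <- sprintf("noncoding%04d", seq_len(cfg$n_train_neg))

  structure(list(genome = genome, rrna = rrna,
                 circs = bind_rows(circ_rows),
                 reads = as_tibble(reads),
                 truth = bind_rows(truth_rows),
                 train_pos = train_pos, train_neg = train_neg,
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> %d circRNAs (%d translated), %d reads, %d+%d training seqs (seed %d)\n",
    nrow(x$circs), sum(x$truth$translated), nrow(x$reads),
    length(x$train_pos), length(x$train_neg), x$config$seed))
  invisible(x)
}

#' Write a simulated bundle to standard files
#'
#' Emits genome.fa, rrna.fa, circs.fa, reads.fastq, train_coding.fa,
#' train_noncoding.fa, truth.tsv and config.yaml under `dir`.
#'
#' @param bundle a [simulate_dataset()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(c(genome = bundle$genome), p("genome.fa"))
  write_fasta(c(rRNA = bundle$rrna), p("rrna.fa"))
  write_fasta(tibble(id = bundle$circs$circ_id, seq = bundle$circs$seq),
              p("circs.fa"))
  write_fastq(bundle$reads, p("reads.fastq"))
  write_fasta(bundle$train_pos, p("train_coding.fa"))
  write_fasta(bundle$train_neg, p("train_noncoding.fa"))
  write.table(as.data.frame(bundle$truth), p("truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(dir)
}

#' Simulate passing junction-read coverage for candidate sequences
#'
#' Treats each input sequence as a candidate circRNA, samples
#' junction-spanning read placements across its doubled junction (at least
#' `min_overhang` nt on each side) and returns the resulting RMRJ records
#' directly, with NMJ equal to `depth`. Used to hand a candidate set
#' "passing" Ribo-seq junction evidence so that the classification stage is
#' the only discriminator — the construction behind null-sequence
#' false-discovery experiments.
#'
#' @param seqs named character vector of circRNA sequences, or tibble with
#'   `circ_id`, `seq`.
#' @param depth junction-spanning reads per sequence (default 8; must
#'   exceed the downstream NMJ threshold to "pass").
#' @param read_len_range RPF length range.
#' @param min_overhang minimum bases on each side of the junction.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return RMRJ tibble compatible with [classify_rmrjs()] and
#'   [predict_peptides()]: `circ_id`, `start`, `end` (doubled-unit
#'   coordinates), `nmj`, `junction_offset`, `seq`.
#' @export
simulate_junction_coverage <- function(seqs, depth = 8L,
                                       read_len_range = c(25L, 35L),
                                       min_overhang = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(seqs)) {
    seqs <- tibble(circ_id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                   seq = unname(seqs))
  }
  n <- nrow(seqs)
  L <- nchar(seqs$seq)
  stopifnot(depth >= 1, all(L > read_len_range[2]))
  lens <- matrix(runif_int(n * depth, read_len_range[1], read_len_range[2]),
                 nrow = depth)
  J <- rep(L, each = depth)
  lo <- J - as.vector(lens) + min_overhang
  hi <- J - min_overhang
  starts <- matrix(runif_int(n * depth, lo, hi), nrow = depth)
  ends <- starts + lens
  s_min <- apply(starts, 2, min)
  e_max <- apply(ends, 2, max)
  doubled <- paste0(seqs$seq, seqs$seq)
  tibble(circ_id = seqs$circ_id,
         start = unname(s_min), end = unname(e_max), nmj = as.integer(depth),
         junction_offset = unname(L - s_min),
         seq = unname(substring(doubled, s_min + 1L, e_max)))
}
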