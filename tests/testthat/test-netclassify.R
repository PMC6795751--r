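test_that("word networks aggregate adjacent word pairs correctly", {
  g <- sequence_network("ATATAT", w = 3)
  expect_setequal(igraph::V(g)$name, c("ATA", "TAT"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 3)

  g2 <- sequence_network("AAAA", w = 3)       # self-adjacency excluded
  expect_equal(igraph::vcount(g2), 1)
  expect_equal(igraph::ecount(g2), 0)

  g3 <- sequence_network("ACG", w = 3)
  expect_equal(igraph::vcount(g3), 1)
  expect_equal(igraph::ecount(g3), 0)

  expect_equal(igraph::vcount(sequence_network("AC", w = 3)), 0)

  # words containing N contribute neither nodes nor edges
  g4 <- sequence_network("ACGTNACGT", w = 3)
  expect_false(any(grepl("N", igraph::V(g4)$name)))
})

test_that("total edge weight equals the count of distinct adjacent word pairs", {
  set.seed(31)
  for (i in 1:20) {
    s <- rand_dna(sample(10:200, 1))
    w <- sample(2:4, 1)
    g <- sequence_network(s, w = w)
    n <- nchar(s)
    words <- substring(s, 1:(n - w + 1), w:n)
    pairs <- sum(words[-length(words)] != words[-1])
    got <- if (igraph::ecount(g) > 0) sum(igraph::E(g)$weight) else 0
    expect_equal(got, pairs)
  }
})

test_that("network measures match hand-derived values on canonical graphs", {
  # single node, no edges
  g0 <- igraph::make_empty_graph(0, directed = FALSE) + igraph::vertices("A")
  expect_equal(unname(network_measures(g0)), rep(0, 6))

  # path A-B-C
  gp <- igraph::make_graph(c("A", "B", "B", "C"), directed = FALSE)
  igraph::E(gp)$weight <- 1
  mp <- network_measures(gp)
  expect_equal(unname(mp),
               c(4 / 3, 0, -1, 1 / 3, 4 / 3, 2 / 3), tolerance = 1e-12)

  # triangle
  gt <- igraph::make_graph(c("A", "B", "B", "C", "C", "A"), directed = FALSE)
  igraph::E(gt)$weight <- 1
  mt <- network_measures(gt)
  expect_equal(unname(mt), c(2, 1, 0, 0, 1, 1), tolerance = 1e-12)

  # "ATATAT" network: 2 nodes, 1 edge
  ma <- network_measures(sequence_network("ATATAT", 3))
  expect_equal(unname(ma), c(1, 0, 0, 0, 1, 1 / 2), tolerance = 1e-12)
})

test_that("feature vectors follow the threshold-iteration rule", {
  fv <- feature_vector("ATATAT", w = 3, T = 5)
  expect_length(fv, 30)
  base <- c(1, 0, 0, 0, 1, 1 / 2)
  expect_equal(unname(fv[1:6]), base)               # t = 0 sees the edge
  expect_equal(unname(fv[7:12]), base)              # weight 3 > 1
  expect_equal(unname(fv[13:18]), base)             # weight 3 > 2
  expect_equal(unname(fv[19:24]), rep(0, 6))        # t = 3 drops it
  expect_equal(unname(fv[25:30]), rep(0, 6))

  expect_length(feature_vector(rand_dna(100), w = 3, T = 10), 60)

  # all-weight-1 graphs zero out from iteration 1 on
  fv1 <- feature_vector("ACGTACGA", w = 3, T = 3)   # no repeated pair
  expect_true(any(fv1[1:6] != 0))
  expect_equal(unname(fv1[7:18]), rep(0, 12))
})

test_that("threshold-iteration edge sets are nested", {
  set.seed(32)
  for (i in 1:10) {
    g <- sequence_network(rand_dna(300), w = 3)
    prev <- NULL
    for (t in 0:5) {
      gt <- igraph::delete_edges(g, which(igraph::E(g)$weight <= t))
      ids <- apply(igraph::as_edgelist(gt), 1, paste, collapse = "|")
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("a separable toy problem reaches CV accuracy 1 and memorization works", {
  pos <- strrep("AT", 20 + 0:9)                 # one heavy edge
  neg <- replicate(10, rand_dna(45))
  set.seed(33)
  m <- train_classifier(pos, neg, method = "tree", cv_folds = 2, seed = 1)
  expect_equal(m$cv_accuracy, 1)
  pr <- predict(m, c(strrep("AT", 25), rand_dna(50)))
  expect_equal(pr$label, c("coding", "noncoding"))

  # an RMRJ identical to a training positive is labeled coding
  rmrj <- tibble::tibble(circ_id = "x", seq = pos[1], junction_offset = 10L)
  expect_equal(classify_rmrjs(rmrj, m)$label, "coding")
})

test_that("training-class errors and degenerate warnings are raised", {
  expect_error(train_classifier(character(0), c("ACGT")), "non-empty")
  expect_warning(
    train_classifier(rep("ATATATAT", 4), rep("ATATATAT", 4),
                     method = "tree", cv_folds = 2, seed = 1),
    "degenerate")
})

test_that("synthetic coding vs random sequences cross-validates above 0.90", {
  set.seed(34)
  pos <- simulate_coding_seqs(100)
  neg <- simulate_random_seqs(100)
  m <- train_classifier(pos, neg, seed = 2)
  expect_gte(m$cv_accuracy, 0.90)
})

test_that("the classifier is deterministic and order-invariant", {
  set.seed(35)
  pos <- simulate_coding_seqs(24, c(120, 260))
  neg <- simulate_random_seqs(24, c(120, 260))
  test_seqs <- c(simulate_coding_seqs(8, c(120, 260)),
                 simulate_random_seqs(8, c(120, 260)))
  m1 <- train_classifier(pos, neg, seed = 9)
  m2 <- train_classifier(pos, neg, seed = 9)
  perm <- sample(length(pos))
  m3 <- train_classifier(pos[perm], neg[rev(seq_along(neg))], seed = 9)
  p1 <- predict(m1, test_seqs)
  expect_identical(p1, predict(m2, test_seqs))
  expect_identical(p1, predict(m3, test_seqs))
  expect_identical(m1$cv_accuracy, m3$cv_accuracy)

  # serialization round-trip preserves predictions exactly
  f <- tempfile(fileext = ".rds")
  write_coding_model(m1, f)
  expect_identical(predict(read_coding_model(f), test_seqs), p1)
})

test_that("classify_rmrjs handles empty input and too-short sequences", {
  set.seed(36)
  m <- train_classifier(simulate_coding_seqs(12, c(100, 200)),
                        simulate_random_seqs(12, c(100, 200)),
                        method = "tree", seed = 1)
  empty <- tibble::tibble(circ_id = character(0), seq = character(0))
  expect_equal(nrow(classify_rmrjs(empty, m)), 0)
  short <- tibble::tibble(circ_id = "s", seq = "AC")
  expect_warning(out <- classify_rmrjs(short, m), "shorter")
  expect_equal(out$label, "noncoding")
})

test_that("tidy/glance/autoplot expose the fitted model", {
  set.seed(37)
  m <- train_classifier(simulate_coding_seqs(15, c(100, 200)),
                        simulate_random_seqs(15, c(100, 200)), seed = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 60)
  expect_true(all(c("feature", "threshold_iter", "measure", "importance")
                  %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_features, 60L)
  expect_equal(gl$n_coding, 15L)
  expect_s3_class(autoplot(m), "ggplot")
})
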