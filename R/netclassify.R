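#' Build the k-mer co-occurrence network of a sequence
#'
#' Nodes are the distinct words of length `w` occurring in the sequence
#' (overlapping, step 1; words containing N are skipped). Each pair of
#' consecutive words adds 1 to the weight of the undirected edge between
#' them; identical consecutive words (self-adjacency) contribute nothing.
#'
#' @param seq nucleotide string.
#' @param w word length (default 3).
#' @return an undirected weighted [igraph::graph] (possibly empty).
#' @export
#' @examples
#' g <- sequence_network("ATATAT", w = 3)   # ATA--TAT, weight 3
sequence_network <- function(seq, w = 3L) {
  w <- as.integer(w)
  stopifnot(w >= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < w) return(igraph::make_empty_graph(0, directed = FALSE))
  starts <- seq_len(n - w + 1L)
  words <- substring(seq, starts, starts + w - 1L)
  valid <- !grepl("N", words, fixed = TRUE)
  nodes <- unique(words[valid])
  g <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(nodes)
  if (n >= w + 1L) {
    a <- words[-length(words)]
    b <- words[-1]
    keep <- valid[-length(valid)] & valid[-1] & a != b
    if (any(keep)) {
      lo <- pmin(a[keep], b[keep])
      hi <- pmax(a[keep], b[keep])
      tab <- table(paste(lo, hi, sep = "|"))
      pairs <- strsplit(names(tab), "|", fixed = TRUE)
      el <- rbind(purrr::map_chr(pairs, 1), purrr::map_chr(pairs, 2))
      g <- igraph::add_edges(g, as.vector(el), weight = as.integer(tab))
    }
  }
  g
}

#' Topological measures of a sequence network
#'
#' Returns, in fixed order: mean degree; mean local clustering coefficient
#' (0 for nodes of degree < 2); degree assortativity (Pearson correlation of
#' endpoint degrees over edges, both orientations; 0 when undefined); mean
#' betweenness normalised by (n-1)(n-2)/2; mean unweighted shortest-path
#' length over ordered pairs within the largest connected component; and
#' edge count / node count. Degenerate graphs map to 0s.
#'
#' @param g an [igraph::graph], e.g. from [sequence_network()].
#' @return named numeric vector of length 6.
#' @export
measure_names <- c("mean_degree", "clustering", "assortativity",
                   "betweenness", "path_length", "edge_density")

network_measures <- function(g) {
  out <- setNames(numeric(6), measure_names)
  n <- igraph::vcount(g)
  if (n == 0) return(out)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  out["mean_degree"] <- mean(deg)
  out["edge_density"] <- m / n
  if (m == 0) return(out)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  out["clustering"] <- mean(cc)
  if (m >= 2) {
    e <- igraph::ends(g, igraph::E(g), names = FALSE)
    d1 <- deg[e[, 1]]; d2 <- deg[e[, 2]]
    x <- c(d1, d2); y <- c(d2, d1)
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      out["assortativity"] <- cor(x, y)
    }
  }
  if (n >= 3) {
    btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    out["betweenness"] <- mean(btw) / ((n - 1) * (n - 2) / 2)
  }
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  if (comp$csize[big] >= 2) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    dmat <- igraph::distances(sub, weights = NA)
    out["path_length"] <- mean(dmat[row(dmat) != col(dmat)])
  }
  out
}

#' Network feature vector under iterative edge thresholding
#'
#' For t = 0 ... T-1, retains only edges with weight > t, recomputes the six
#' [network_measures()] on the thresholded graph (nodes are kept), and
#' concatenates the results, giving a vector of length 6*T. Edge sets are
#' nested across iterations, so the vector traces how the network's core of
#' repeated word transitions decays.
#'
#' @param seq nucleotide string.
#' @param w word length (default 3).
#' @param T number of threshold iterations (default 10).
#' @return named numeric vector of length `6 * T`.
#' @export
feature_vector <- function(seq, w = 3L, T = 10L) {
  stopifnot(T >= 1)
  g <- sequence_network(seq, w = w)
  wts <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  out <- numeric(6L * T)
  mt <- NULL
  for (t in 0:(T - 1L)) {
    # nested edge sets: the graph only changes at thresholds that drop an
    # edge, so previous measures can be reused otherwise
    if (is.null(mt) || any(wts == t)) {
      gt <- if (length(wts) > 0) {
        igraph::delete_edges(g, which(wts <= t))
      } else g
      mt <- network_measures(gt)
    }
    out[(6L * t + 1L):(6L * t + 6L)] <- mt
  }
  names(out) <- paste0(rep(paste0("t", 0:(T - 1L)), each = 6L), "_",
                       rep(measure_names, T))
  out
}

#' Feature matrix for a set of sequences
#'
#' @param seqs character vector of sequences.
#' @param w word length.
#' @param T threshold iterations.
#' @return numeric matrix, one row per sequence, `6 * T` columns.
#' @export
feature_matrix <- function(seqs, w = 3L, T = 10L) {
  rows <- purrr::map(seqs, feature_vector, w = w, T = T)
  do.call(rbind, rows)
}

# deterministically sample one window per sequence (uniform length in
# `window`, uniform placement); sequences shorter than window[1] are used
# whole. RNG state of the caller is used.
sample_windows <- function(seqs, window) {
  lens <- nchar(seqs)
  wl <- runif_int(length(seqs), window[1], window[2])
  wl <- pmin(wl, lens)
  start <- runif_int(length(seqs), 0, lens - wl)   # 0-based
  substring(seqs, start + 1L, start + wl)
}

# one junction-coverage window per sequence: the merged interval of `depth`
# junction-spanning read placements on the doubled sequence — the same
# geometry as an RMRJ. Sequences too short for read placement are used
# whole. RNG state of the caller is used.
junction_windows <- function(seqs, depth, read_len) {
  lens <- nchar(seqs)
  out <- seqs
  long <- lens > read_len[2]
  if (any(long)) {
    cov <- simulate_junction_coverage(
      tibble(circ_id = as.character(seq_len(sum(long))), seq = seqs[long]),
      depth = depth, read_len_range = read_len)
    out[long] <- cov$seq
  }
  out
}

as_seq_vector <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "seq" %in% names(x)) return(x$seq)
  abort("expected a character vector of sequences or a data frame with a `seq` column")
}

#' Train a coding/noncoding sequence classifier
#'
#' Computes thresholded network feature vectors for positive (coding) and
#' negative (noncoding) training sequences, min-max scales them on the
#' training bounds, and fits either an information-gain decision tree
#' (`method = "tree"`, an rpart tree split on information) or a small forest
#' (`method = "forest"`, default, 25 trees). Stratified cross-validation
#' accuracy is computed on the same features. Training rows are internally
#' sorted into a canonical order, so permuting the input sequences does not
#' change the fitted model or its predictions; everything is deterministic
#' given `seed`.
#'
#' Because the thresholded features are length-sensitive, the classifier
#' should be trained on the same kind of object it will classify. `window`
#' controls this: `"junction"` (the pipeline default) makes each training
#' sequence contribute one junction-coverage window — the merged interval
#' of `window_depth` junction-spanning read placements on the doubled
#' sequence, i.e. exactly the geometry of an RMRJ; a numeric `c(min, max)`
#' samples one uniformly placed window per sequence with length drawn from
#' that range; `NULL` uses whole sequences.
#'
#' @param pos coding training sequences (character vector or tibble with a
#'   `seq` column).
#' @param neg noncoding training sequences.
#' @param w word length for the networks.
#' @param T threshold iterations.
#' @param cv_folds stratified cross-validation folds (>= 2).
#' @param seed integer seed controlling window sampling, fold assignment and
#'   forest bootstrap.
#' @param method `"forest"` (default) or `"tree"`.
#' @param trees number of trees for the forest.
#' @param window `NULL` (whole sequences), a numeric `c(min, max)`
#'   training-window length range, or `"junction"` for RMRJ-geometry
#'   junction-coverage windows.
#' @param window_depth junction-spanning placements per junction window
#'   (only for `window = "junction"`).
#' @param window_read_len read length range for junction windows.
#' @return an object of class `coding_model`.
#' @export
train_classifier <- function(pos, neg, w = 3L, T = 10L, cv_folds = 5L,
                             seed = 1L, method = c("forest", "tree"),
                             trees = 25L, window = NULL,
                             window_depth = 8L,
                             window_read_len = c(25L, 35L)) {
  method <- match.arg(method)
  pos <- as_seq_vector(pos)
  neg <- as_seq_vector(neg)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both training classes must be non-empty")
  }
  stopifnot(cv_folds >= 2)
  seqs <- c(pos, neg)
  label <- factor(rep(c("coding", "noncoding"), c(length(pos), length(neg))),
                  levels = c("coding", "noncoding"))
  # canonical order: label, then sequence string -> permutation invariance
  ord <- order(label, seqs)
  seqs <- seqs[ord]; label <- label[ord]
  if (!is.null(window)) {
    set.seed(seed)
    if (identical(window, "junction")) {
      seqs <- junction_windows(seqs, depth = window_depth,
                               read_len = as.integer(window_read_len))
    } else {
      stopifnot(is.numeric(window), length(window) == 2, window[1] >= 4,
                window[2] >= window[1])
      seqs <- sample_windows(seqs, as.integer(window))
    }
  }
  X <- feature_matrix(seqs, w = w, T = T)
  sc_min <- apply(X, 2, min)
  sc_max <- apply(X, 2, max)
  rng <- sc_max - sc_min
  Xs <- sweep(X, 2, sc_min)
  Xs <- sweep(Xs, 2, ifelse(rng > 0, rng, 1), "/")
  if (all(duplicated(Xs)[-1]) && nrow(Xs) > 1) {
    warn("degenerate separation: all training feature vectors are identical")
  }
  fit_one <- function(Xtr, ytr) {
    set.seed(seed)
    if (method == "forest") {
      randomForest::randomForest(x = as.data.frame(Xtr), y = ytr,
                                 ntree = trees, importance = TRUE)
    } else {
      df <- as.data.frame(Xtr)
      df$.label <- ytr
      fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(minsplit = 4,
                                                         cp = 0.001,
                                                         xval = 0))
      attr(fit$terms, ".Environment") <- baseenv()
      fit
    }
  }
  predict_one <- function(fit, Xte) {
    if (method == "forest") {
      predict(fit, as.data.frame(Xte), type = "response")
    } else {
      factor(predict(fit, as.data.frame(Xte), type = "class"),
             levels = levels(label))
    }
  }
  # stratified CV folds, deterministic per seed
  set.seed(seed)
  fold <- integer(length(label))
  for (lv in levels(label)) {
    i <- which(label == lv)
    fold[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
  }
  correct <- logical(length(label))
  for (f in seq_len(cv_folds)) {
    te <- fold == f
    if (!any(te) || length(unique(label[!te])) < 2) next
    pr <- predict_one(fit_one(Xs[!te, , drop = FALSE], label[!te]),
                      Xs[te, , drop = FALSE])
    correct[te] <- pr == label[te]
  }
  fit <- fit_one(Xs, label)
  fit$call <- NULL   # canonical serialisation: no call/env references
  structure(list(method = method, w = as.integer(w), T = as.integer(T),
                 trees = as.integer(trees), window = window,
                 seed = as.integer(seed),
                 scaling = list(min = sc_min, max = sc_max),
                 fit = fit, levels = levels(label),
                 n_train = c(coding = length(pos), noncoding = length(neg)),
                 cv_folds = as.integer(cv_folds),
                 cv_accuracy = mean(correct),
                 version = 1L),
            class = "coding_model")
}

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf(
    "<coding_model> %s (w=%d, T=%d%s), trained on %d coding / %d noncoding, CV accuracy %.3f\n",
    x$method, x$w, x$T,
    if (identical(x$window, "junction")) ", junction windows"
    else if (!is.null(x$window)) sprintf(", windows %d-%d nt", x$window[1], x$window[2])
    else "",
    x$n_train["coding"], x$n_train["noncoding"], x$cv_accuracy))
  invisible(x)
}

scale_features <- function(model, X) {
  rng <- model$scaling$max - model$scaling$min
  Xs <- sweep(X, 2, model$scaling$min)
  sweep(Xs, 2, ifelse(rng > 0, rng, 1), "/")
}

#' Predict coding potential of sequences
#'
#' @param object a [train_classifier()] model.
#' @param newdata character vector of sequences (or tibble with `seq`).
#' @param ... unused.
#' @return tibble with `label` ("coding"/"noncoding") and `score` (fraction
#'   of votes / class probability for "coding").
#' @export
predict.coding_model <- function(object, newdata, ...) {
  seqs <- as_seq_vector(newdata)
  if (length(seqs) == 0) {
    return(tibble(label = character(0), score = numeric(0)))
  }
  short <- nchar(seqs) < object$w + 1L
  if (any(short)) {
    warn(sprintf("%d sequence(s) shorter than w+1 labeled noncoding", sum(short)))
  }
  X <- scale_features(object, feature_matrix(seqs, w = object$w, T = object$T))
  prob <- if (object$method == "forest") {
    predict(object$fit, as.data.frame(X), type = "prob")[, "coding"]
  } else {
    predict(object$fit, as.data.frame(X), type = "prob")[, "coding"]
  }
  label <- ifelse(prob > 0.5, "coding", "noncoding")
  label[short] <- "noncoding"
  prob[short] <- 0
  tibble(label = unname(label), score = unname(prob))
}

#' Classify RMRJs and call translated circRNAs
#'
#' Labels each RMRJ coding or noncoding with a trained model. A circRNA
#' whose RMRJ is recognised as coding is identified as a translated circRNA.
#'
#' @param rmrjs tibble from [compute_rmrjs()] (columns `circ_id`, `seq`).
#' @param model a [train_classifier()] model.
#' @param full_sequence classify the full circRNA sequence instead of the
#'   RMRJ sequence; requires `circs`.
#' @param circs circRNA table (`circ_id`, `seq`), only for
#'   `full_sequence = TRUE`.
#' @return `rmrjs` with added `label` and `score` columns.
#' @export
classify_rmrjs <- function(rmrjs, model, full_sequence = FALSE, circs = NULL) {
  stopifnot(inherits(model, "coding_model"))
  if (nrow(rmrjs) == 0) {
    rmrjs$label <- character(0)
    rmrjs$score <- numeric(0)
    return(rmrjs)
  }
  seqs <- if (full_sequence) {
    if (is.null(circs)) abort("`circs` required when full_sequence = TRUE")
    circs$seq[match(rmrjs$circ_id, circs$circ_id)]
  } else {
    rmrjs$seq
  }
  pr <- predict(model, seqs)
  rmrjs$label <- pr$label
  rmrjs$score <- pr$score
  rmrjs
}

#' Save a coding model to disk
#'
#' The file is a versioned RDS carrying the word size, iteration count and
#' scaling bounds alongside the fitted model, so it reloads bit-identically.
#'
#' @param model a `coding_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coding_model <- function(model, path) {
  stopifnot(inherits(model, "coding_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "coding_model")) abort("not a coding_model file")
  model
}

#' Tidy a coding model: per-feature importance
#'
#' @param x a `coding_model`.
#' @param ... unused.
#' @return tibble with `feature`, `threshold_iter`, `measure`, `importance`.
#' @method tidy coding_model
#' @export
tidy.coding_model <- function(x, ...) {
  imp <- if (x$method == "forest") {
    x$fit$importance[, "MeanDecreaseGini"]
  } else {
    v <- x$fit$variable.importance
    if (is.null(v)) v <- numeric(0)
    full <- setNames(numeric(6 * x$T), paste0(
      rep(paste0("t", 0:(x$T - 1)), each = 6), "_",
      c("mean_degree", "clustering", "assortativity", "betweenness",
        "path_length", "edge_density")))
    full[names(v)] <- v
    full
  }
  tibble(feature = names(imp),
         threshold_iter = as.integer(sub("^t(\\d+)_.*$", "\\1", names(imp))),
         measure = sub("^t\\d+_", "", names(imp)),
         importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' Glance at a coding model
#'
#' @param x a `coding_model`.
#' @param ... unused.
#' @return one-row tibble with model metadata and CV accuracy.
#' @method glance coding_model
#' @export
glance.coding_model <- function(x, ...) {
  tibble(method = x$method, w = x$w, T = x$T, n_features = 6L * x$T,
         n_coding = unname(x$n_train["coding"]),
         n_noncoding = unname(x$n_train["noncoding"]),
         cv_folds = x$cv_folds, cv_accuracy = x$cv_accuracy)
}

#' Plot feature importance of a coding model
#'
#' @param object a `coding_model`.
#' @param top_n number of features to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coding_model
#' @export
autoplot.coding_model <- function(object, top_n = 20, ...) {
  td <- head(tidy(object), top_n)
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance),
    fill = .data$measure)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance", y = NULL,
                  title = "Coding-model feature importance") +
    ggplot2::theme_minimal()
}
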