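#' Pipeline configuration
#'
#' All file paths and tunables for the five-stage pipeline. Any input path
#' may be `NULL` to skip the corresponding step (e.g. no rRNA reference
#' skips rRNA depletion). Defaults embed the package-wide parameter choices:
#' 100-N spacers, seed length 8 (so 25-nt reads keep the pigeonhole
#' guarantee at 2 mismatches), NMJ threshold 3 (an RMRJ needs at least 4
#' junction reads), word size 3 with 10 threshold iterations, a 25-tree
#' forest trained on junction-coverage windows (so the classifier is
#' trained on the same kind of object it classifies), and a 10-aa minimum
#' peptide.
#'
#' @param reads_fastq raw Ribo-seq reads (FASTQ, Phred+33).
#' @param circ_fasta candidate circRNA sequences (FASTA).
#' @param out_dir output directory for all stage products.
#' @param rrna_fasta optional rRNA reference for depletion.
#' @param genome_fasta optional linear genome; reads perfectly aligned to it
#'   are removed.
#' @param train_pos_fasta,train_neg_fasta coding / noncoding training FASTAs.
#' @param adapters adapter sequences for trimming.
#' @param spacer N-spacer length between virtual-genome units.
#' @param k seed length of the aligner index.
#' @param max_mismatch mismatch budget for virtual-genome alignment.
#' @param rrna_max_mismatch mismatch budget for rRNA depletion.
#' @param nmj_min NMJ threshold (RMRJ requires NMJ > `nmj_min`).
#' @param min_overhang junction overhang per side.
#' @param w,T network word size and threshold iterations.
#' @param classifier `"forest"` or `"tree"`.
#' @param trees forest size.
#' @param cv_folds cross-validation folds for the reported accuracy.
#' @param train_window `"junction"` (default: RMRJ-geometry training
#'   windows), a numeric length range, or `NULL` for whole sequences.
#' @param full_sequence classify full circRNA sequences instead of RMRJs.
#' @param plus_strand_only count only plus-strand reads toward NMJ.
#' @param dedupe drop duplicate placements before NMJ counting.
#' @param min_aa minimum peptide length.
#' @param seed seed for every stochastic step (training windows, forest).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads_fastq, circ_fasta, out_dir,
                            rrna_fasta = NULL, genome_fasta = NULL,
                            train_pos_fasta = NULL, train_neg_fasta = NULL,
                            adapters = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            spacer = 100L, k = 8L, max_mismatch = 2L,
                            rrna_max_mismatch = 2L, nmj_min = 3L,
                            min_overhang = 1L, w = 3L, T = 10L,
                            classifier = "forest", trees = 25L,
                            cv_folds = 5L, train_window = "junction",
                            full_sequence = FALSE, plus_strand_only = FALSE,
                            dedupe = FALSE, min_aa = 10L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return a `pipeline_config` (for the reader); `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  vals <- vals[keep]
  num_int <- c("spacer", "k", "max_mismatch", "rrna_max_mismatch", "nmj_min",
               "min_overhang", "w", "T", "trees", "cv_folds", "min_aa",
               "seed")
  for (f in intersect(num_int, names(vals))) {
    vals[[f]] <- as.integer(vals[[f]])
  }
  if (!is.null(vals$train_window) && is.numeric(vals$train_window)) {
    vals$train_window <- as.integer(vals$train_window)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(purrr::compact(unclass(cfg)), path)
  invisible(path)
}

pipeline_paths <- function(out_dir) {
  p <- function(f) file.path(out_dir, f)
  list(clean_reads = p("clean_reads.fastq"),
       vg_fasta = p("virtual_genome.fa"),
       vg_bed = p("junctions.bed"),
       vg_units = p("units.tsv"),
       placements = p("placements.tsv"),
       sam = p("alignments.sam"),
       rmrj_fasta = p("rmrj.fa"),
       rmrj_tsv = p("rmrj.tsv"),
       model = p("coding_model.rds"),
       predictions = p("predictions.tsv"),
       translated = p("translated_circrnas.tsv"),
       pep_fasta = p("peptides.fa"),
       pep_tsv = p("peptides.tsv"),
       report = p("report.yaml"))
}

read_tsv_plain <- function(path, ...) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, ...))
}

#' Pipeline stage: read preparation
#'
#' Trims adapters/low-quality bases, depletes rRNA-derived reads (up to
#' `rrna_max_mismatch` substitutions, either strand) and removes reads with
#' a perfect full-length match on the linear genome, writing the surviving
#' "final unique Ribo-seq reads" to `clean_reads.fastq`.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return named counts, invisibly.
#' @export
stage_prep <- function(cfg, quiet = FALSE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(cfg$out_dir)
  reads <- read_fastq(cfg$reads_fastq)
  counts <- c(raw = nrow(reads))
  reads <- trim_reads(reads, trim_params(adapters = cfg$adapters),
                      quiet = quiet)
  counts["trimmed"] <- nrow(reads)
  if (!is.null(cfg$rrna_fasta) && nrow(reads) > 0) {
    rrna <- read_fasta(cfg$rrna_fasta)
    reads <- filter_by_reference(reads, setNames(rrna$seq, rrna$id),
                                 max_mismatch = cfg$rrna_max_mismatch,
                                 quiet = quiet)
  }
  counts["rrna_depleted"] <- nrow(reads)
  if (!is.null(cfg$genome_fasta) && nrow(reads) > 0) {
    gen <- read_fasta(cfg$genome_fasta)
    reads <- filter_by_reference(reads, setNames(gen$seq, gen$id),
                                 max_mismatch = 0L, quiet = quiet)
  }
  counts["final_unique"] <- nrow(reads)
  write_fastq(reads, paths$clean_reads)
  invisible(counts)
}

#' Pipeline stage: virtual-genome construction
#'
#' @inheritParams stage_prep
#' @return the `virtual_genome`, invisibly.
#' @export
stage_buildref <- function(cfg, quiet = FALSE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(cfg$out_dir)
  circs <- read_fasta(cfg$circ_fasta)
  vg <- build_virtual_genome(setNames(circs$seq, circs$id),
                             spacer = cfg$spacer)
  write_virtual_genome(vg, paths$vg_fasta, paths$vg_bed, paths$vg_units)
  if (!quiet) {
    message(sprintf("[buildref] units=%d layout=%dnt", nrow(vg$units),
                    nchar(vg$layout)))
  }
  invisible(vg)
}

# reconstruct the virtual genome from the circRNA input (file contract)
load_virtual_genome <- function(cfg) {
  circs <- read_fasta(cfg$circ_fasta)
  build_virtual_genome(setNames(circs$seq, circs$id), spacer = cfg$spacer)
}

#' Pipeline stage: junction mapping and RMRJ extraction
#'
#' @inheritParams stage_prep
#' @return the RMRJ tibble, invisibly.
#' @export
stage_map <- function(cfg, quiet = FALSE) {
  paths <- pipeline_paths(cfg$out_dir)
  vg <- load_virtual_genome(cfg)
  reads <- read_fastq(paths$clean_reads)
  index <- build_index(vg$layout, k = cfg$k)
  alns <- align_reads(reads, index, max_mismatch = cfg$max_mismatch)
  placements <- assign_to_units(alns, vg, min_overhang = cfg$min_overhang)
  write.table(as.data.frame(placements), paths$placements, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sam(placements, reads, "virtual_genome", nchar(vg$layout), paths$sam)
  rmrjs <- compute_rmrjs(placements, vg, nmj_min = cfg$nmj_min,
                         min_overhang = cfg$min_overhang,
                         plus_strand_only = cfg$plus_strand_only,
                         dedupe = cfg$dedupe)
  write_rmrjs(rmrjs, paths$rmrj_fasta, paths$rmrj_tsv)
  if (!quiet) {
    message(sprintf("[map] reads=%d placed=%d rmrjs=%d", nrow(reads),
                    nrow(placements), nrow(rmrjs)))
  }
  invisible(rmrjs)
}

#' Pipeline stage: classifier training
#'
#' @inheritParams stage_prep
#' @return the fitted `coding_model`, invisibly.
#' @export
stage_train <- function(cfg, quiet = FALSE) {
  paths <- pipeline_paths(cfg$out_dir)
  pos <- read_fasta(cfg$train_pos_fasta)
  neg <- read_fasta(cfg$train_neg_fasta)
  model <- train_classifier(pos$seq, neg$seq, w = cfg$w, T = cfg$T,
                            cv_folds = cfg$cv_folds, seed = cfg$seed,
                            method = cfg$classifier, trees = cfg$trees,
                            window = cfg$train_window)
  write_coding_model(model, paths$model)
  if (!quiet) {
    message(sprintf("[train] n=%d+%d cv_accuracy=%.3f",
                    length(pos$seq), length(neg$seq), model$cv_accuracy))
  }
  invisible(model)
}

#' Pipeline stage: RMRJ classification
#'
#' @inheritParams stage_prep
#' @return the predictions tibble, invisibly.
#' @export
stage_classify <- function(cfg, quiet = FALSE) {
  paths <- pipeline_paths(cfg$out_dir)
  model <- read_coding_model(paths$model)
  rmrjs <- read_rmrjs(cfg)
  circs <- read_fasta(cfg$circ_fasta)
  preds <- classify_rmrjs(rmrjs, model, full_sequence = cfg$full_sequence,
                          circs = tibble(circ_id = circs$id,
                                         seq = circs$seq))
  write.table(as.data.frame(select(preds, -"seq")), paths$predictions,
              sep = "\t", quote = FALSE, row.names = FALSE)
  translated <- filter(preds, .data$label == "coding")
  write.table(as.data.frame(select(translated, "circ_id", "nmj", "score")),
              paths$translated, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!quiet) {
    message(sprintf("[classify] rmrjs=%d translated=%d", nrow(preds),
                    nrow(translated)))
  }
  invisible(preds)
}

read_rmrjs <- function(cfg) {
  paths <- pipeline_paths(cfg$out_dir)
  tab <- read_tsv_plain(paths$rmrj_tsv,
                        colClasses = c(circ_id = "character"))
  seqs <- read_fasta(paths$rmrj_fasta)
  tab$seq <- seqs$seq[match(tab$circ_id, seqs$id)]
  tab
}

#' Pipeline stage: peptide prediction
#'
#' @inheritParams stage_prep
#' @return the peptide tibble, invisibly.
#' @export
stage_peptides <- function(cfg, quiet = FALSE) {
  paths <- pipeline_paths(cfg$out_dir)
  vg <- load_virtual_genome(cfg)
  rmrjs <- read_rmrjs(cfg)
  preds <- read_tsv_plain(paths$predictions,
                          colClasses = c(circ_id = "character"))
  coding <- rmrjs[rmrjs$circ_id %in% preds$circ_id[preds$label == "coding"], ,
                  drop = FALSE]
  peptides <- predict_peptides(coding, min_aa = cfg$min_aa, vg = vg)
  write_peptides(peptides, paths$pep_fasta, paths$pep_tsv)
  if (!quiet) {
    message(sprintf("[peptides] translated=%d peptides=%d", nrow(coding),
                    nrow(peptides)))
  }
  invisible(peptides)
}

#' Run the full translated-circRNA pipeline
#'
#' Executes read preparation, virtual-genome construction, junction mapping,
#' classifier training, RMRJ classification and peptide prediction, writing
#' every stage product plus a YAML run report (per-stage counts and the full
#' parameter set) under `cfg$out_dir`. Each stage exchanges data through its
#' output files, so the stages can equally be run one at a time with the
#' `stage_*()` functions or the command-line tool. Re-running with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param cfg a [pipeline_config()] (or path to its YAML form).
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with `report`, `rmrjs`, `predictions`,
#'   `translated`, `peptides` and the fitted `model`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  paths <- pipeline_paths(cfg$out_dir)
  counts <- stage_prep(cfg, quiet = quiet)
  vg <- stage_buildref(cfg, quiet = quiet)
  rmrjs <- stage_map(cfg, quiet = quiet)
  model <- stage_train(cfg, quiet = quiet)
  preds <- stage_classify(cfg, quiet = quiet)
  peptides <- stage_peptides(cfg, quiet = quiet)
  translated <- filter(preds, .data$label == "coding")
  report <- list(
    parameters = purrr::compact(unclass(cfg)),
    counts = c(as.list(counts),
               list(circ_units = nrow(vg$units), rmrjs = nrow(rmrjs),
                    translated_circrnas = nrow(translated),
                    peptides = nrow(peptides))),
    cv_accuracy = model$cv_accuracy)
  yaml::write_yaml(report, paths$report)
  invisible(list(report = report, rmrjs = rmrjs, predictions = preds,
                 translated = translated, peptides = peptides,
                 model = model))
}
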