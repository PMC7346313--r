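# Performance evaluation against a benchmark circle list: confusion
# counts with one-to-one truth matching, sensitivity / precision / F1,
# and the RNase-R enrichment labelling criteria for real-data
# benchmarking.

#' Confusion counts of a prediction against a truth circle list
#'
#' Predicted-positive candidates are matched one-to-one to truth
#' circles (both breakpoints within `tol`), greedily by total
#' breakpoint distance, so one truth circle can never yield two true
#' positives. TP = matched positives; FP = unmatched positives; FN =
#' truth circles without a matched positive; TN = predicted-negative
#' candidates that match no truth circle.
#'
#' @param cands Candidate data frame (`chrom`, `brk1`, `brk2`).
#' @param predicted Integer/logical vector: predicted label per
#'   candidate (1 = called circRNA).
#' @param circles Truth circle table (`chrom`, `brk1`, `brk2`).
#' @param tol Breakpoint tolerance (bp).
#' @return A list of class `confusion_counts` with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(cands, predicted, circles, tol = 2L) {
  predicted <- as.integer(predicted)
  stopifnot(length(predicted) == nrow(cands))
  pos <- which(predicted == 1L)
  hits <- list()
  for (i in pos) {
    jj <- which(circles$chrom == cands$chrom[i] &
                  abs(circles$brk1 - cands$brk1[i]) <= tol &
                  abs(circles$brk2 - cands$brk2[i]) <= tol)
    for (j in jj) {
      d <- abs(circles$brk1[j] - cands$brk1[i]) +
        abs(circles$brk2[j] - cands$brk2[i])
      hits[[length(hits) + 1L]] <- c(i, j, d)
    }
  }
  tp <- 0L
  used_c <- integer(0); used_t <- integer(0)
  if (length(hits) > 0L) {
    h <- do.call(rbind, hits)
    h <- h[order(h[, 3L], h[, 1L], h[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      if (h[r, 1L] %in% used_c || h[r, 2L] %in% used_t) next
      used_c <- c(used_c, h[r, 1L]); used_t <- c(used_t, h[r, 2L])
      tp <- tp + 1L
    }
  }
  fp <- length(pos) - tp
  fn <- nrow(circles) - tp
  neg <- which(predicted == 0L)
  tn <- sum(vapply(neg, function(i) {
    !any(circles$chrom == cands$chrom[i] &
           abs(circles$brk1 - cands$brk1[i]) <= tol &
           abs(circles$brk2 - cands$brk2[i]) <= tol)
  }, TRUE))
  structure(list(TP = tp, FP = fp, FN = as.integer(fn), TN = as.integer(tn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("sensitivity %.4f  precision %.4f  F1 %.4f\n",
              sensitivity(x), precision(x), f1_score(x)))
  invisible(x)
}

#' Sensitivity, precision, F1
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F1 = 2 * S * P / (S + P)`. A zero denominator yields 0 with a
#' warning. The false discovery rate is `1 - precision`.
#'
#' @param c A `confusion_counts` object (or list with TP/FP/FN).
#' @return A number in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  den <- c$TP + c$FN
  if (den == 0L) { warning("sensitivity: TP + FN == 0"); return(0) }
  c$TP / den
}

#' @rdname sensitivity
#' @export
precision <- function(c) {
  den <- c$TP + c$FP
  if (den == 0L) { warning("precision: TP + FP == 0"); return(0) }
  c$TP / den
}

#' @rdname sensitivity
#' @export
f1_score <- function(c) {
  s <- suppressWarnings(sensitivity(c))
  p <- suppressWarnings(precision(c))
  if (s + p == 0) return(0)
  2 * s * p / (s + p)
}

#' RNase-R enrichment labelling of detected circRNAs
#'
#' Implements the benchmarking criteria for samples with and without
#' RNase R treatment (the exonuclease degrades linear RNA, so real
#' circles are enriched after treatment). Candidates with fewer than
#' `min_support` junction reads in the untreated sample are excluded
#' from evaluation. A candidate whose treated/untreated junction-read
#' ratio is at least `fold` is a true positive; one that disappears or
#' is depleted after treatment is a false positive. Ratios between 1
#' and `fold` are not covered by the criteria; `gap_policy` decides
#' (conservative default: false positive).
#'
#' @param untreated Data frame `chrom`, `brk1`, `brk2`, `count`
#'   (junction reads without treatment).
#' @param treated Same columns for the RNase-R-treated sample.
#' @param min_support Minimum untreated junction-read count.
#' @param fold Minimum enrichment ratio for a true positive.
#' @param gap_policy One of `"fp"`, `"tp"`, `"excluded"` for ratios in
#'   `[1, fold)`.
#' @return `untreated` with a `label` column in
#'   `{"TP", "FP", "excluded"}`.
#' @export
rnase_r_label <- function(untreated, treated, min_support = 3L, fold = 3,
                          gap_policy = c("fp", "tp", "excluded")) {
  gap_policy <- match.arg(gap_policy)
  key <- function(d) paste(d$chrom, d$brk1, d$brk2)
  t_count <- treated$count[match(key(untreated), key(treated))]
  t_count[is.na(t_count)] <- 0L
  ratio <- t_count / untreated$count
  label <- ifelse(untreated$count < min_support, "excluded",
           ifelse(ratio >= fold, "TP",
           ifelse(t_count < untreated$count, "FP",
                  switch(gap_policy, fp = "FP", tp = "TP",
                         excluded = "excluded"))))
  out <- untreated
  out$treated_count <- t_count
  out$label <- label
  out
}

#' Run the full simulate-train-classify-evaluate pipeline
#'
#' Simulates a training and a test dataset, collects PSS candidates on
#' both, extracts the 23 features, trains the gradient-boosted
#' classifier on the truth-labelled training candidates, classifies
#' the test candidates, and evaluates the raw candidate set
#' ("pre-filter") and the classified call set ("post-filter") against
#' the test truth.
#'
#' @param config Test-set [sim_config()].
#' @param train_config Training-set config (defaults to `config` with
#'   a shifted seed so the replicate is independent).
#' @param out_dir Optional directory for result files (`metrics.json`,
#'   candidate and feature tables).
#' @param hyper List of classifier hyperparameters passed to
#'   [circ_gbdt()].
#' @param tol Breakpoint tolerance used for labelling and evaluation.
#' @param model Optional pre-trained `circ_gbdt` (skips training-set
#'   simulation).
#' @return A list of class `circ_pipeline`: `metrics` (pre/post
#'   sensitivity, precision, F1, FDR), confusion counts, tables and
#'   file paths.
#' @export
run_pipeline <- function(config = sim_config(), train_config = NULL,
                         out_dir = NULL, hyper = list(), tol = 2L,
                         model = NULL) {
  if (is.null(model)) {
    if (is.null(train_config)) {
      train_config <- config
      train_config$seed <- derive_seed(config$seed, 777L)
    }
    train <- pipeline_stage_dataset(train_config)
    if (length(unique(train$labels)) < 2L) {
      stop("pipeline stage 'train': training simulation produced a ",
           "single candidate class", call. = FALSE)
    }
    xtr <- as.matrix(train$features[, FEATURE_NAMES])
    model <- do.call(circ_gbdt,
                     c(list(x = xtr, y = train$labels,
                            seed = derive_seed(config$seed, 13L)), hyper))
  } else {
    train <- NULL
  }
  test <- pipeline_stage_dataset(config)
  xte <- as.matrix(test$features[, FEATURE_NAMES])
  pred <- if (nrow(xte) > 0L) predict(model, xte)
          else data.frame(prob = numeric(0), label = integer(0))
  pre <- confusion(test$cands, rep(1L, nrow(test$cands)),
                   test$sim$circles, tol = tol)
  post <- confusion(test$cands, pred$label, test$sim$circles, tol = tol)
  metrics <- list(
    pre = list(sensitivity = suppressWarnings(sensitivity(pre)),
               precision = suppressWarnings(precision(pre)),
               f1 = f1_score(pre), fdr = 1 - suppressWarnings(precision(pre))),
    post = list(sensitivity = suppressWarnings(sensitivity(post)),
                precision = suppressWarnings(precision(post)),
                f1 = f1_score(post),
                fdr = 1 - suppressWarnings(precision(post))),
    n_candidates = nrow(test$cands),
    n_true_circles = nrow(test$sim$circles))
  out <- list(metrics = metrics, pre = pre, post = post, model = model,
              test = test, train = train, prediction = pred)
  class(out) <- "circ_pipeline"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_candidates(test$cands, file.path(out_dir, "candidates.tsv"))
    write_feature_table(test$features, file.path(out_dir, "features.tsv"))
    save_model(model, file.path(out_dir, "model.json"))
    out$paths <- list(
      metrics = file.path(out_dir, "metrics.json"),
      candidates = file.path(out_dir, "candidates.tsv"),
      features = file.path(out_dir, "features.tsv"),
      model = file.path(out_dir, "model.json"))
  }
  out
}

# Simulate one dataset and take it through candidate collection and
# feature extraction (in memory; the SAM/FASTA round trip is exercised
# by the I/O unit tests instead to keep the pipeline fast).
pipeline_stage_dataset <- function(config) {
  sim <- simulate_dataset(config)
  aln <- read_alignments(sim$sam)
  model <- estimate_insert_size(aln)
  cands <- collect_candidates(aln, model)
  labels <- label_candidates(cands, sim$circles)
  feats <- feature_table(cands, aln, sim$fasta, model, labels = labels,
                         chrom_len = config$genome_length)
  list(sim = sim, aln = aln, model = model, cands = cands,
       labels = labels, features = feats)
}

#' @export
print.circ_pipeline <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("circRNA pipeline on %d candidates (%d true circles)\n",
              m$n_candidates, m$n_true_circles))
  cat(sprintf("  pre-filter : sensitivity %.3f  precision %.3f  F1 %.3f\n",
              m$pre$sensitivity, m$pre$precision, m$pre$f1))
  cat(sprintf("  post-filter: sensitivity %.3f  precision %.3f  F1 %.3f\n",
              m$post$sensitivity, m$post$precision, m$post$f1))
  invisible(x)
}

#' Scaled-down detection benchmark
#'
#' Reruns the package's two simulation benchmarks at desk scale on a
#' ~1 Mb synthetic genome with 200 genes and 40 circles: (1) 100 bp
#' paired-end reads with circRNA coverage fixed at 10x and linear
#' coverage varied over 10/30/50x, and (2) 150 bp reads with both
#' coverages at 10x. For each condition the classifier is trained on an
#' independent labelled simulation replicate and the raw (pre-filter)
#' and classified (post-filter) call sets are scored against the
#' simulation truth.
#'
#' @param seed Integer seed; every simulation derives its stream from
#'   it.
#' @param linear_coverages Linear-transcript coverages for the 100 bp
#'   arm.
#' @param genome_length,n_genes Scale of the synthetic genome.
#' @return A data frame with one row per condition: read length,
#'   linear coverage, pre/post sensitivity, precision and F1.
#' @export
detection_benchmark <- function(seed = 1L,
                                linear_coverages = c(10, 30, 50),
                                genome_length = 1e6, n_genes = 200L) {
  base <- function(...) sim_config(genome_length = genome_length,
                                   n_genes = n_genes, ...)
  rows <- list()
  # 100 bp arm: one model trained at the middle coverage replicate
  train_cfg <- base(read_length = 100L, linear_coverage = 30,
                    seed = derive_seed(seed, 501L))
  train <- pipeline_stage_dataset(train_cfg)
  fit <- circ_gbdt(as.matrix(train$features[, FEATURE_NAMES]),
                   train$labels, seed = derive_seed(seed, 502L))
  for (cov in linear_coverages) {
    cfg <- base(read_length = 100L, linear_coverage = cov,
                seed = derive_seed(seed, 510L + cov))
    rep <- run_pipeline(cfg, model = fit)
    rows[[length(rows) + 1L]] <- data.frame(
      read_length = 100L, linear_coverage = cov,
      pre_sensitivity = rep$metrics$pre$sensitivity,
      pre_precision = rep$metrics$pre$precision,
      pre_f1 = rep$metrics$pre$f1,
      post_sensitivity = rep$metrics$post$sensitivity,
      post_precision = rep$metrics$post$precision,
      post_f1 = rep$metrics$post$f1)
  }
  # 150 bp arm: independent training replicate at the same read length
  cfg150 <- base(read_length = 150L, linear_coverage = 10,
                 seed = derive_seed(seed, 551L))
  rep150 <- run_pipeline(cfg150)
  rows[[length(rows) + 1L]] <- data.frame(
    read_length = 150L, linear_coverage = 10,
    pre_sensitivity = rep150$metrics$pre$sensitivity,
    pre_precision = rep150$metrics$pre$precision,
    pre_f1 = rep150$metrics$pre$f1,
    post_sensitivity = rep150$metrics$post$sensitivity,
    post_precision = rep150$metrics$post$precision,
    post_f1 = rep150$metrics$post$f1)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
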