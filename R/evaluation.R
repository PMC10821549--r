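#' Classification metrics for imbalanced binary prediction
#'
#' ROC AUC is the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with half credit for score ties (the rank/
#' Mann-Whitney formulation). Average precision is the step-wise area under
#' the precision-recall curve: the sum over positives, taken in descending
#' score order, of the precision at that rank divided by the number of
#' positives; tied scores are kept in input order, so ties should be broken
#' upstream when a canonical order matters. Thresholded metrics use
#' `score >= threshold`.
#'
#' @param y_true 0/1 truth vector.
#' @param scores Scores in `[0, 1]`, same length.
#' @param threshold Decision threshold for the confusion metrics
#'   (default 0.5).
#' @return List of class `metric_report`: `accuracy`, `precision`, `recall`,
#'   `f_measure`, `auc_roc`, `average_precision`, `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC and AP are undefined with a single-class truth vector")
  # rank AUC with 0.5 tie credit
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  # step-wise AP (non-interpolated)
  ord <- order(-scores)
  ys <- y[ord]
  prec_at <- cumsum(ys) / seq_along(ys)
  ap <- sum(prec_at[ys == 1]) / npos
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  conf_report(tp, fp, tn, fn, auc, ap)
}

conf_report <- function(tp, fp, tn, fn, auc = NA_real_, ap = NA_real_) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / (tp + fp + tn + fn),
                 precision = precision, recall = recall, f_measure = f,
                 auc_roc = auc, average_precision = ap,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report: acc %.3f  prec %.3f  rec %.3f  F %.3f  AUC %s  AP %s\n",
    x$accuracy, x$precision, x$recall, x$f_measure,
    ifelse(is.na(x$auc_roc), "NA", sprintf("%.3f", x$auc_roc)),
    ifelse(is.na(x$average_precision), "NA",
           sprintf("%.3f", x$average_precision))))
  invisible(x)
}

#' Top-fraction evaluation protocol
#'
#' Mirrors how centrality rankings are scored for essential-protein
#' discovery: the top `ceiling(fraction * n)` proteins by descending score
#' are predicted essential (score ties broken by protein identifier) and
#' the confusion metrics are computed on that labeling. `fraction` is
#' typically set to the species' essential-protein proportion.
#'
#' @param scores Named (or unnamed) score vector.
#' @param y_true 0/1 truth vector aligned with `scores`.
#' @param fraction Fraction in (0, 1] of proteins to call positive.
#' @param proteins Optional identifiers for tie-breaking (defaults to
#'   `names(scores)` or the index order).
#' @return A `metric_report` (AUC/AP carried over from the full ranking).
#' @export
top_fraction_eval <- function(scores, y_true, fraction,
                              proteins = names(scores)) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(scores)
  if (is.null(proteins)) proteins <- sprintf("idx%09d", seq_len(n))
  k <- ceiling(fraction * n)
  ord <- order(-scores, proteins, method = "radix")
  pred <- integer(n)
  pred[ord[seq_len(k)]] <- 1L
  y <- as.integer(y_true)
  conf_report(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
              tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
}

#' Branch-contribution ablation
#'
#' Trains three models on one identical split and seed — community features
#' only, subcellular features only, and both — and evaluates each on the
#' same held-out test set, isolating what each input source contributes.
#'
#' @param community_X,subcellular_X Full feature matrices over the sample
#'   universe.
#' @param y 0/1 labels.
#' @param split A [split_dataset()] result (reused across variants).
#' @param spec,cfg Model and training configuration shared by all variants.
#' @return Named list of `metric_report`s: `COM`, `SUB`, `COM+SUB`; the
#'   split is attached as an attribute.
#' @export
ablate_branches <- function(community_X, subcellular_X, y, split,
                            spec = model_spec(), cfg = train_config()) {
  variants <- list(
    "COM" = list(com = community_X, sub = NULL),
    "SUB" = list(com = NULL, sub = subcellular_X),
    "COM+SUB" = list(com = community_X, sub = subcellular_X))
  out <- lapply(variants, function(vr) {
    m <- train_model(
      if (is.null(vr$com)) NULL else vr$com[split$train, , drop = FALSE],
      if (is.null(vr$sub)) NULL else vr$sub[split$train, , drop = FALSE],
      y[split$train], spec, cfg)
    s <- predict_scores(
      m,
      if (is.null(vr$com)) NULL else vr$com[split$test, , drop = FALSE],
      if (is.null(vr$sub)) NULL else vr$sub[split$test, , drop = FALSE])
    compute_metrics(y[split$test], s)
  })
  attr(out, "split") <- split
  out
}

#' Drop one snapshot and rerun the community pipeline
#'
#' Removes snapshot `t` from a dynamic network, rebuilds the interaction
#' stream, communities, features and classifier with otherwise unchanged
#' parameters, and evaluates on the same split. The full sweep over all
#' snapshots shows whether any single network state carries the signal.
#'
#' @param dataset An [align_dataset()] result.
#' @param t Snapshot index to detach (1-based), or `NULL` for the intact
#'   pipeline.
#' @param seed Seed for split and training.
#' @param ... Passed to [run_essnet_pipeline()] (for example
#'   `observation_window`, `k_communities`).
#' @return List with the variant label and its test `metric_report`.
#' @export
detach_snapshot <- function(dataset, t = NULL, seed = 1L, ...) {
  T_ <- ncol(dataset$expression)
  if (T_ < 3L) stop("need at least 3 timepoints to detach one")
  drop_t <- t
  if (!is.null(drop_t) && (drop_t < 1L || drop_t > T_))
    stop("snapshot index out of range")
  res <- run_essnet_pipeline(dataset, seed = seed, drop_snapshot = drop_t, ...)
  list(variant = if (is.null(drop_t)) "full" else sprintf("detach-T%d", drop_t),
       report = res$report, n_snapshots = res$n_snapshots)
}

#' Sweep the snapshot-detachment ablation over every timepoint
#' @inheritParams detach_snapshot
#' @return List: `full` (intact run) plus one entry per detached snapshot.
#' @export
detach_sweep <- function(dataset, seed = 1L, ...) {
  T_ <- ncol(dataset$expression)
  out <- list(full = detach_snapshot(dataset, NULL, seed = seed, ...))
  for (t in seq_len(T_))
    out[[sprintf("detach-T%d", t)]] <-
      detach_snapshot(dataset, t, seed = seed, ...)
  out
}

#' Write a metric report (or list of reports) as TSV
#' @param reports A `metric_report` or named list of them.
#' @param path Output path.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "metric_report")) reports <- list(report = reports)
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(variant = nm, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f_measure = r$f_measure,
               auc_roc = r$auc_roc, average_precision = r$average_precision,
               tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Precision-recall and ROC curve points for plotting
#' @param y_true 0/1 truth vector.
#' @param scores Score vector.
#' @return List of two data.frames: `pr` (recall, precision) and `roc`
#'   (fpr, tpr), one row per rank cut.
#' @export
curve_points <- function(y_true, scores) {
  y <- as.integer(y_true)[order(-scores)]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  list(pr = data.frame(recall = tp / sum(y),
                       precision = tp / seq_along(y)),
       roc = data.frame(fpr = fp / sum(1 - y), tpr = tp / sum(y)))
}
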