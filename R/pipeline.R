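#' Run the full essential-protein prediction pipeline
#'
#' Stages, in order: 3-sigma activity profiles and dynamic-network
#' snapshots; edge birth/death interaction stream; streaming community
#' discovery with windowed observations; candidate community features;
#' stratified 80/20 split; SVM-RFE ranking of community features on the
#' training split and selection of the top `k_communities`; rank-filtered
#' subcellular features; two-branch classifier training with balanced
#' per-epoch downsampling; evaluation on the held-out test set (threshold
#' metrics, AUC, AP, and the top-fraction protocol at the dataset's
#' essential-protein proportion).
#'
#' When `outdir` is given every stage writes its artifact there and the
#' expensive stages are content-cached: a rerun with identical inputs and
#' configuration reuses the stored stage outputs.
#'
#' @param dataset An [align_dataset()] result.
#' @param seed Integer seed driving split and training.
#' @param first_snapshot_static Replace snapshot 1 by the static network
#'   (default TRUE).
#' @param observation_window Timesteps per community observation (default 1).
#' @param membership Community membership counted for features: `"all"`
#'   (core + peripheral) or `"core"`.
#' @param svm Configuration for the RFE inner SVM ([svm_config()]).
#' @param k_communities Community features kept after RFE (default 64).
#' @param top_n,exclude_lo,exclude_hi Subcellular rank filter
#'   (defaults 1024, 11, 64).
#' @param spec Classifier architecture ([model_spec()]).
#' @param train_fraction Training fraction of the 80/20 split.
#' @param epochs,learning_rate,coverage_P Training controls (see
#'   [train_config()]).
#' @param drop_snapshot Optional snapshot index to detach before the stream
#'   is built (ablation support).
#' @param outdir Optional artifact directory (enables caching).
#' @param verbose Log per-stage counts via `message()` (default TRUE).
#' @return List of class `essnet_run` with every stage product: `dyn`,
#'   `stream`, `catalog`, `candidates`, `ranking`, `selected`,
#'   `community_X`, `subcellular_X`, `split`, `model`, `scores`, `report`,
#'   `top_fraction`, `n_snapshots`.
#' @export
run_essnet_pipeline <- function(dataset, seed = 1L,
                                first_snapshot_static = TRUE,
                                observation_window = 1L,
                                membership = c("all", "core"),
                                svm = svm_config(),
                                k_communities = 64L,
                                top_n = 1024L, exclude_lo = 11L,
                                exclude_hi = 64L,
                                spec = model_spec(),
                                train_fraction = 0.8,
                                epochs = NULL, learning_rate = 1e-3,
                                coverage_P = 0.001,
                                drop_snapshot = NULL,
                                outdir = NULL, verbose = TRUE) {
  membership <- match.arg(membership)
  say <- function(...) if (verbose) message(sprintf(...))
  cache <- make_stage_cache(outdir)

  nodes <- dataset$network$nodes
  say("stage align: %d nodes, %d edges, %d essential",
      length(nodes), nrow(dataset$network$edges), sum(dataset$labels))

  dyn <- cache("snapshots",
               list(dataset$network$edges, dataset$expression,
                    first_snapshot_static, drop_snapshot),
               {
    d <- build_snapshots(dataset, first_snapshot_static)
    if (!is.null(drop_snapshot)) {
      if (drop_snapshot < 1L || drop_snapshot > length(d$snapshots))
        stop("drop_snapshot out of range")
      d$snapshots <- d$snapshots[-drop_snapshot]
    }
    d
  })
  say("stage snapshots: %d snapshots, edges %s", length(dyn$snapshots),
      paste(vapply(dyn$snapshots, nrow, 0L), collapse = "/"))

  stream <- cache("stream", list(dyn$snapshots), build_stream(dyn))
  say("stage stream: %d events (%d births, %d deaths)", nrow(stream),
      sum(stream$kind == "birth"), sum(stream$kind == "death"))

  catalog <- cache("communities",
                   list(stream, nodes, observation_window,
                        length(dyn$snapshots)),
                   run_stream(stream, nodes = nodes,
                              observation_window = observation_window,
                              total_time = length(dyn$snapshots)))
  say("stage communities: %d live, %d windows, %d records",
      length(catalog$live), catalog$n_windows, nrow(catalog$history))

  candidates <- collect_candidate_features(catalog, membership)
  say("stage candidates: %d candidate community features",
      length(candidates))
  community_all <- build_membership_matrix(nodes, candidates)

  y <- dataset$labels
  split <- split_dataset(y, train_fraction = train_fraction,
                         stratified = TRUE, seed = seed)

  ranking <- NULL
  community_X <- NULL
  selected <- integer()
  if (ncol(community_all) > 0L) {
    ranking <- cache("rfe",
                     list(community_all, y, split$train, svm),
                     rfe_rank(community_all[split$train, , drop = FALSE],
                              y[split$train], svm))
    selected <- select_top_communities(
      ranking, min(k_communities, length(ranking$ranked)))
    community_X <- community_all[, selected, drop = FALSE]
    say("stage rfe: kept %d of %d community features", length(selected),
        ncol(community_all))
  } else {
    say("stage rfe: no candidate communities; community branch disabled")
  }

  subcellular_X <- subcellular_features(dataset$localization, nodes,
                                        top_n = top_n,
                                        exclude_lo = exclude_lo,
                                        exclude_hi = exclude_hi)
  say("stage subcellular: %d feature columns", ncol(subcellular_X))
  if (ncol(subcellular_X) == 0L) subcellular_X <- NULL

  cfg <- train_config(epochs = epochs, learning_rate = learning_rate,
                      seed = seed, coverage_P = coverage_P)
  model <- cache("model",
                 list(community_X, subcellular_X, y, split$train, spec, cfg),
                 train_model(
                   if (is.null(community_X)) NULL
                   else community_X[split$train, , drop = FALSE],
                   if (is.null(subcellular_X)) NULL
                   else subcellular_X[split$train, , drop = FALSE],
                   y[split$train], spec, cfg))
  say("stage train: %d epochs, final balanced loss %.4f", model$epochs,
      utils::tail(model$trace, 1))

  scores <- predict_scores(
    model,
    if (is.null(community_X)) NULL
    else community_X[split$test, , drop = FALSE],
    if (is.null(subcellular_X)) NULL
    else subcellular_X[split$test, , drop = FALSE])
  report <- compute_metrics(y[split$test], scores)
  frac <- mean(y)
  topf <- top_fraction_eval(scores, y[split$test], frac,
                            proteins = nodes[split$test])
  say("stage evaluate: AUC %.3f  AP %.3f  F %.3f", report$auc_roc,
      report$average_precision, report$f_measure)

  res <- structure(
    list(dyn = dyn, stream = stream, catalog = catalog,
         candidates = candidates, ranking = ranking, selected = selected,
         community_X = community_X, subcellular_X = subcellular_X,
         split = split, model = model, scores = scores, report = report,
         top_fraction = topf, n_snapshots = length(dyn$snapshots),
         seed = seed),
    class = "essnet_run")

  if (!is.null(outdir)) {
    write_stream(stream, file.path(outdir, "stream.tsv"))
    write_catalog(catalog, file.path(outdir, "catalog.tsv"))
    write_candidates(candidates, file.path(outdir, "candidates.tsv"))
    if (!is.null(ranking))
      write_ranking(ranking, file.path(outdir, "ranking.tsv"))
    if (!is.null(community_X))
      write_feature_matrix(community_X,
                           file.path(outdir, "community_features.tsv"))
    if (!is.null(subcellular_X))
      write_feature_matrix(subcellular_X,
                           file.path(outdir, "subcellular_features.tsv"))
    write_predictions(nodes[split$test], scores,
                      as.integer(scores >= 0.5),
                      file.path(outdir, "predictions.tsv"))
    write_report(list(test = report, top_fraction = topf),
                 file.path(outdir, "report.tsv"))
  }
  res
}

#' @export
print.essnet_run <- function(x, ...) {
  cat(sprintf(
    "essnet_run: %d snapshots, %d events, %d candidates -> %d selected; test AUC %.3f AP %.3f F %.3f\n",
    x$n_snapshots, nrow(x$stream), length(x$candidates),
    length(x$selected), x$report$auc_roc, x$report$average_precision,
    x$report$f_measure))
  invisible(x)
}

# Content-addressed stage cache: `cache(stage, key_objects, expr)` reuses
# the stored result when the serialized key is unchanged. No-op without an
# output directory.
make_stage_cache <- function(outdir) {
  if (is.null(outdir)) return(function(stage, key, expr) force(expr))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  function(stage, key, expr) {
    keyhash <- digest_obj(key)
    rds <- file.path(outdir, paste0("stage_", stage, ".rds"))
    hf <- file.path(outdir, paste0("stage_", stage, ".hash"))
    if (file.exists(rds) && file.exists(hf) &&
        identical(readLines(hf, warn = FALSE)[1], keyhash)) {
      message(sprintf("stage %s: cache hit", stage))
      return(readRDS(rds))
    }
    val <- force(expr)
    saveRDS(val, rds, version = 2)
    writeLines(keyhash, hf)
    val
  }
}

digest_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
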