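#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a planted-partition PPI graph (dense within blocks, sparse between), a
#' two-level temporal expression profile in which each block is highly
#' expressed during its own contiguous phase of timepoints, a localization
#' table whose first `n_enriched_terms` terms are enriched among essential
#' proteins, and a rare essential class planted by block and/or term.
#'
#' The two-level profile keeps the activity calculation analytically
#' checkable: with phase fraction f and expression step d = active - baseline
#' the zero-noise margin between the active level and the protein's own
#' threshold is `d(1 - f) - 3 sigma^3/(1 + sigma^2)` with
#' `sigma^2 = d^2 f (1-f) n/(n-1)`. The margin shrinks as d grows (the
#' threshold rises with sigma cubed), so the default step is deliberately
#' modest: d = 1 keeps the margin positive for every phase fraction up to
#' 1/2, while d = 2 already fails near f = 1/3. [generate_dataset()] warns
#' when a configuration leaves its own active phases below threshold.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param n_timepoints Expression timepoints (default 12).
#' @param n_communities Planted blocks K (default 5).
#' @param p_in,p_out Within- and between-block edge probabilities
#'   (defaults 0.9 and 0.02).
#' @param baseline_expr,active_expr Expression means outside/inside a
#'   block's active phase (defaults 1 and 2).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param n_terms Number of localization terms (default 30).
#' @param n_enriched_terms Terms enriched among essentials (default 3).
#' @param enrichment Probability an essential carries each enriched term
#'   (default 0.9); non-essentials carry them with probability 0.03.
#' @param n_background_terms Background terms drawn per protein (default 2).
#' @param essential_fraction Fraction of essential proteins, in (0, 0.5)
#'   (default 0.2).
#' @param label_model Where the essential signal lives: `"mixed"` (block
#'   preference + term enrichment, default), `"community"` (block only) or
#'   `"localization"` (terms only).
#' @param seed Integer seed; every random draw derives from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, n_timepoints = 12L,
                             n_communities = 5L, p_in = 0.9, p_out = 0.02,
                             baseline_expr = 1, active_expr = 2,
                             noise_sd = 0.1, n_terms = 30L,
                             n_enriched_terms = 3L, enrichment = 0.9,
                             n_background_terms = 2L,
                             essential_fraction = 0.2,
                             label_model = c("mixed", "community",
                                             "localization"),
                             seed = 1L) {
  label_model <- match.arg(label_model)
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            active_expr > baseline_expr,
            essential_fraction > 0, essential_fraction < 0.5,
            n_timepoints >= 2, n_communities >= 1)
  if (n_communities * 3L > n_proteins)
    stop("infeasible sizes: each planted block needs >= 3 proteins")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Easy-regime configuration for end-to-end recovery checks
#'
#' Strong community structure (p_in 0.95, p_out 0.01), low noise, strong
#' localization enrichment — the regime in which the pipeline is expected
#' to recover the planted signal nearly perfectly.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @export
easy_regime_config <- function(seed = 1L, ...) {
  args <- list(p_in = 0.95, p_out = 0.01, noise_sd = 0.05, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# contiguous phase windows: split 1..T into K nearly equal segments
phase_windows <- function(T_, K) {
  cuts <- floor(seq(0, T_, length.out = K + 1))
  data.frame(start = cuts[-(K + 1)] + 1L, end = cuts[-1])
}

#' Generate a synthetic benchmark dataset
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: `network`
#'   ([ppi_network()]), `expression` (matrix), `localization` (data.frame),
#'   `labels` (character vector of essential proteins), `truth` (data.frame
#'   `protein`, `block`, `essential`, `phase_start`, `phase_end`), `cfg`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  K <- cfg$n_communities
  T_ <- cfg$n_timepoints
  ids <- sprintf("P%04d", seq_len(n))
  block <- sort(rep(seq_len(K), length.out = n))

  # planted-partition graph
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  p_edge <- ifelse(block[pair_i] == block[pair_j], cfg$p_in, cfg$p_out)
  on <- runif(length(p_edge)) < p_edge
  net <- ppi_network(ids[pair_i[on]], ids[pair_j[on]], nodes = ids)

  # phased two-level expression
  ph <- phase_windows(T_, K)
  expr <- matrix(cfg$baseline_expr, n, T_,
                 dimnames = list(ids, paste0("t", seq_len(T_))))
  for (k in seq_len(K))
    expr[block == k, ph$start[k]:ph$end[k]] <- cfg$active_expr
  if (cfg$noise_sd > 0)
    expr <- expr + matrix(rnorm(n * T_, sd = cfg$noise_sd), n, T_)
  expr <- pmax(expr, 0)
  margin <- two_level_threshold_margin(cfg$baseline_expr, cfg$active_expr,
                                       min(ph$end - ph$start + 1L), T_)
  if (margin <= 0)
    warning("configured expression levels leave phase-active proteins below their own threshold")

  # essential labels
  n_ess <- round(cfg$essential_fraction * n)
  w <- rep(1, n)
  if (cfg$label_model %in% c("mixed", "community")) {
    ess_blocks <- seq_len(max(1L, round(K * 0.4)))
    w[block %in% ess_blocks] <- 6
  }
  essential <- sort(sample(n, n_ess, prob = w))
  ess_flag <- seq_len(n) %in% essential

  # localization: enriched terms for essentials plus uniform background
  terms <- sprintf("term%03d", seq_len(cfg$n_terms))
  enr <- terms[seq_len(min(cfg$n_enriched_terms, cfg$n_terms))]
  bg <- setdiff(terms, enr)
  recs <- list()
  use_loc <- cfg$label_model %in% c("mixed", "localization")
  for (i in seq_len(n)) {
    p_enr <- if (use_loc && ess_flag[i]) cfg$enrichment
             else if (use_loc) 0.03 else 0.15
    carry <- enr[runif(length(enr)) < p_enr]
    nb <- min(cfg$n_background_terms, length(bg))
    carry <- c(carry, if (nb > 0) sample(bg, nb))
    if (length(carry))
      recs[[length(recs) + 1L]] <- data.frame(protein = ids[i], term = carry,
                                              stringsAsFactors = FALSE)
  }
  loc <- do.call(rbind, recs)
  loc <- loc[order(loc$protein, loc$term, method = "radix"), , drop = FALSE]
  rownames(loc) <- NULL

  truth <- data.frame(protein = ids, block = block,
                      essential = as.integer(ess_flag),
                      phase_start = ph$start[block], phase_end = ph$end[block],
                      stringsAsFactors = FALSE)
  structure(list(network = net, expression = expr, localization = loc,
                 labels = ids[essential], truth = truth, cfg = cfg),
            class = "synthetic_dataset")
}

# zero-noise threshold margin of the two-level profile: active value minus
# the protein's own 3-sigma threshold, for the shortest phase
two_level_threshold_margin <- function(baseline, active, phase_len, T_) {
  f <- phase_len / T_
  d <- active - baseline
  mu <- baseline + f * d
  v <- d^2 * f * (1 - f) * T_ / (T_ - 1)
  thr <- mu + 3 * sqrt(v) * (1 - 1 / (1 + v))
  active - thr
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d proteins, %d edges, %d blocks, %d timepoints, %d essential\n",
    length(x$network$nodes), nrow(x$network$edges), x$cfg$n_communities,
    x$cfg$n_timepoints, length(x$labels)))
  invisible(x)
}

#' Write a synthetic dataset as the four standard input files plus truth
#'
#' Emits `ppi.tsv`, `expression.tsv`, `localization.tsv`, `essential.txt`
#' and `truth.tsv` under `dir`; the four inputs re-parse through the
#' package readers without loss.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ppi_edge_list(ds$network, file.path(dir, "ppi.tsv"))
  # header holds timepoint labels only; the id column is implicit
  rows <- vapply(seq_len(nrow(ds$expression)), function(i)
    paste(c(rownames(ds$expression)[i],
            formatC(ds$expression[i, ], format = "g", digits = 15)),
          collapse = "\t"), "")
  writeLines(c(paste(colnames(ds$expression), collapse = "\t"), rows),
             file.path(dir, "expression.tsv"))
  write.table(ds$localization, file.path(dir, "localization.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$labels, file.path(dir, "essential.txt"))
  write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Align a synthetic dataset for the pipeline
#' @param ds A [generate_dataset()] result.
#' @return An [align_dataset()] result.
#' @export
as_aligned_dataset <- function(ds) {
  align_dataset(ds$network, ds$expression, ds$localization, ds$labels)
}

#' Jaccard recovery of planted blocks by discovered communities
#'
#' For every planted block, the best Jaccard index between the block's
#' member set and any candidate community member set.
#'
#' @param ds A [generate_dataset()] result.
#' @param candidates Candidate member sets, e.g. from
#'   [collect_candidate_features()].
#' @return Numeric vector, one value per block.
#' @export
recovery_check <- function(ds, candidates) {
  blocks <- split(ds$truth$protein, ds$truth$block)
  vapply(blocks, function(b) {
    if (length(candidates) == 0L) return(0)
    max(vapply(candidates, function(s)
      length(intersect(b, s)) / length(union(b, s)), 0))
  }, 0)
}
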