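#' Per-protein activity statistics under the 3-sigma rule
#'
#' For a temporal expression series \eqn{EV_1..EV_n} of one protein the rule
#' computes the mean \eqn{\mu}, the sample variance \eqn{\sigma^2} (divisor
#' \eqn{n-1}), the fluctuation factor \eqn{F = 1/(1+\sigma^2)} and the
#' activity threshold
#' \deqn{t = \mu + 3\sigma(1 - F).}
#' A flat series has \eqn{\sigma^2 = 0}, hence \eqn{F = 1} and \eqn{t = \mu}:
#' the protein counts as active at every timepoint. Strongly fluctuating
#' proteins get a threshold well above their mean, so only clear expression
#' peaks mark them active.
#'
#' @param series Numeric vector of expression values, length >= 2, all finite.
#' @return List with `mu`, `var`, `fluct`, `threshold`.
#' @export
compute_activity_profile <- function(series) {
  if (length(series) < 2L)
    stop("activity profile needs >= 2 timepoints (variance undefined)")
  if (!all(is.finite(series))) stop("non-finite expression value")
  mu <- sum(series) / length(series)
  # a constant series has variance exactly zero (no floating-point residue)
  v <- if (max(series) == min(series)) 0
       else max(0, sum((series - mu)^2) / (length(series) - 1L))
  f <- 1 / (1 + v)
  list(mu = mu, var = v, fluct = f, threshold = mu + 3 * sqrt(v) * (1 - f))
}

# Vectorized profiles for a proteins x timepoints matrix.
activity_profiles <- function(expr) {
  if (ncol(expr) < 2L) stop("need >= 2 timepoints")
  if (!all(is.finite(expr))) stop("non-finite expression value")
  n <- ncol(expr)
  mu <- rowMeans(expr)
  v <- pmax(0, rowSums((expr - mu)^2) / (n - 1L))
  v[apply(expr, 1L, max) == apply(expr, 1L, min)] <- 0
  f <- 1 / (1 + v)
  thr <- mu + 3 * sqrt(v) * (1 - f)
  active <- expr >= thr  # >= : flat series stay active (t == mu == EV)
  list(mu = mu, var = v, fluct = f, threshold = thr, active = active)
}

#' Average a periodic expression series over its cycles
#'
#' Optional preprocessor for expression series that repeat a cycle (for
#' example several metabolic cycles measured back to back): the matrix is
#' folded to `period` timepoints by arithmetic mean across cycles. Off by
#' default in the pipeline.
#'
#' @param expr Proteins x timepoints matrix; column count must be a multiple
#'   of `period`.
#' @param period Number of timepoints per cycle.
#' @return Proteins x `period` matrix.
#' @export
average_cycles <- function(expr, period) {
  if (ncol(expr) %% period != 0L)
    stop("timepoint count is not a multiple of the period")
  k <- ncol(expr) / period
  out <- matrix(0, nrow(expr), period,
                dimnames = list(rownames(expr), paste0("t", seq_len(period))))
  for (j in seq_len(period))
    out[, j] <- rowMeans(expr[, j + period * (seq_len(k) - 1L), drop = FALSE])
  out
}

#' Build dynamic network snapshots from expression activity
#'
#' A protein is active at timepoint i when its expression there is at or
#' above its own 3-sigma threshold; proteins without an expression row are
#' treated as always active. Snapshot `E_t` keeps the static edges whose two
#' endpoints are both active at t. By default the first snapshot is replaced
#' by the full static edge set, so the stream starts from the complete
#' network and subsequent snapshots prune it.
#'
#' @param dataset An [align_dataset()] result (needs `network`, `expression`).
#' @param first_snapshot_static Replace `E_1` by the static edge set
#'   (default `TRUE`).
#' @return Object of class `dynamic_network`: list with `static`
#'   ([ppi_network()]), `snapshots` (list of edge data.frames), `active`
#'   (nodes x T logical matrix) and `profiles`.
#' @export
build_snapshots <- function(dataset, first_snapshot_static = TRUE) {
  net <- dataset$network
  expr <- dataset$expression
  if (is.null(expr) || ncol(expr) < 2L)
    stop("need an expression matrix with >= 2 timepoints")
  prof <- activity_profiles(expr)
  T_ <- ncol(expr)
  nodes <- net$nodes
  active <- matrix(TRUE, length(nodes), T_,
                   dimnames = list(nodes, colnames(expr)))
  have <- intersect(rownames(expr), nodes)
  active[have, ] <- prof$active[have, , drop = FALSE]
  snapshots <- vector("list", T_)
  for (t in seq_len(T_)) {
    on <- active[net$edges$u, t] & active[net$edges$v, t]
    snapshots[[t]] <- net$edges[on, , drop = FALSE]
    rownames(snapshots[[t]]) <- NULL
  }
  if (first_snapshot_static) snapshots[[1L]] <- net$edges
  structure(list(static = net, snapshots = snapshots, active = active,
                 profiles = prof),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf("dynamic_network: %d snapshots over %d nodes; edges per snapshot: %s\n",
              length(x$snapshots), length(x$static$nodes),
              paste(vapply(x$snapshots, nrow, 0L), collapse = " ")))
  invisible(x)
}

#' Derive the edge birth/death interaction stream from snapshots
#'
#' Time 1 emits a birth for every edge of the first snapshot; at each later
#' time t the edges of `E_t \\ E_{t-1}` are births and `E_{t-1} \\ E_t` are
#' deaths. Within a timestep deaths are ordered before births (so replay
#' never holds a duplicate edge), and events with the same time and kind are
#' ordered by their canonical endpoint pair.
#'
#' @param dyn A [build_snapshots()] result.
#' @return data.frame of class `interaction_stream` with columns
#'   `time` (integer), `kind` ("birth"/"death"), `u`, `v`.
#' @export
build_stream <- function(dyn) {
  snaps <- lapply(dyn$snapshots, function(e) paste(e$u, e$v, sep = "\t"))
  ev <- list()
  for (t in seq_along(snaps)) {
    if (t == 1L) {
      births <- snaps[[1L]]; deaths <- character()
    } else {
      births <- setdiff(snaps[[t]], snaps[[t - 1L]])
      deaths <- setdiff(snaps[[t - 1L]], snaps[[t]])
    }
    mk <- function(keys, kind) {
      if (length(keys) == 0L) return(NULL)
      p <- strsplit(sort(keys), "\t", fixed = TRUE)
      data.frame(time = t, kind = kind,
                 u = vapply(p, `[[`, "", 1L), v = vapply(p, `[[`, "", 2L),
                 stringsAsFactors = FALSE)
    }
    ev[[length(ev) + 1L]] <- mk(deaths, "death")
    ev[[length(ev) + 1L]] <- mk(births, "birth")
  }
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(time = integer(), kind = character(),
                      u = character(), v = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interaction_stream", "data.frame")
  out
}

#' Replay an interaction stream into snapshot edge sets
#'
#' Applies births and deaths in stored order and records the edge set after
#' each timestep. Errors on a birth of a present edge or a death of an absent
#' edge, so a successful replay certifies the stream's integrity.
#'
#' @param stream An [build_stream()] result.
#' @param times Number of timesteps to reconstruct (default: max event time).
#' @return List of edge-key character vectors (sorted), one per timestep.
#' @export
replay_stream <- function(stream, times = if (nrow(stream)) max(stream$time) else 0L) {
  present <- character()
  out <- vector("list", times)
  key <- paste(stream$u, stream$v, sep = "\t")
  for (t in seq_len(times)) {
    idx <- which(stream$time == t)
    for (i in idx) {
      k <- key[i]
      if (stream$kind[i] == "birth") {
        if (k %in% present) stop(sprintf("birth of present edge %s at t=%d", k, t))
        present <- c(present, k)
      } else {
        if (!(k %in% present)) stop(sprintf("death of absent edge %s at t=%d", k, t))
        present <- setdiff(present, k)
      }
    }
    out[[t]] <- sort(present)
  }
  out
}

#' Per-timestep edge and event counts of a dynamic network
#'
#' @param dyn A [build_snapshots()] result.
#' @param stream The matching [build_stream()] result.
#' @return data.frame with columns `time`, `EdgeNum` (edges in the snapshot),
#'   `NodeNum` (non-isolated nodes), `NewEdge` (births), `VanishEdge`
#'   (deaths); satisfies `EdgeNum_t = EdgeNum_{t-1} + NewEdge_t - VanishEdge_t`.
#' @export
stream_stats <- function(dyn, stream) {
  T_ <- length(dyn$snapshots)
  data.frame(
    time = seq_len(T_),
    EdgeNum = vapply(dyn$snapshots, nrow, 0L),
    NodeNum = vapply(dyn$snapshots,
                     function(e) length(unique(c(e$u, e$v))), 0L),
    NewEdge = vapply(seq_len(T_), function(t)
      sum(stream$time == t & stream$kind == "birth"), 0L),
    VanishEdge = vapply(seq_len(T_), function(t)
      sum(stream$time == t & stream$kind == "death"), 0L))
}

#' Write / read an interaction stream as TSV
#' @param stream Stream data.frame.
#' @param path File path.
#' @export
write_stream <- function(stream, path) {
  write.table(stream, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "character"))
  class(out) <- c("interaction_stream", "data.frame")
  out
}
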