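#' Create a streaming community-discovery engine
#'
#' The engine maintains the current graph and the live overlapping
#' communities while edge birth and death events are applied one at a time.
#' Community membership has two levels: core members (each participates in a
#' triangle whose three vertices are all core members of the same community)
#' and peripheral members (one-hop neighbours of the core). Only core
#' members propagate community labels.
#'
#' @param nodes Character vector of protein identifiers (the node universe).
#' @return An engine handle (environment) for [apply_birth()],
#'   [apply_death()], [observe_communities()], [live_communities()].
#' @export
tiles_engine <- function(nodes) {
  nodes <- sort_ids(nodes)
  env <- new.env(parent = emptyenv())
  env$nodes <- nodes
  env$ptr <- tiles_engine_new(length(nodes))
  class(env) <- "tiles_engine"
  env
}

node_index <- function(eng, id) {
  i <- match(id, eng$nodes)
  if (anyNA(i)) stop(sprintf("unknown protein '%s'", id[is.na(i)][1]))
  i
}

#' Apply a single edge birth or death to the engine
#'
#' A birth of an edge already present, or a death of an absent edge, is an
#' error: it means the interaction stream violates its replay invariant.
#'
#' @param eng A [tiles_engine()].
#' @param u,v Protein identifiers (endpoint order irrelevant).
#' @return The engine, invisibly.
#' @export
apply_birth <- function(eng, u, v) {
  tiles_engine_birth(eng$ptr, node_index(eng, u), node_index(eng, v))
  invisible(eng)
}

#' @rdname apply_birth
#' @export
apply_death <- function(eng, u, v) {
  tiles_engine_death(eng$ptr, node_index(eng, u), node_index(eng, v))
  invisible(eng)
}

#' Record the live communities as an observation window
#' @param eng A [tiles_engine()].
#' @return The engine, invisibly.
#' @export
observe_communities <- function(eng) {
  tiles_engine_observe(eng$ptr)
  invisible(eng)
}

#' Current live communities of an engine
#' @param eng A [tiles_engine()].
#' @return List of communities, each a list with `cid`, `core` and
#'   `peripheral` (character vectors of protein identifiers).
#' @export
live_communities <- function(eng) {
  lapply(tiles_engine_live(eng$ptr), function(co)
    list(cid = co$cid,
         core = eng$nodes[co$core],
         peripheral = eng$nodes[co$peripheral]))
}

#' Current graph held by an engine (edge data.frame)
#' @param eng A [tiles_engine()].
#' @return data.frame with columns `u`, `v` in canonical order.
#' @export
engine_graph <- function(eng) {
  g <- tiles_engine_graph(eng$ptr)
  p <- canonical_pair(eng$nodes[g$u], eng$nodes[g$v])
  e <- data.frame(u = p$u, v = p$v, stringsAsFactors = FALSE)
  e[order(e$u, e$v, method = "radix"), , drop = FALSE]
}

#' Run streaming community discovery over an interaction stream
#'
#' Applies the stream's events in stored order (within a timestep deaths
#' precede births) and records every live community after each
#' `observation_window` timesteps, plus once after the final timestep when
#' it does not fall on a window boundary.
#'
#' @param stream An interaction stream from [build_stream()].
#' @param nodes Node universe (character). Defaults to the identifiers seen
#'   in the stream.
#' @param observation_window Positive integer number of timesteps between
#'   observations (default 1: one observation per snapshot transition).
#' @param total_time Total number of timesteps (default: max event time).
#' @return Object of class `community_catalog`: list with `history`
#'   (data.frame `window`, `cid`, `protein`, `role`), `live` (final live
#'   communities as in [live_communities()]), `nodes`, and `n_windows`.
#' @export
run_stream <- function(stream, nodes = sort_ids(c(stream$u, stream$v)),
                       observation_window = 1L,
                       total_time = if (nrow(stream)) max(stream$time) else 0L) {
  eng <- tiles_engine(nodes)
  if (nrow(stream)) {
    iu <- node_index(eng, stream$u)
    iv <- node_index(eng, stream$v)
    tiles_engine_run(eng$ptr, as.integer(stream$time),
                     as.integer(stream$kind == "birth"), iu, iv,
                     as.integer(observation_window), as.integer(total_time))
  }
  h <- tiles_engine_history(eng$ptr)
  history <- data.frame(window = h$window, cid = h$cid,
                        protein = eng$nodes[h$node],
                        role = ifelse(h$core == 1L, "core", "peripheral"),
                        stringsAsFactors = FALSE)
  structure(list(history = history, live = live_communities(eng),
                 nodes = eng$nodes,
                 n_windows = if (nrow(history)) max(history$window) else 0L),
            class = "community_catalog")
}

#' @export
print.community_catalog <- function(x, ...) {
  cat(sprintf("community_catalog: %d live communities, %d observation windows, %d membership records\n",
              length(x$live), x$n_windows, nrow(x$history)))
  invisible(x)
}

#' Collect candidate community features from a catalog
#'
#' Every observed community state (one community in one observation window)
#' is a candidate feature defined by its member set; states with exactly the
#' same member set are collapsed to the first occurrence. Candidates are
#' ordered by (first window, community id).
#'
#' @param catalog A [run_stream()] result.
#' @param membership Which members define the feature: `"all"`
#'   (core + peripheral, default) or `"core"`.
#' @return List of character vectors (member sets, sorted), with attributes
#'   `window` and `cid` (integer vectors of first occurrence).
#' @export
collect_candidate_features <- function(catalog,
                                       membership = c("all", "core")) {
  membership <- match.arg(membership)
  h <- catalog$history
  if (membership == "core") h <- h[h$role == "core", , drop = FALSE]
  if (nrow(h) == 0L) {
    out <- list()
    attr(out, "window") <- integer()
    attr(out, "cid") <- integer()
    return(out)
  }
  grp <- split(h$protein, list(window = h$window, cid = h$cid), drop = TRUE)
  meta <- do.call(rbind, strsplit(names(grp), ".", fixed = TRUE))
  ord <- order(as.integer(meta[, 1]), as.integer(meta[, 2]))
  sets <- lapply(grp[ord], sort_ids)
  keys <- vapply(sets, paste, "", collapse = "\t")
  keep <- !duplicated(keys)
  out <- sets[keep]
  names(out) <- NULL
  attr(out, "window") <- as.integer(meta[ord, 1])[keep]
  attr(out, "cid") <- as.integer(meta[ord, 2])[keep]
  out
}

#' Binary community-membership feature matrix
#'
#' Entry (n, m) is 1 when protein n belongs to the member set of candidate
#' community m, else 0.
#'
#' @param proteins Character vector of proteins (rows; kept in given order).
#' @param candidates List of member sets from [collect_candidate_features()].
#' @return Integer 0/1 matrix, rows named by protein, columns `C1..Cm`.
#' @export
build_membership_matrix <- function(proteins, candidates) {
  m <- matrix(0L, length(proteins), length(candidates),
              dimnames = list(proteins,
                              if (length(candidates))
                                paste0("C", seq_along(candidates))
                              else character()))
  for (j in seq_along(candidates))
    m[proteins %in% candidates[[j]], j] <- 1L
  m
}

#' Write an observed-community catalog as TSV
#' @param catalog A [run_stream()] result.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog$history, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write candidate community features as TSV (feature_index, protein)
#' @param candidates From [collect_candidate_features()].
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(
    feature_index = rep(seq_along(candidates), lengths(candidates)),
    protein = unlist(candidates, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
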