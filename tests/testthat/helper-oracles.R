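# Independent oracles used across the suite. These are deliberately naive
# (literal loops, exhaustive enumeration) and share no code with the package
# internals they check.

# literal-summation activity statistics
oracle_activity <- function(series) {
  n <- length(series)
  mu <- 0
  for (x in series) mu <- mu + x
  mu <- mu / n
  v <- 0
  for (x in series) v <- v + (x - mu)^2
  v <- v / (n - 1)
  f <- 1 / (1 + v)
  list(mu = mu, var = v, fluct = f, threshold = mu + 3 * sqrt(v) * (1 - f))
}

# pair-counting ROC AUC with half credit for ties
oracle_auc <- function(y, s) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# rank-by-rank average precision (descending score, stable input order)
oracle_ap <- function(y, s) {
  ord <- order(-s)
  hits <- 0
  total <- 0
  for (k in seq_along(ord)) {
    if (y[ord[k]] == 1) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / sum(y == 1)
}

# brute-force scan for the minimal coverage epoch count
oracle_min_epochs <- function(M, N, P) {
  k <- 1
  while ((1 - M / N)^k > P) k <- k + 1
  k
}

# ---- community-engine invariants (exhaustive) ---------------------------

adjacency_from_edges <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  adj
}

# does `m` sit in a triangle whose three vertices are all in `core`?
oracle_in_core_triangle <- function(m, core, adj) {
  nb <- intersect(adj[[m]], core)
  if (length(nb) < 2) return(FALSE)
  for (i in seq_len(length(nb) - 1))
    for (j in (i + 1):length(nb))
      if (nb[j] %in% adj[[nb[i]]]) return(TRUE)
  FALSE
}

# check every live community of an engine against the structural contract
check_engine_invariants <- function(eng) {
  edges <- engine_graph(eng)
  adj <- adjacency_from_edges(edges, eng$nodes)
  for (co in live_communities(eng)) {
    expect_gte(length(co$core), 3)
    expect_length(intersect(co$core, co$peripheral), 0)
    for (m in co$core)
      expect_true(oracle_in_core_triangle(m, co$core, adj),
                  label = sprintf("core %s of cid %d in all-core triangle",
                                  m, co$cid))
    hood <- setdiff(unique(unlist(adj[co$core])), co$core)
    expect_setequal(co$peripheral, hood)
  }
  invisible(TRUE)
}

# quiet variant used where thousands of per-event checks are aggregated:
# returns a character vector of violations (empty when all invariants hold)
engine_violations <- function(eng) {
  edges <- engine_graph(eng)
  adj <- adjacency_from_edges(edges, eng$nodes)
  out <- character()
  for (co in live_communities(eng)) {
    if (length(co$core) < 3)
      out <- c(out, sprintf("cid %d: core smaller than 3", co$cid))
    if (length(intersect(co$core, co$peripheral)) > 0)
      out <- c(out, sprintf("cid %d: core/peripheral overlap", co$cid))
    for (m in co$core)
      if (!oracle_in_core_triangle(m, co$core, adj))
        out <- c(out, sprintf("cid %d: core %s outside all-core triangles",
                              co$cid, m))
    hood <- setdiff(unique(unlist(adj[co$core])), co$core)
    if (!setequal(co$peripheral, hood))
      out <- c(out, sprintf("cid %d: stale peripheral set", co$cid))
  }
  out
}

# maximal cliques of size >= 3 via igraph would be cheating the "independent"
# goal only mildly, but a direct component-of-triangle-graph oracle is easy:
# nodes of planted vertex-disjoint cliques are exactly the triangle-connected
# components of the final graph.
oracle_clique_blocks <- function(edges, nodes) {
  adj <- adjacency_from_edges(edges, nodes)
  comp <- list()
  seen <- character()
  for (s in nodes) {
    if (s %in% seen || length(adj[[s]]) < 2) next
    grp <- s
    queue <- s
    while (length(queue)) {
      m <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[m]]) {
        if (nb %in% grp) next
        # require a shared triangle before joining the component
        if (length(intersect(adj[[m]], adj[[nb]])) >= 1) {
          grp <- c(grp, nb)
          queue <- c(queue, nb)
        }
      }
    }
    if (length(grp) >= 3) comp[[length(comp) + 1]] <- sort(grp)
    seen <- c(seen, grp)
  }
  comp
}

# ---- random fixtures ----------------------------------------------------

# random aligned dataset -> dynamic network -> stream, small enough for
# per-event invariant checking
random_stream_fixture <- function(seed, n_nodes = NULL, n_times = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(8:30, 1)
  if (is.null(n_times)) n_times <- sample(3:5, 1)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  m <- round(1.8 * n_nodes)
  u <- character(0); v <- character(0)
  while (length(u) < m) {
    a <- sample(ids, 2)
    u <- c(u, a[1]); v <- c(v, a[2])
  }
  net <- ppi_network(u, v, nodes = ids)
  # random activity: each node active at each time with prob 0.7
  act <- matrix(runif(n_nodes * n_times) < 0.7, n_nodes, n_times,
                dimnames = list(ids, paste0("t", seq_len(n_times))))
  snaps <- lapply(seq_len(n_times), function(t) {
    on <- act[net$edges$u, t] & act[net$edges$v, t]
    net$edges[on, , drop = FALSE]
  })
  dyn <- structure(list(static = net, snapshots = snaps, active = act),
                   class = "dynamic_network")
  list(net = net, dyn = dyn, stream = build_stream(dyn), n_times = n_times)
}

# KKT residual of the soft-margin dual at a fitted model
kkt_residual <- function(model, X, cfg) {
  a <- model$alpha
  y <- model$y
  Kt <- tcrossprod(as.matrix(X))
  diag(Kt) <- diag(Kt) + cfg$lam
  f <- drop(Kt %*% (a * y)) + model$b
  resid <- max(abs(sum(a * y)), 0)
  margin <- y * f
  for (k in seq_along(a)) {
    if (a[k] < 1e-8) resid <- max(resid, 1 - margin[k])
    else if (a[k] > cfg$C - 1e-8) resid <- max(resid, margin[k] - 1)
    else resid <- max(resid, abs(margin[k] - 1))
  }
  resid
}

# exhaustive maximum-margin oracle for small separable 2-D sets: candidate
# directions come from opposite-class pairs and same-class edges
oracle_max_margin <- function(X, y) {
  dirs <- list()
  n <- nrow(X)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- X[i, ] - X[j, ]
    if (sum(d^2) < 1e-18) next
    if (y[i] != y[j]) dirs[[length(dirs) + 1]] <- d
    else dirs[[length(dirs) + 1]] <- c(-d[2], d[1])  # perpendicular
  }
  best <- 0
  for (d in dirs) {
    d <- d / sqrt(sum(d^2))
    proj <- drop(X %*% d)
    for (sgn in c(1, -1)) {
      p <- sgn * proj
      lo <- min(p[y == 1]); hi <- max(p[y == -1])
      marg <- (lo - hi) / 2
      best <- max(best, marg)
    }
  }
  best * 2  # full margin width, comparable with 2/||w||
}
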