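test_that("a fresh triangle founds a community and neighbors join as peripherals", {
  eng <- tiles_engine(c("a", "b", "c", "d"))
  apply_birth(eng, "a", "b")
  apply_birth(eng, "b", "c")
  expect_length(live_communities(eng), 0)  # no triangle yet
  apply_birth(eng, "a", "c")
  live <- live_communities(eng)
  expect_length(live, 1)
  expect_setequal(live[[1]]$core, c("a", "b", "c"))
  expect_length(live[[1]]$peripheral, 0)

  # a new node with no triangle becomes peripheral
  apply_birth(eng, "c", "d")
  live <- live_communities(eng)
  expect_setequal(live[[1]]$core, c("a", "b", "c"))
  expect_equal(live[[1]]$peripheral, "d")

  # closing a triangle with two cores promotes the third node
  apply_birth(eng, "b", "d")
  live <- live_communities(eng)
  expect_setequal(live[[1]]$core, c("a", "b", "c", "d"))
  expect_length(live[[1]]$peripheral, 0)
})

test_that("deaths demote, dissolve or preserve cores per the triangle rule", {
  # K4: every pair still shares a triangle after one edge dies
  eng <- tiles_engine(letters[1:4])
  for (p in list(c("a","b"), c("a","c"), c("a","d"), c("b","c"),
                 c("b","d"), c("c","d")))
    apply_birth(eng, p[1], p[2])
  live <- live_communities(eng)
  expect_length(live, 1)
  expect_setequal(live[[1]]$core, letters[1:4])
  apply_death(eng, "a", "b")
  live <- live_communities(eng)
  expect_setequal(live[[1]]$core, letters[1:4])
  check_engine_invariants(eng)

  # a lone triangle dissolves when any edge dies
  eng2 <- tiles_engine(c("a", "b", "c"))
  apply_birth(eng2, "a", "b"); apply_birth(eng2, "b", "c")
  apply_birth(eng2, "a", "c")
  apply_death(eng2, "a", "b")
  expect_length(live_communities(eng2), 0)

  # two triangles sharing edge bc: killing bc leaves no triangle at all
  eng3 <- tiles_engine(letters[1:4])
  for (p in list(c("a","b"), c("a","c"), c("b","c"), c("b","d"), c("c","d")))
    apply_birth(eng3, p[1], p[2])
  expect_setequal(live_communities(eng3)[[1]]$core, letters[1:4])
  apply_death(eng3, "b", "c")
  expect_length(live_communities(eng3), 0)
})

test_that("a community whose core disconnects splits into fresh communities", {
  eng <- tiles_engine(letters[1:7])
  # grow one community by repeated third-node promotion: K4 {a,b,c,d},
  # then e via (c,d), f via (d,e), g via (e,f)
  for (p in list(c("a","b"), c("a","c"), c("a","d"), c("b","c"),
                 c("b","d"), c("c","d"),
                 c("c","e"), c("d","e"),
                 c("d","f"), c("e","f"),
                 c("e","g"), c("f","g")))
    apply_birth(eng, p[1], p[2])
  live <- live_communities(eng)
  expect_length(live, 1)
  expect_setequal(live[[1]]$core, letters[1:7])
  old_cid <- live[[1]]$cid
  check_engine_invariants(eng)

  # sever the three bridge edges: both sides keep their own triangles but
  # the core-induced subgraph falls into {a,b,c,d} and {e,f,g}
  apply_death(eng, "c", "e")
  check_engine_invariants(eng)
  apply_death(eng, "d", "e")
  check_engine_invariants(eng)
  apply_death(eng, "d", "f")
  live <- live_communities(eng)
  expect_length(live, 2)
  cores <- lapply(live, `[[`, "core")
  expect_setequal(cores[[1]], c("a", "b", "c", "d"))
  expect_setequal(cores[[2]], c("e", "f", "g"))
  expect_equal(live[[1]]$cid, old_cid)  # smallest-member component keeps it
  expect_gt(live[[2]]$cid, old_cid)
  check_engine_invariants(eng)
})

test_that("stream errors surface on duplicate births and absent deaths", {
  eng <- tiles_engine(c("a", "b"))
  apply_birth(eng, "a", "b")
  expect_error(apply_birth(eng, "a", "b"), "present")
  expect_error(apply_death(eng, "a", "b"), NA)
  expect_error(apply_death(eng, "a", "b"), "absent")
  expect_error(apply_birth(eng, "a", "zz"), "unknown protein")
})

make_stream <- function(events) {
  df <- data.frame(time = integer(), kind = character(), u = character(),
                   v = character(), stringsAsFactors = FALSE)
  if (length(events))
    df <- do.call(rbind, lapply(events, function(e)
      data.frame(time = e[[1]], kind = e[[2]], u = e[[3]], v = e[[4]],
                 stringsAsFactors = FALSE)))
  class(df) <- c("interaction_stream", "data.frame")
  df
}

test_that("windowed observation records live communities per window", {
  st <- make_stream(list(list(1L, "birth", "a", "b"),
                         list(1L, "birth", "b", "c"),
                         list(1L, "birth", "a", "c")))
  cat3 <- run_stream(st, nodes = c("a", "b", "c"), observation_window = 1,
                     total_time = 3)
  expect_equal(cat3$n_windows, 3)
  expect_equal(unique(cat3$history$cid), 1L)
  expect_equal(nrow(cat3$history), 9)  # 3 cores x 3 windows

  empty <- run_stream(make_stream(list()), nodes = c("a", "b"),
                      total_time = 0)
  expect_equal(nrow(empty$history), 0)
  expect_length(empty$live, 0)

  # window of 2 over 3 timesteps: boundary at t=2 plus the final off-boundary
  cat2 <- run_stream(st, nodes = c("a", "b", "c"), observation_window = 2,
                     total_time = 3)
  expect_equal(cat2$n_windows, 2)
})

test_that("vertex-disjoint planted cliques are recovered exactly", {
  set.seed(1)
  sizes <- c(4, 5, 3)
  nodes <- sprintf("n%02d", seq_len(sum(sizes)))
  blocks <- split(nodes, rep(seq_along(sizes), sizes))
  ev <- list()
  for (b in blocks)
    for (i in seq_len(length(b) - 1)) for (j in (i + 1):length(b))
      ev[[length(ev) + 1]] <- list(1L, "birth", b[[i]], b[[j]])
  st <- make_stream(ev)
  cat <- run_stream(st, nodes = nodes, total_time = 1)
  expect_length(cat$live, 3)
  got <- lapply(cat$live, `[[`, "core")
  # oracle: triangle-connected components of the final graph
  edges <- data.frame(u = vapply(ev, `[[`, "", 3),
                      v = vapply(ev, `[[`, "", 4))
  want <- oracle_clique_blocks(edges, nodes)
  expect_equal(lapply(got, sort), want)
})

test_that("catalogs are deterministic and reversal empties the live set", {
  fx <- random_stream_fixture(21)
  c1 <- run_stream(fx$stream, nodes = fx$net$nodes, total_time = fx$n_times)
  c2 <- run_stream(fx$stream, nodes = fx$net$nodes, total_time = fx$n_times)
  expect_identical(c1$history, c2$history)
  expect_identical(c1$live, c2$live)

  # reversed stream (births and deaths swapped, order reversed)
  rev <- fx$stream[rev(seq_len(nrow(fx$stream))), ]
  rev$kind <- ifelse(rev$kind == "birth", "death", "birth")
  rev$time <- max(fx$stream$time) + 1L - rev$time
  eng <- tiles_engine(fx$net$nodes)
  for (i in seq_len(nrow(fx$stream))) {
    e <- fx$stream[i, ]
    if (e$kind == "birth") apply_birth(eng, e$u, e$v)
    else apply_death(eng, e$u, e$v)
  }
  for (i in seq_len(nrow(rev))) {
    e <- rev[i, ]
    if (e$kind == "birth") apply_birth(eng, e$u, e$v)
    else apply_death(eng, e$u, e$v)
  }
  expect_length(live_communities(eng), 0)
  expect_equal(nrow(engine_graph(eng)), 0)
})

test_that("structural invariants hold after every event on random streams", {
  for (seed in 1:30) {
    fx <- random_stream_fixture(seed, n_nodes = sample(10:24, 1))
    eng <- tiles_engine(fx$net$nodes)
    for (i in seq_len(nrow(fx$stream))) {
      e <- fx$stream[i, ]
      if (e$kind == "birth") apply_birth(eng, e$u, e$v)
      else apply_death(eng, e$u, e$v)
      check_engine_invariants(eng)
    }
  }
})

test_that("candidate features deduplicate identical member sets across windows", {
  st <- make_stream(list(list(1L, "birth", "a", "b"),
                         list(1L, "birth", "b", "c"),
                         list(1L, "birth", "a", "c"),
                         list(3L, "birth", "c", "d"),
                         list(3L, "birth", "b", "d")))
  cat <- run_stream(st, nodes = c("a", "b", "c", "d"), total_time = 4)
  cand <- collect_candidate_features(cat)
  # windows 1-2 observe {a,b,c}; windows 3-4 observe {a,b,c,d}
  expect_length(cand, 2)
  expect_equal(cand[[1]], c("a", "b", "c"))
  expect_equal(cand[[2]], c("a", "b", "c", "d"))
  expect_equal(attr(cand, "window"), c(1L, 3L))

  core_only <- collect_candidate_features(cat, membership = "core")
  expect_length(core_only, 2)
})

test_that("membership matrix is the brute-force indicator", {
  prots <- c("P", "Q", "R")
  cands <- list(c("P", "Q"), c("Q"), c("P", "R"), c("Z"))
  m <- build_membership_matrix(prots, cands)
  expect_equal(unname(m["P", ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(m["R", ]), c(0L, 0L, 1L, 0L))
  for (i in seq_along(prots)) for (j in seq_along(cands))
    expect_equal(m[i, j], as.integer(prots[i] %in% cands[[j]]))
  # protein in no community has an all-zero row
  expect_equal(sum(build_membership_matrix("X", cands)), 0L)
})
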