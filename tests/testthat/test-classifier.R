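test_that("coverage-epoch arithmetic matches the brute-force scan", {
  expect_equal(min_epochs_for_coverage(5, 5), 1L)
  expect_equal(min_epochs_for_coverage(5, 10, 0.001), 10L)
  expect_equal(min_epochs_for_coverage(100, 900, 0.001), 59L)
  expect_error(min_epochs_for_coverage(0, 5), "positive")
  expect_error(min_epochs_for_coverage(6, 5), "exceed")

  set.seed(37)
  for (i in 1:200) {
    N <- sample(2:2000, 1)
    M <- sample(seq_len(N), 1)
    P <- runif(1, 1e-5, 0.1)
    expect_equal(min_epochs_for_coverage(M, N, P), oracle_min_epochs(M, N, P))
  }
})

test_that("balanced subsets hold all positives plus an equal negative draw", {
  y <- c(rep(1, 3), rep(0, 10))
  set.seed(1)
  idx <- sample_balanced_subset(y)
  expect_length(idx, 6)
  expect_equal(sum(y[idx]), 3)
  expect_equal(anyDuplicated(idx), 0)

  # M = N: the subset is the whole split
  yy <- rep(c(1, 0), 4)
  expect_setequal(sample_balanced_subset(yy), seq_along(yy))

  # epoch draws differ but the sequence reproduces under the seed
  set.seed(99)
  two <- list(sample_balanced_subset(y), sample_balanced_subset(y))
  expect_false(identical(two[[1]], two[[2]]))
  set.seed(99)
  again <- list(sample_balanced_subset(y), sample_balanced_subset(y))
  expect_identical(two, again)

  expect_error(sample_balanced_subset(rep(1, 4)), "both classes")
})

test_that("stratified splitting keeps proportions and reproduces", {
  y <- c(rep(1, 20), rep(0, 80))
  sp <- split_dataset(y, 0.8, stratified = TRUE, seed = 5)
  expect_length(sp$train, 80)
  expect_equal(sum(y[sp$train]), 16)
  expect_setequal(c(sp$train, sp$test), 1:100)

  sp2 <- split_dataset(y, 0.8, stratified = TRUE, seed = 5)
  expect_identical(sp, sp2)

  expect_error(split_dataset(y, 1.0), "train_fraction")
  expect_error(split_dataset(rep(1, 20), stratified = TRUE), "both classes")
  expect_error(split_dataset(c(rep(1, 3), rep(0, 40)), stratified = TRUE),
               ">= 5 samples")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(12)
  n <- 8
  Xc <- matrix(rnorm(n * 4), n, 4)
  Xs <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c(0, 1), each = n / 2)
  spec <- model_spec(community_branch = c(5L, 4L),
                     subcellular_branch = c(4L, 4L), head = c(3L, 1L))
  set.seed(77)
  model <- list(branches = list(
    community = essnet:::build_branch(4, spec$community_branch),
    subcellular = essnet:::build_branch(3, spec$subcellular_branch)))
  model$head <- essnet:::build_head(8, spec$head)

  loss_at <- function(model) {
    fw <- essnet:::model_forward(model, list(community = Xc,
                                             subcellular = Xs), TRUE)
    p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- essnet:::model_forward(model, list(community = Xc,
                                           subcellular = Xs), TRUE)
  dz <- matrix((fw$p - y) / n, ncol = 1)
  hb <- essnet:::backprop_blocks(model$head, fw$head_caches, dz)
  offs <- c(0L, cumsum(fw$branch_dims))
  analytic <- list(head = hb$grads)
  for (k in seq_along(model$branches)) {
    nm <- names(model$branches)[k]
    dbr <- hb$dX[, (offs[k] + 1L):offs[k + 1L], drop = FALSE]
    analytic[[nm]] <- essnet:::backprop_blocks(
      model$branches[[nm]], fw$branch_caches[[nm]], dbr)$grads
  }
  eps <- 1e-5
  num_grad <- function(get, set) {
    m1 <- set(get() + eps); l1 <- loss_at(m1)
    m2 <- set(get() - eps); l2 <- loss_at(m2)
    (l1 - l2) / (2 * eps)
  }
  # spot-check a handful of coordinates in every parameter kind
  for (probe in list(c("community", 1, "W", 2), c("community", 2, "gamma", 1),
                     c("subcellular", 1, "beta", 2), c("head", 1, "W", 5),
                     c("head", 2, "b", 1))) {
    comp <- probe[1]; blk <- as.integer(probe[2])
    par <- probe[3]; pos <- as.integer(probe[4])
    get <- function() {
      tgt <- if (comp == "head") model$head else model$branches[[comp]]
      tgt[[blk]][[par]][pos]
    }
    set <- function(val) {
      m <- model
      if (comp == "head") m$head[[blk]][[par]][pos] <- val
      else m$branches[[comp]][[blk]][[par]][pos] <- val
      m
    }
    want <- num_grad(get, set)
    got <- analytic[[comp]][[blk]][[par]][pos]
    expect_equal(got, want, tolerance = 1e-5,
                 label = paste("grad", paste(probe, collapse = ".")))
  }
})

separable_fixture <- function(n = 40, seed = 42) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  Xc <- matrix(rnorm(n * 6, mean = rep(2 * y, 6)), n, 6)
  Xs <- matrix(rnorm(n * 4, mean = rep(-2 * y, 4)), n, 4)
  list(Xc = Xc, Xs = Xs, y = y)
}

test_that("training overfits a separable fixture and respects label symmetry", {
  fx <- separable_fixture()
  cfg <- train_config(epochs = 300, seed = 42)
  m <- train_model(fx$Xc, fx$Xs, fx$y, model_spec(), cfg)
  expect_lt(tail(m$trace, 1), 0.05)

  m_flip <- train_model(fx$Xc, fx$Xs, 1 - fx$y, model_spec(), cfg)
  expect_lt(tail(m_flip$trace, 1), 0.05)

  expect_error(train_config(epochs = 0), ">= 1")
  expect_error(train_model(NULL, NULL, fx$y), "at least one")
  expect_error(train_model(fx$Xc, fx$Xs, rep(0, 40)), "both classes")
})

test_that("training is bit-reproducible under one seed", {
  fx <- separable_fixture()
  cfg <- train_config(epochs = 30, seed = 7)
  m1 <- train_model(fx$Xc, fx$Xs, fx$y, model_spec(), cfg)
  m2 <- train_model(fx$Xc, fx$Xs, fx$y, model_spec(), cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(predict_scores(m1, fx$Xc, fx$Xs),
                   predict_scores(m2, fx$Xc, fx$Xs))
  # epochs resolve via the coverage rule when unset
  expect_equal(m1$epochs, 30)
  m3 <- train_model(fx$Xc, fx$Xs, fx$y, model_spec(),
                    train_config(seed = 7, min_epochs = 5))
  expect_equal(m3$epochs,
               max(min_epochs_for_coverage(20, 20, 0.001), 5))
})

test_that("prediction is deterministic, bounded, and width-checked", {
  fx <- separable_fixture()
  m <- train_model(fx$Xc, fx$Xs, fx$y, model_spec(),
                   train_config(epochs = 200, seed = 42))
  s <- predict_scores(m, fx$Xc, fx$Xs)
  expect_true(all(s >= 0 & s <= 1))
  dup <- predict_scores(m, fx$Xc[c(1, 1), ], fx$Xs[c(1, 1), ])
  expect_equal(dup[1], dup[2])
  # held-out copies of the two cluster centres separate perfectly
  ctr_c <- rbind(rep(0, 6), rep(2, 6))
  ctr_s <- rbind(rep(0, 4), rep(-2, 4))
  sc <- predict_scores(m, ctr_c, ctr_s)
  expect_equal(as.integer(sc >= 0.5), c(0L, 1L))
  expect_error(predict_scores(m, fx$Xc[, 1:3], fx$Xs), "width")
  expect_error(predict_scores(m, fx$Xc, NULL), "expects subcellular")
})

test_that("branch embeddings have length 16 under the default architecture", {
  set.seed(3)
  n <- 30
  Xc <- matrix(rbinom(n * 20, 1, 0.3), n, 20)
  Xs <- matrix(rbinom(n * 12, 1, 0.3), n, 12)
  y <- rep(c(0, 1), n / 2)
  m <- train_model(Xc, Xs, y, model_spec(), train_config(epochs = 5, seed = 1))
  emb <- branch_embeddings(m, Xc, Xs)
  expect_equal(ncol(emb$community), 16)
  expect_equal(ncol(emb$subcellular), 16)
  expect_equal(nrow(emb$community), n)
})
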