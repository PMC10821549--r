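#' Two-branch classifier architecture
#'
#' The community branch and the subcellular branch are stacks of fully
#' connected layers, each followed by batch normalization and ReLU, ending
#' in a 16-length representation per branch. The two 16-vectors are
#' concatenated and passed to a fully connected head (ReLU hidden layer,
#' then a single sigmoid output giving the essentiality probability).
#' Input widths are taken from the data at training time.
#'
#' @param community_branch Hidden widths of the community branch; must end
#'   in 16.
#' @param subcellular_branch Hidden widths of the subcellular branch; must
#'   end in 16.
#' @param head Widths of the head; must end in 1.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(community_branch = c(32L, 16L),
                       subcellular_branch = c(256L, 64L, 16L),
                       head = c(16L, 1L)) {
  stopifnot(length(community_branch) >= 1, length(subcellular_branch) >= 1,
            utils::tail(head, 1) == 1L)
  structure(list(community_branch = as.integer(community_branch),
                 subcellular_branch = as.integer(subcellular_branch),
                 head = as.integer(head)),
            class = "model_spec")
}

#' Training configuration
#'
#' `epochs = NULL` (default) resolves at training time to
#' `max(min_epochs_for_coverage(M, N, coverage_P), min_epochs)`, so every
#' non-essential training sample is drawn into at least one balanced epoch
#' subset with probability at least `1 - coverage_P`.
#'
#' @param epochs Number of epochs, or `NULL` for the coverage rule.
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed controlling initialization and every epoch's
#'   balanced draw.
#' @param coverage_P Bound on the probability that a given negative is never
#'   sampled (default 0.001).
#' @param min_epochs Floor on the epoch count (default 100).
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = NULL, learning_rate = 1e-3, seed = 1L,
                         coverage_P = 0.001, min_epochs = 100L) {
  if (!is.null(epochs) && epochs < 1L) stop("epochs must be >= 1")
  stopifnot(learning_rate > 0, coverage_P > 0, coverage_P < 1)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 seed = as.integer(seed), coverage_P = coverage_P,
                 min_epochs = as.integer(min_epochs)),
            class = "train_config")
}

#' Minimal epochs for negative-class coverage
#'
#' With M essential and N non-essential training samples, each balanced
#' epoch draws M of the N negatives, so a given negative is missed by one
#' epoch with probability `1 - M/N` and by k independent epochs with
#' probability `(1 - M/N)^k`. Returns the smallest k driving that
#' probability to at most `P`.
#'
#' @param M Positive count (0 < M <= N).
#' @param N Negative count.
#' @param P Probability bound in (0, 1), default 0.001.
#' @return Integer k.
#' @export
min_epochs_for_coverage <- function(M, N, P = 0.001) {
  if (M <= 0) stop("M must be positive")
  if (M > N) stop("M must not exceed N")
  stopifnot(P > 0, P < 1)
  if (M == N) return(1L)
  k <- ceiling(log(P) / log(1 - M / N))
  # guard the exact inequality against log rounding
  while ((1 - M / N)^k > P) k <- k + 1
  while (k > 1 && (1 - M / N)^(k - 1) <= P) k <- k - 1
  as.integer(k)
}

#' Draw one balanced training subset
#'
#' Keeps all M positives and samples M negatives uniformly without
#' replacement from the current RNG stream (one fresh draw per epoch).
#'
#' @param y 0/1 label vector of the training split.
#' @return Integer indices into `y`, positives first.
#' @export
sample_balanced_subset <- function(y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present in the training split")
  if (length(pos) > length(neg))
    stop("more positives than negatives; balanced downsampling undefined")
  c(pos, sort(sample(neg, length(pos))))
}

#' Stratified train/test split
#'
#' @param y 0/1 label vector over the sample universe.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param stratified Keep class proportions within one sample (default TRUE).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(y, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(y)
  set.seed(seed)
  if (stratified) {
    if (length(unique(y)) < 2L) stop("stratified split needs both classes")
    if (min(table(y)) < 5L) stop("stratified split needs >= 5 samples per class")
    train <- integer(0)
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      train <- c(train, sort(sample(idx, round(train_fraction * length(idx)))))
    }
    train <- sort(train)
  } else {
    train <- sort(sample(n, round(train_fraction * n)))
  }
  test <- setdiff(seq_len(n), train)
  if (length(test) == 0L || length(train) == 0L)
    stop("degenerate split: empty train or test set")
  list(train = train, test = test)
}

## ---- dense / batch-norm blocks ------------------------------------------

bn_eps <- 1e-5
bn_momentum <- 0.1

init_block <- function(d_in, d_out, bn, act) {
  list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out),
       bn = bn, act = act,
       gamma = if (bn) rep(1, d_out), beta = if (bn) numeric(d_out),
       rmean = if (bn) numeric(d_out), rvar = if (bn) rep(1, d_out))
}

forward_block <- function(block, X, train) {
  Z <- X %*% block$W + rep(block$b, each = nrow(X))
  cache <- list(X = X)
  if (block$bn) {
    if (train) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
      cache$new_rmean <- (1 - bn_momentum) * block$rmean + bn_momentum * mu
      cache$new_rvar <- (1 - bn_momentum) * block$rvar + bn_momentum * v
    } else {
      mu <- block$rmean
      v <- block$rvar
    }
    xhat <- (Z - rep(mu, each = nrow(Z))) / rep(sqrt(v + bn_eps), each = nrow(Z))
    cache$xhat <- xhat
    cache$sd <- sqrt(v + bn_eps)
    Z <- xhat * rep(block$gamma, each = nrow(Z)) + rep(block$beta, each = nrow(Z))
  }
  cache$pre <- Z
  A <- switch(block$act, relu = pmax(Z, 0), linear = Z)
  list(out = A, cache = cache)
}

backward_block <- function(block, cache, dA) {
  n <- nrow(dA)
  dZ <- if (block$act == "relu") dA * (cache$pre > 0) else dA
  g <- list()
  if (block$bn) {
    xhat <- cache$xhat
    g$gamma <- colSums(dZ * xhat)
    g$beta <- colSums(dZ)
    gam <- rep(block$gamma, each = n)
    sdv <- rep(cache$sd, each = n)
    dxhat <- dZ * gam
    dZ <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) / sdv
  }
  g$W <- crossprod(cache$X, dZ)
  g$b <- colSums(dZ)
  g$dX <- dZ %*% t(block$W)
  g
}

build_branch <- function(d_in, widths) {
  blocks <- list()
  d <- d_in
  for (w in widths) {
    blocks[[length(blocks) + 1L]] <- init_block(d, w, bn = TRUE, act = "relu")
    d <- w
  }
  blocks
}

build_head <- function(d_in, widths) {
  blocks <- list()
  d <- d_in
  for (i in seq_along(widths)) {
    act <- if (i == length(widths)) "linear" else "relu"
    blocks[[length(blocks) + 1L]] <- init_block(d, widths[i], bn = FALSE,
                                                act = act)
    d <- widths[i]
  }
  blocks
}

run_blocks <- function(blocks, X, train) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    f <- forward_block(blocks[[i]], X, train)
    X <- f$out
    caches[[i]] <- f$cache
  }
  list(out = X, caches = caches)
}

backprop_blocks <- function(blocks, caches, dA) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    g <- backward_block(blocks[[i]], caches[[i]], dA)
    dA <- g$dX
    g$dX <- NULL
    grads[[i]] <- g
  }
  list(grads = grads, dX = dA)
}

adam_step <- function(blocks, grads, state, lr, t, prefix) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(blocks)) {
    for (p in intersect(names(grads[[i]]), c("W", "b", "gamma", "beta"))) {
      g <- grads[[i]][[p]]
      key <- paste0(prefix, ":", i, ".", p)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
      mhat <- state$m[[key]] / (1 - b1^t)
      vhat <- state$v[[key]] / (1 - b2^t)
      blocks[[i]][[p]] <- blocks[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(blocks = blocks, state = state)
}

update_running_stats <- function(blocks, caches) {
  for (i in seq_along(blocks)) {
    if (isTRUE(blocks[[i]]$bn)) {
      blocks[[i]]$rmean <- caches[[i]]$new_rmean
      blocks[[i]]$rvar <- caches[[i]]$new_rvar
    }
  }
  blocks
}

model_forward <- function(model, Xs, train) {
  outs <- list(); caches <- list()
  for (nm in names(model$branches)) {
    r <- run_blocks(model$branches[[nm]], Xs[[nm]], train)
    outs[[nm]] <- r$out
    caches[[nm]] <- r$caches
  }
  concat <- do.call(cbind, outs)
  h <- run_blocks(model$head, concat, train)
  z <- drop(h$out)
  p <- 1 / (1 + exp(-z))
  list(p = p, z = z, branch_caches = caches, head_caches = h$caches,
       branch_dims = vapply(outs, ncol, 0L))
}

#' Train the two-branch essentiality classifier
#'
#' Each epoch draws a fresh balanced subset (all positives plus an equal
#' number of negatives), runs one full-batch forward/backward pass under
#' binary cross-entropy, and takes one Adam step. Batch-normalization
#' running statistics accumulate over epochs and are used at prediction
#' time. All randomness (initialization and the per-epoch draws) comes from
#' `cfg$seed`, so training is reproducible.
#'
#' @param community_X Binary community feature matrix (rows = samples), or
#'   `NULL` to train without the community branch.
#' @param subcellular_X Binary subcellular feature matrix, or `NULL`.
#' @param y 0/1 labels aligned with the feature rows.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @return Object of class `essnet_model`: branches, head, loss trace,
#'   resolved epoch count.
#' @export
train_model <- function(community_X, subcellular_X, y, spec = model_spec(),
                        cfg = train_config()) {
  Xs <- list()
  if (!is.null(community_X) && ncol(community_X) > 0L)
    Xs$community <- as.matrix(community_X)
  if (!is.null(subcellular_X) && ncol(subcellular_X) > 0L)
    Xs$subcellular <- as.matrix(subcellular_X)
  if (length(Xs) == 0L) stop("at least one feature branch is required")
  n <- length(y)
  for (x in Xs) if (nrow(x) != n) stop("feature rows and labels differ")
  M <- sum(y == 1); Nn <- sum(y == 0)
  if (M == 0L || Nn == 0L) stop("both classes required for training")
  epochs <- cfg$epochs
  if (is.null(epochs))
    epochs <- max(min_epochs_for_coverage(M, Nn, cfg$coverage_P),
                  cfg$min_epochs)
  set.seed(cfg$seed)
  branch_widths <- list(community = spec$community_branch,
                        subcellular = spec$subcellular_branch)
  model <- list(branches = list(), spec = spec)
  for (nm in names(Xs))
    model$branches[[nm]] <- build_branch(ncol(Xs[[nm]]), branch_widths[[nm]])
  d_cat <- sum(vapply(names(Xs), function(nm)
    utils::tail(branch_widths[[nm]], 1L), 0L))
  model$head <- build_head(d_cat, spec$head)
  model$input_widths <- vapply(Xs, ncol, 0L)

  state <- list(m = list(), v = list())
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample_balanced_subset(y)
    yb <- y[idx]
    Xb <- lapply(Xs, function(x) x[idx, , drop = FALSE])
    fw <- model_forward(model, Xb, train = TRUE)
    p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", ep))
    trace[ep] <- loss
    dz <- matrix((fw$p - yb) / length(yb), ncol = 1L)
    hb <- backprop_blocks(model$head, fw$head_caches, dz)
    # split the concatenated gradient back onto the branches
    offs <- c(0L, cumsum(fw$branch_dims))
    grads <- list()
    for (k in seq_along(model$branches)) {
      nm <- names(model$branches)[k]
      dbr <- hb$dX[, (offs[k] + 1L):offs[k + 1L], drop = FALSE]
      bb <- backprop_blocks(model$branches[[nm]], fw$branch_caches[[nm]], dbr)
      grads[[nm]] <- bb$grads
      model$branches[[nm]] <- update_running_stats(model$branches[[nm]],
                                                   fw$branch_caches[[nm]])
    }
    for (nm in names(model$branches)) {
      st <- adam_step(model$branches[[nm]], grads[[nm]], state,
                      cfg$learning_rate, ep, prefix = nm)
      model$branches[[nm]] <- st$blocks
      state <- st$state
    }
    st <- adam_step(model$head, hb$grads, state, cfg$learning_rate, ep,
                    prefix = "head")
    model$head <- st$blocks
    state <- st$state
  }
  model$trace <- trace
  model$epochs <- epochs
  class(model) <- "essnet_model"
  model
}

#' @export
print.essnet_model <- function(x, ...) {
  cat(sprintf("essnet_model: branches [%s], %d epochs, final balanced-subset loss %.4f\n",
              paste(names(x$branches), collapse = ", "), x$epochs,
              utils::tail(x$trace, 1)))
  invisible(x)
}

#' Predict essentiality scores
#'
#' Runs the trained model in inference mode (batch normalization uses the
#' running statistics, so scores are deterministic and row-independent).
#'
#' @param model An [train_model()] result.
#' @param community_X,subcellular_X Feature matrices with the training
#'   widths; pass only the branches the model was trained with.
#' @return Numeric vector of probabilities in `[0, 1]` (named by rownames
#'   when available).
#' @export
predict_scores <- function(model, community_X = NULL, subcellular_X = NULL) {
  Xs <- list()
  if ("community" %in% names(model$branches)) {
    if (is.null(community_X)) stop("model expects community features")
    Xs$community <- as.matrix(community_X)
  }
  if ("subcellular" %in% names(model$branches)) {
    if (is.null(subcellular_X)) stop("model expects subcellular features")
    Xs$subcellular <- as.matrix(subcellular_X)
  }
  for (nm in names(Xs))
    if (ncol(Xs[[nm]]) != model$input_widths[[nm]])
      stop(sprintf("%s feature width %d does not match training width %d",
                   nm, ncol(Xs[[nm]]), model$input_widths[[nm]]))
  fw <- model_forward(model, Xs, train = FALSE)
  p <- fw$p
  rn <- rownames(Xs[[1]])
  if (!is.null(rn)) names(p) <- rn
  p
}

#' Branch representations (the 16-length embeddings before the head)
#' @param model A trained model.
#' @param community_X,subcellular_X Feature matrices as in
#'   [predict_scores()].
#' @return Named list of embedding matrices, one per branch.
#' @export
branch_embeddings <- function(model, community_X = NULL,
                              subcellular_X = NULL) {
  Xs <- list()
  if ("community" %in% names(model$branches))
    Xs$community <- as.matrix(community_X)
  if ("subcellular" %in% names(model$branches))
    Xs$subcellular <- as.matrix(subcellular_X)
  lapply(seq_along(Xs), function(k) {
    run_blocks(model$branches[[names(Xs)[k]]], Xs[[k]], train = FALSE)$out
  }) -> out
  names(out) <- names(Xs)
  out
}
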