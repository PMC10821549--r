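test_that("a separable 1-D problem is classified with positive weight", {
  X <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c(-1, -1, 1, 1)
  fit <- train_linear_svm(X, y, svm_config(C = 1, lam = 0))
  expect_gt(fit$w[1], 0)
  expect_equal(sign(drop(X %*% fit$w) + fit$b), y)
  expect_lte(kkt_residual(fit, X, svm_config(C = 1, lam = 0)), 1e-6)
})

test_that("a class-constant feature gets zero weight", {
  set.seed(2)
  X <- cbind(sig = c(-1, -1, -1, 1, 1, 1), const = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  fit <- train_linear_svm(X, y)
  expect_lt(abs(fit$w["const"]), 1e-5)
  expect_error(train_linear_svm(X, rep(1, 6)), "both classes")
})

test_that("the dual solution matches an independent QP solver", {
  set.seed(4)
  n <- 24
  X <- rbind(matrix(rnorm(n / 2 * 2, mean = -1), ncol = 2),
             matrix(rnorm(n / 2 * 2, mean = 1), ncol = 2))
  y <- rep(c(-1, 1), each = n / 2)
  cfg <- svm_config(C = 2, lam = 1e-3, tol = 1e-9)
  fit <- train_linear_svm(X, y, cfg)

  Kt <- tcrossprod(X)
  diag(Kt) <- diag(Kt) + cfg$lam
  H <- (y %o% y) * Kt
  qp <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                      l = rep(0, n), u = rep(cfg$C, n), r = 0,
                      sigf = 9, maxiter = 200)
  alpha_qp <- kernlab::primal(qp)
  w_qp <- drop(crossprod(X, alpha_qp * y))
  expect_equal(fit$w, w_qp, tolerance = 1e-4)
  # identical dual objective value at both solutions
  obj <- function(a) 0.5 * drop(a %*% H %*% a) - sum(a)
  expect_equal(obj(fit$alpha), obj(alpha_qp), tolerance = 1e-6)
})

test_that("the margin matches the exhaustive support-pair oracle", {
  set.seed(9)
  repeat {  # draw until linearly separable with a real margin
    X <- rbind(matrix(rnorm(8, mean = -2), ncol = 2),
               matrix(rnorm(8, mean = 2), ncol = 2))
    y <- rep(c(-1, 1), each = 4)
    if (oracle_max_margin(X, y) > 0.5) break
  }
  fit <- train_linear_svm(X, y, svm_config(C = 1e3, lam = 1e-9, tol = 1e-10))
  expect_equal(2 / sqrt(sum(fit$w^2)), oracle_max_margin(X, y),
               tolerance = 1e-6)
})

test_that("KKT conditions hold on random fixtures", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sign(X[, 1] + rnorm(n, sd = 0.5))
    y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    cfg <- svm_config(C = sample(c(0.5, 1, 10), 1))
    fit <- train_linear_svm(X, y, cfg)
    expect_lte(kkt_residual(fit, X, cfg), 1e-6)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= cfg$C + 1e-12))
    expect_lt(abs(sum(fit$alpha * fit$y)), 1e-9)
  }
})

test_that("RFE removes zero-weight features first and ranks a single feature", {
  y <- rep(c(0, 1), each = 5)
  one <- matrix(2 * y - 1, ncol = 1)
  expect_equal(rfe_rank(one, y)$ranked, 1L)

  X <- cbind(copy = 2 * y - 1, zeros = 0)
  r <- rfe_rank(X, y)
  expect_equal(r$ranked, c(1L, 2L))
  expect_equal(unname(r$criterion[2]), 0)  # the zero column had criterion 0

  set.seed(5)
  X3 <- cbind(copy = 2 * y - 1,
              noise = rnorm(10, sd = 0.5),
              zeros = 0)
  r3 <- rfe_rank(X3, y)
  expect_equal(r3$ranked[1], 1L)      # best: the label copy
  expect_equal(r3$ranked[3], 3L)      # worst: the zero column, removed first
  expect_equal(unname(r3$criterion[3]), 0)
})

test_that("RFE output is a permutation and informative features rise", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n * 15), n, 15)
  w_true <- c(rep(2, 4), rep(0, 11))
  y <- as.integer(drop(X %*% w_true) + rnorm(n, sd = 0.3) > 0)
  r <- rfe_rank(X, y)
  expect_setequal(r$ranked, 1:15)
  expect_true(all(1:4 %in% r$ranked[1:7]))
})

test_that("argmin ties break toward the smallest original column index", {
  y <- rep(c(0, 1), each = 4)
  X <- cbind(a = 0, b = 0, c = 2 * y - 1)  # two identical zero columns
  r <- rfe_rank(X, y)
  expect_equal(r$ranked, c(3L, 2L, 1L))  # col 1 removed before col 2
})

test_that("top-community selection saturates and validates k", {
  y <- rep(c(0, 1), each = 10)
  set.seed(6)
  X <- matrix(rbinom(20 * 10, 1, 0.4), 20, 10)
  X[, 1] <- y
  r <- rfe_rank(X, y)
  expect_length(select_top_communities(r, 5), 5)
  expect_warning(sel <- select_top_communities(r, 64), "only 10")
  expect_length(sel, 10)
  expect_error(select_top_communities(r, 0), "positive")
  # original column order restored
  expect_false(is.unsorted(select_top_communities(r, 5)))
})

test_that("subcellular rank filter orders by count and removes ranks 11-64", {
  # five terms with counts 9,7,7,3,1: ties broken lexicographically
  tab <- data.frame(
    protein = c(sprintf("p%02d", 1:9), sprintf("p%02d", 1:7),
                sprintf("q%02d", 1:7), sprintf("p%02d", 1:3), "p01"),
    term = c(rep("zeta", 9), rep("beta", 7), rep("alpha", 7),
             rep("gamma", 3), "omega"))
  m <- subcellular_features(tab, sprintf("p%02d", 1:9))
  expect_equal(colnames(m), c("zeta", "alpha", "beta", "gamma", "omega"))
  expect_equal(unname(m["p01", ]), c(1L, 0L, 1L, 1L, 1L))
  expect_equal(unname(m["p09", ]), c(1L, 0L, 0L, 0L, 0L))

  # with >= 1024 distinct terms the filter leaves exactly 970 columns
  set.seed(10)
  prot <- sprintf("P%03d", 1:40)
  big <- data.frame(protein = sample(prot, 1500, replace = TRUE),
                    term = sprintf("t%04d", 1:1500))
  mb <- subcellular_features(big, prot)
  expect_equal(ncol(mb), 970)
  expect_equal(ncol(mb), min(1500, 1024) - length(11:64))
  expect_true(all(!(attr(mb, "term_rank") %in% 11:64)))

  # a protein with no annotation has an all-zero row
  m0 <- subcellular_features(tab, c("p01", "stranger"))
  expect_equal(sum(m0["stranger", ]), 0L)
})

test_that("column-count identity holds for intermediate term counts", {
  prot <- sprintf("P%02d", 1:10)
  for (nterms in c(5, 10, 11, 40, 64, 65, 200)) {
    tab <- data.frame(protein = sample(prot, nterms, replace = TRUE),
                      term = sprintf("t%03d", 1:nterms))
    m <- subcellular_features(tab, prot)
    expect_equal(ncol(m),
                 min(nterms, 1024) - sum(11:64 <= min(nterms, 1024)))
  }
})
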