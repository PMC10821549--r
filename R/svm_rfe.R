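#' Configuration for the linear soft-margin SVM
#'
#' `C` bounds the dual coefficients (soft margin); `lam` is a small ridge
#' added to the linear-kernel diagonal that keeps the dual strictly convex
#' even on degenerate feature sets; `tol` is the maximal KKT violation
#' accepted at convergence.
#'
#' @param C Positive soft-margin bound (default 1).
#' @param lam Nonnegative diagonal regularization (default 1e-6).
#' @param tol Convergence tolerance on the dual KKT gap (default 1e-6).
#' @param max_iter Iteration cap for the pairwise solver.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(C = 1, lam = 1e-6, tol = 1e-6, max_iter = 2000000L) {
  stopifnot(C > 0, lam >= 0, tol > 0)
  structure(list(C = C, lam = lam, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "svm_config")
}

# Solve the soft-margin dual (kernel K + lam*I already folded into Kt):
# thin wrapper over the compiled pairwise solver.
smo_solve <- function(Kt, y, C, tol, max_iter) {
  smo_solve_cpp(as.matrix(Kt), as.numeric(y), C, tol, as.integer(max_iter))
}

#' Train a linear soft-margin SVM (dual form)
#'
#' Maximizes the soft-margin dual with linear kernel plus a ridge `lam` on
#' the diagonal, box constraint `0 <= alpha_k <= C` and the balance
#' constraint `sum(alpha * y) = 0`. The weight vector is the support-vector
#' expansion `w = sum_k alpha_k y_k x_k`.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param y Labels in `{-1, +1}` (0/1 input is recoded).
#' @param cfg An [svm_config()].
#' @return Object of class `svm_model`: list with `w`, `b`, `alpha`, `y`,
#'   `iterations`, `gap`.
#' @export
train_linear_svm <- function(X, y, cfg = svm_config()) {
  X <- as.matrix(X)
  y <- recode_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  Kt <- tcrossprod(X)
  diag(Kt) <- diag(Kt) + cfg$lam
  fit <- smo_solve(Kt, y, cfg$C, cfg$tol, cfg$max_iter)
  w <- drop(crossprod(X, fit$alpha * y))
  structure(list(w = w, b = fit$b, alpha = fit$alpha, y = y,
                 iterations = fit$iterations, gap = fit$gap, cfg = cfg),
            class = "svm_model")
}

recode_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be 0/1 or -1/+1")
  y
}

#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly trains the linear SVM on the surviving features, scores each
#' surviving feature i by the squared weight `c_i = w_i^2`, and removes the
#' feature with the smallest criterion (ties broken by the smallest original
#' column index) until none survive. Features removed last are the most
#' informative, so the returned ranking is best-first.
#'
#' @param X Sample-by-feature matrix (binary membership features in the
#'   pipeline, any numeric features in general).
#' @param y Labels (0/1 or -1/+1).
#' @param cfg An [svm_config()].
#' @param chunk Number of features to drop per round (default 1, the exact
#'   one-per-round elimination; larger values trade fidelity for speed).
#' @return Object of class `rfe_ranking`: list with `ranked` (best-first
#'   original column indices), `criterion` (the c value each feature had in
#'   the round it was removed, aligned with `ranked`) and `n_features`.
#' @export
rfe_rank <- function(X, y, cfg = svm_config(), chunk = 1L) {
  X <- as.matrix(X)
  y <- recode_labels(y)
  p <- ncol(X)
  if (p < 1L) stop("need at least one feature")
  stopifnot(chunk >= 1L)
  Kt <- tcrossprod(X)
  diag(Kt) <- diag(Kt) + cfg$lam
  s <- seq_len(p)
  ranked <- integer(0)
  crit <- numeric(0)
  round_i <- 0L
  while (length(s) > 0L) {
    round_i <- round_i + 1L
    fit <- tryCatch(smo_solve(Kt, y, cfg$C, cfg$tol, cfg$max_iter),
                    error = function(e)
                      stop(sprintf("RFE round %d: %s", round_i,
                                   conditionMessage(e))))
    w <- drop(crossprod(X[, s, drop = FALSE], fit$alpha * y))
    cvals <- w^2
    ndrop <- min(chunk, length(s))
    drop_pos <- order(cvals, seq_along(s))[seq_len(ndrop)]
    drop_pos <- sort(drop_pos, decreasing = TRUE)  # worst last when chunked
    for (dp in drop_pos) {
      ranked <- c(s[dp], ranked)
      crit <- c(cvals[dp], crit)
      xf <- X[, s[dp]]
      Kt <- Kt - tcrossprod(xf)   # downdate the linear kernel
      s <- s[-dp]
    }
  }
  structure(list(ranked = ranked, criterion = crit, n_features = p),
            class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf("rfe_ranking over %d features; best five: %s\n",
              x$n_features,
              paste(head(x$ranked, 5), collapse = ", ")))
  invisible(x)
}

#' Keep the top-ranked community features
#'
#' @param ranking An [rfe_rank()] result.
#' @param k Number of features to keep (default 64). When fewer features
#'   exist all are returned with a warning.
#' @return Integer vector of original column indices, sorted increasing so
#'   the selected columns keep their original matrix order.
#' @export
select_top_communities <- function(ranking, k = 64L) {
  if (k < 1L) stop("k must be a positive integer")
  if (k > length(ranking$ranked)) {
    warning(sprintf("only %d features available; returning all",
                    length(ranking$ranked)))
    k <- length(ranking$ranked)
  }
  sort(ranking$ranked[seq_len(k)])
}

#' Rank-filtered binary subcellular-localization features
#'
#' Localization terms are ranked by the number of annotated proteins
#' (descending, ties lexicographic). The top `top_n` terms are kept except
#' ranks `exclude_lo..exclude_hi`, which contribute little signal; with at
#' least `top_n` distinct terms and the defaults this leaves 970 columns.
#'
#' @param table Localization data.frame (`protein`, `term`).
#' @param proteins Character vector: the feature-matrix rows, in order.
#' @param top_n Number of top-ranked terms considered (default 1024).
#' @param exclude_lo,exclude_hi Rank band removed (defaults 11 and 64).
#' @return Integer 0/1 matrix, rows `proteins`, one column per retained term
#'   in rank order; attribute `term_rank` gives each column's rank.
#' @export
subcellular_features <- function(table, proteins, top_n = 1024L,
                                 exclude_lo = 11L, exclude_hi = 64L) {
  counts <- table(factor(table$term))
  if (length(counts) == 0L)
    return(matrix(0L, length(proteins), 0L,
                  dimnames = list(proteins, character())))
  terms <- sort_ids(names(counts))
  cnt <- as.integer(counts[terms])
  ord <- order(-cnt, terms, method = "radix")
  terms <- terms[ord]
  ranks <- seq_along(terms)
  keep <- ranks <= top_n & !(ranks >= exclude_lo & ranks <= exclude_hi)
  terms <- terms[keep]
  m <- matrix(0L, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  hit <- table$protein %in% proteins & table$term %in% terms
  if (any(hit))
    m[cbind(match(table$protein[hit], proteins),
            match(table$term[hit], terms))] <- 1L
  attr(m, "term_rank") <- ranks[keep]
  m
}

#' Write an RFE ranking as TSV (rank, feature_index, criterion_at_removal)
#' @param ranking An [rfe_rank()] result.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(
    data.frame(rank = seq_along(ranking$ranked),
               feature_index = ranking$ranked,
               criterion_at_removal = ranking$criterion),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
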