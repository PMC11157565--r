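# Independent oracles used across the suite. Each re-derives the quantity
# from first principles, never calling the code path it checks.

# Plug-in mutual information from a joint contingency table (nats).
oracle_mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  as.numeric(s)
}

oracle_mi <- function(x, y) oracle_mi_from_table(table(x, y))

# Exhaustive greedy mRMR on natively discrete features: recompute the
# incremental criterion argmax at every step with its own MI.
oracle_mrmr_order <- function(X, y) {
  m <- ncol(X)
  rel <- vapply(seq_len(m), function(j) oracle_mi(X[, j], y), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(m)
  while (length(remaining) > 0) {
    crit <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(rel[j])
      rel[j] - mean(vapply(selected, function(s) oracle_mi(X[, j], X[, s]),
                           numeric(1)))
    }, numeric(1))
    pick <- remaining[which.max(crit)] # first max = lowest index tie-break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# O(n^2) pairwise non-dominated filter (minimization).
oracle_non_dominated <- function(P) {
  n <- nrow(P)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(P[j, ] <= P[i, ]) && any(P[j, ] < P[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# Fold-loop CV RMSE with mixOmics::pls as the regression engine: an
# independent route through the same contract (shuffle once by seed,
# contiguous folds, mean of per-fold RMSEs).
oracle_cv_pls_rmse <- function(X, y, folds, ncomp, shuffle_seed) {
  n <- nrow(X)
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(shuffle_seed)
    p <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    p
  })
  sizes <- rep(n %/% folds, folds) +
    c(rep(1, n %% folds), rep(0, folds - n %% folds))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(folds), sizes)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  per_fold <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                         scale = TRUE, mode = "regression")
    pr <- predict(fit, X[!tr, , drop = FALSE])$predict[, , ncomp]
    sqrt(mean((y[!tr] - pr)^2))
  }, numeric(1))
  mean(per_fold)
}

# Small random discrete design for ranking tests.
random_discrete_toy <- function(m, n, n_levels = 3) {
  X <- matrix(sample.int(n_levels, n * m, replace = TRUE), n, m)
  colnames(X) <- paste0("f", seq_len(m))
  y <- X[, 1] + sample.int(2, n, replace = TRUE) - 1
  list(X = X, y = y,
       data = dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(y = y)))
}
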