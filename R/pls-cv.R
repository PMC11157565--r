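# Univariate-response partial least squares (NIPALS), the regression engine
# behind every cross-validated subset evaluation. Written as a lean kernel
# because the optimizer calls it tens of thousands of times per run;
# predictions agree with mixOmics::pls to machine precision (see tests).
#
# X is standardized (training statistics), y centered. Returns enough to
# predict on new data. ncomp is capped at the usable rank: if a deflated
# weight vector collapses, remaining components are dropped.
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  mx <- colMeans(X)
  E <- X - rep(mx, each = n)
  sx <- sqrt(colSums(E^2) / (n - 1))
  sx[sx == 0] <- 1
  E <- E / rep(sx, each = n)
  my <- mean(y)
  f <- y - my
  A <- min(ncomp, p, n - 1)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w * w))
    if (nw < 1e-10) break
    w <- w / nw
    tsc <- drop(E %*% w)
    tt <- sum(tsc * tsc)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(E, tsc)) / tt
    q_a <- sum(f * tsc) / tt
    E <- E - tcrossprod(tsc, p_a)
    f <- f - q_a * tsc
    W[, a] <- w
    P[, a] <- p_a
    q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) {
    coef <- numeric(p) # constant model: predict the training mean
  } else {
    Wa <- W[, seq_len(a_used), drop = FALSE]
    Pa <- P[, seq_len(a_used), drop = FALSE]
    coef <- drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a_used)]))
  }
  list(coef = coef, mx = mx, sx = sx, my = my, ncomp = a_used)
}

pls1_predict <- function(fit, Xnew) {
  drop(((Xnew - rep(fit$mx, each = nrow(Xnew))) /
          rep(fit$sx, each = nrow(Xnew))) %*% fit$coef) + fit$my
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# generator state afterwards. Keeps fold assignment a pure function of
# (n, folds, seed) even inside the stochastic optimizer.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Contiguous fold labels after one seeded shuffle of the rows.
fold_assignment <- function(n, folds, shuffle_seed) {
  if (folds > n) abort("`folds` cannot exceed the number of samples.")
  if (folds < 2) abort("`folds` must be at least 2.")
  perm <- with_local_seed(shuffle_seed, sample.int(n))
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds), rep(0L, folds - n %% folds))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(folds), sizes)
  fold
}

# Matrix-level k-fold CV used by the wrapper and the optimizer objective.
# Returns mean of per-fold RMSEs (the default aggregate), plus the pooled
# out-of-fold predictions for metric computation.
cv_pls <- function(X, y, folds = 10, ncomp = 2, shuffle_seed = 0,
                   aggregate = c("fold_mean", "pooled"), quiet = FALSE) {
  aggregate <- match.arg(aggregate)
  n <- nrow(X)
  fold <- fold_assignment(n, folds, shuffle_seed)
  fold_rmse <- numeric(folds)
  pred <- numeric(n)
  reduced <- FALSE
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- pls1_fit(X[!test, , drop = FALSE], y[!test], ncomp)
    if (fit$ncomp < ncomp) reduced <- TRUE
    pred[test] <- pls1_predict(fit, X[test, , drop = FALSE])
    fold_rmse[k] <- sqrt(mean((y[test] - pred[test])^2))
  }
  if (reduced && !quiet) {
    warn("PLS components reduced to the usable rank in at least one fold.")
  }
  list(
    rmse = if (aggregate == "fold_mean") mean(fold_rmse) else
      sqrt(mean((y - pred)^2)),
    fold_rmse = fold_rmse,
    pred = pred,
    fold = fold
  )
}

#' Cross-validated PLS regression error for a feature subset
#'
#' Scores a feature subset by k-fold cross-validated partial least squares
#' regression. Rows are shuffled once by `shuffle_seed` and split into
#' contiguous folds; per fold, a PLS model with `ncomp` latent components
#' is fitted on the training portion (features standardized on the
#' training rows only) and predictions are made on the held-out fold. The
#' score is the mean over folds of the per-fold root-mean-square error
#' \eqn{\sqrt{\frac{1}{n_k}\sum_i (y_i - \hat y_i)^2}}; `aggregate =
#' "pooled"` instead pools all out-of-fold residuals into one RMSE.
#'
#' If a fold's training matrix cannot support `ncomp` components the
#' count is reduced to the usable rank with a warning.
#'
#' @inheritParams mrmr_rank
#' @param features Character vector of feature columns to use
#'   (default: all feature columns in `data`).
#' @param folds Number of cross-validation folds (default 10).
#' @param ncomp Number of PLS latent components (default 2).
#' @param shuffle_seed Integer seed controlling the single row shuffle
#'   that defines the folds.
#' @param aggregate `"fold_mean"` (mean of per-fold RMSEs, the default)
#'   or `"pooled"` (RMSE of all out-of-fold residuals).
#'
#' @return A single non-negative number: the cross-validated RMSE.
#' @export
kfold_pls_rmse <- function(data, target, features = NULL, folds = 10,
                           ncomp = 2, shuffle_seed = 0,
                           aggregate = c("fold_mean", "pooled")) {
  parts <- split_target(data, {{ target }})
  X <- parts$X
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing) > 0) {
      abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")))
    }
    X <- X[, features, drop = FALSE]
  }
  if (ncol(X) == 0) abort("feature subset is empty.")
  cv_pls(X, parts$y, folds, ncomp, shuffle_seed, aggregate)$rmse
}
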