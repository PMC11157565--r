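new_ranking <- function(tbl, method) {
  structure(tbl, class = c("ss_ranking", class(tbl)), method = method)
}

split_target <- function(data, target) {
  target <- rlang::as_name(rlang::enquo(target))
  if (!target %in% names(data)) {
    abort(paste0("target column `", target, "` not found in `data`."))
  }
  y <- data[[target]]
  if (!is.numeric(y)) abort("target column must be numeric.")
  X <- dplyr::select(data, -dplyr::all_of(target), -dplyr::any_of("sample_id"))
  keep <- vapply(X, is.numeric, logical(1))
  X <- X[keep]
  if (ncol(X) < 1) abort("no numeric feature columns in `data`.")
  if (anyNA(y) || anyNA(as.matrix(X))) {
    abort("missing values present; drop or filter rows before ranking.")
  }
  list(X = as.matrix(X), y = y, target = target)
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy incremental mRMR ranking. The first feature maximizes the
#' mutual information \eqn{I(f, Y)} with the target; each subsequent
#' feature maximizes
#' \deqn{I(f, Y) - \frac{1}{|S|}\sum_{s \in S} I(f, s)}
#' over the not-yet-selected features, where \eqn{S} is the set already
#' selected. Mutual information is the histogram plug-in estimate of
#' [mi_estimate()], in nats. Ties are broken toward the lower original
#' column index, so the ranking is deterministic.
#'
#' `scheme = "relevance"` skips the redundancy charge and sorts once by
#' \eqn{I(f, Y)} alone — a one-shot relevance ranking useful for
#' comparison with the incremental criterion.
#'
#' @param data Data frame holding numeric feature columns and the target
#'   column. A `sample_id` column, if present, is ignored.
#' @param target Unquoted name of the target column.
#' @param max_rank Return only the first `max_rank` positions
#'   (default: all features).
#' @param bins Mutual-information bin setting, passed to [discretize()].
#' @param scheme `"incremental"` (the mRMR criterion) or `"relevance"`
#'   (relevance-only, no redundancy term).
#'
#' @return A tibble of class `ss_ranking` with columns `rank`, `feature`,
#'   `index` (original column position among the features), `score` (the
#'   criterion value at the step the feature was selected) and
#'   `relevance` (\eqn{I(f, Y)}).
#' @seealso [correlation_rank()] for the Pearson/Spearman baselines.
#' @export
mrmr_rank <- function(data, target, max_rank = Inf, bins = "auto",
                      scheme = c("incremental", "relevance")) {
  scheme <- match.arg(scheme)
  parts <- split_target(data, {{ target }})
  X <- parts$X
  y <- parts$y
  m <- ncol(X)
  n <- nrow(X)
  if (var(y) == 0) abort("target is constant; ranking is undefined.")

  dy <- discretize(y, bins)
  codes <- matrix(0L, n, m)
  levels <- integer(m)
  for (j in seq_len(m)) {
    d <- discretize(X[, j], bins)
    codes[, j] <- d$codes
    levels[j] <- d$n_levels
  }
  relevance <- vapply(seq_len(m), function(j) {
    mi_from_codes(codes[, j], levels[j], dy$codes, dy$n_levels, n)
  }, numeric(1))
  if (all(levels == 1L)) abort("no informative features: all features constant.")

  k <- min(m, max_rank)
  if (scheme == "relevance") {
    ord <- order(-relevance, seq_len(m))[seq_len(k)]
    scores <- relevance[ord]
  } else {
    ord <- integer(k)
    scores <- numeric(k)
    remaining <- rep(TRUE, m)
    red_sum <- numeric(m) # cumulative sum of MI(f, s) over selected s
    for (step in seq_len(k)) {
      crit <- relevance
      if (step > 1) crit <- crit - red_sum / (step - 1)
      crit[!remaining] <- -Inf
      pick <- which.max(crit) # which.max takes the first maximum: lowest index
      ord[step] <- pick
      scores[step] <- crit[pick]
      remaining[pick] <- FALSE
      if (step < k) {
        idx <- which(remaining)
        red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
          mi_from_codes(codes[, j], levels[j], codes[, pick], levels[pick], n)
        }, numeric(1))
      }
    }
  }

  new_ranking(
    tibble::tibble(
      rank = seq_len(k),
      feature = colnames(X)[ord],
      index = ord,
      score = scores,
      relevance = relevance[ord]
    ),
    method = if (scheme == "incremental") "mrmr" else "relevance"
  )
}

#' Rank features by absolute correlation with the target
#'
#' Baseline filter rankings: features sorted by descending absolute
#' Pearson or Spearman correlation with the target. A constant feature
#' gets correlation 0 (ranked last) with a warning.
#'
#' @inheritParams mrmr_rank
#' @param method `"pearson"` or `"spearman"`.
#'
#' @return A tibble of class `ss_ranking`; `score` and `relevance` both
#'   carry the absolute correlation.
#' @export
correlation_rank <- function(data, target, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  parts <- split_target(data, {{ target }})
  X <- parts$X
  y <- parts$y
  if (var(y) == 0) abort("target is constant; ranking is undefined.")
  sds <- apply(X, 2, sd)
  r <- numeric(ncol(X))
  ok <- sds > 0
  if (any(!ok)) {
    warn(paste0(sum(!ok), " constant feature(s) assigned correlation 0."))
  }
  if (any(ok)) r[ok] <- abs(drop(cor(X[, ok, drop = FALSE], y, method = method)))
  ord <- order(-r, seq_along(r))
  new_ranking(
    tibble::tibble(
      rank = seq_along(ord),
      feature = colnames(X)[ord],
      index = ord,
      score = r[ord],
      relevance = r[ord]
    ),
    method = method
  )
}
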