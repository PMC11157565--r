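#' Adaptive candidate-subset selection by sequential forward search
#'
#' Walks down a feature ranking in prefix steps, scoring each prefix by
#' k-fold cross-validated PLS regression, and returns the prefix with the
#' lowest RMSE as the candidate subset for the swarm stage. Prefix sizes
#' are `step, 2 step, ...` up to the full ranking (a final partial prefix
#' is included), so the full feature set is always among the evaluated
#' prefixes and the candidate's RMSE can never exceed the full-set RMSE
#' under the same folds. Ties go to the smaller prefix.
#'
#' @inheritParams kfold_pls_rmse
#' @param ranking An `ss_ranking` from [mrmr_rank()] or
#'   [correlation_rank()] (or any tibble with `feature` in rank order).
#' @param step Number of features added per prefix. A value below 1 is a
#'   fraction of the number of ranked features, resolved as
#'   `max(1, round(step * m))`; the default 0.01 adds 1% of the features
#'   at a time.
#'
#' @return An object of class `ss_candidate`: a list with `features`
#'   (character, the chosen prefix), `rmse` (its CV RMSE), `trace`
#'   (tibble of every evaluated `(size, rmse)` pair), and the CV settings
#'   used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
sfs_select <- function(data, target, ranking, step = 0.01, folds = 10,
                       ncomp = 2, shuffle_seed = 0,
                       aggregate = c("fold_mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!is.data.frame(ranking) || !"feature" %in% names(ranking)) {
    abort("`ranking` must be a data frame with a `feature` column.")
  }
  if (nrow(ranking) == 0) abort("`ranking` is empty.")
  parts <- split_target(data, {{ target }})
  X <- parts$X
  y <- parts$y
  feats <- ranking$feature
  missing <- setdiff(feats, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("ranking names feature(s) absent from `data`: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  m <- length(feats)
  if (step < 1) step <- max(1, round(step * m))
  step <- as.integer(step)
  sizes <- if (step >= m) m else unique(c(seq.int(step, m, by = step), m))

  rmse <- vapply(sizes, function(s) {
    cv_pls(X[, feats[seq_len(s)], drop = FALSE], y, folds, ncomp,
           shuffle_seed, aggregate, quiet = TRUE)$rmse
  }, numeric(1))

  best <- which.min(rmse) # first minimum: smaller prefix wins ties
  structure(
    list(
      features = feats[seq_len(sizes[best])],
      indices = ranking$index[seq_len(sizes[best])] %||% seq_len(sizes[best]),
      rmse = rmse[best],
      trace = tibble::tibble(size = sizes, rmse = rmse),
      step = step,
      folds = folds,
      ncomp = ncomp,
      shuffle_seed = shuffle_seed,
      aggregate = aggregate,
      target = parts$target
    ),
    class = "ss_candidate"
  )
}

#' @export
print.ss_candidate <- function(x, ...) {
  cat("Candidate feature subset (sequential forward search)\n")
  cat("  prefixes evaluated:", nrow(x$trace), " (step ", x$step, ")\n", sep = "")
  cat("  chosen size:", length(x$features),
      "  CV RMSE:", format(x$rmse, digits = 5), "\n")
  invisible(x)
}
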