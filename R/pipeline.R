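#' Regression evaluation metrics
#'
#' Root-mean-square error, coefficient of determination and mean absolute
#' error of predictions against observations:
#' \deqn{RMSE = \sqrt{\tfrac1n\sum (y - \hat y)^2},\quad
#'       R^2 = 1 - SS_{res}/SS_{tot},\quad
#'       MAE = \tfrac1n\sum |y - \hat y|.}
#'
#' @param y_true Observed values (nonconstant, length at least 2).
#' @param y_pred Predicted values, same length.
#' @return A one-row tibble with columns `rmse`, `r2`, `mae`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 5))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("lengths differ.")
  if (length(y_true) < 2) abort("need at least 2 observations.")
  if (var(y_true) == 0) abort("`y_true` is constant: R-squared is undefined.")
  res <- y_true - y_pred
  tibble::tibble(
    rmse = sqrt(mean(res^2)),
    r2 = 1 - sum(res^2) / sum((y_true - mean(y_true))^2),
    mae = mean(abs(res))
  )
}

#' Two-stage swarm feature selection (filter + wrapper, then Pareto swarm)
#'
#' Runs the full pipeline on a wide regression table:
#' \enumerate{
#'   \item \strong{Filter}: rank all features by mRMR mutual information
#'     ([mrmr_rank()]) or an absolute-correlation baseline
#'     ([correlation_rank()]).
#'   \item \strong{Wrapper}: walk ranked prefixes with sequential forward
#'     search scored by cross-validated PLS and keep the prefix with
#'     minimum RMSE as the candidate set ([sfs_select()]).
#'   \item \strong{Swarm}: search subsets of the candidate set with the
#'     multi-objective particle swarm ([cmopso()]), returning a Pareto
#'     front trading subset size against CV RMSE.
#' }
#' All randomness flows from `seed`: it fixes the CV fold shuffle and the
#' swarm's draws, so identical calls give identical results. Front
#' members are reported in original feature names, with out-of-fold
#' prediction metrics (RMSE, R-squared, MAE) computed on the same folds.
#'
#' If the candidate set collapses to a single feature the swarm stage is
#' skipped with a warning and the front is that single subset.
#'
#' @inheritParams cmopso
#' @param filter `"mrmr"`, `"pearson"` or `"spearman"`.
#' @param sfs_step Prefix step for the forward search; values below 1 are
#'   a fraction of the feature count (default 0.01).
#' @param bins Mutual-information bin setting (mRMR filter only).
#' @param seed Integer seed for the entire run (default 1).
#'
#' @return An object of class `mcmopso_result`: a list with `ranking`
#'   (the Stage-1 ranking), `candidate` (the `ss_candidate`), `front`
#'   (tibble: `n_features`, `rmse`, `r2`, `mae`, `features` list-column
#'   in original names), `history`, and `config`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' sim <- synth_hdss(n_samples = 40, n_relevant = 3, n_redundant = 2,
#'                   n_noise = 20, seed = 1)
#' fit <- mcmopso(sim$data, y, iterations = 10, pop_size = 10, seed = 1)
#' glance(fit)
#' @export
mcmopso <- function(data, target, filter = c("mrmr", "pearson", "spearman"),
                    sfs_step = 0.01, bins = "auto",
                    optimizer = c("cmopso", "mopso"),
                    iterations = 300, pop_size = 100, archive_size = 50,
                    mesh = 20, threshold = 0.6, folds = 10, ncomp = 2,
                    aggregate = c("fold_mean", "pooled"),
                    w_max = 0.9, w_min = 0.4,
                    c1i = 1.25, c1f = 2.75, c2i = 2.25, c2f = 0.5,
                    literal_c2 = FALSE, v_max = 0.5, seed = 1) {
  filter <- match.arg(filter)
  optimizer <- match.arg(optimizer)
  aggregate <- match.arg(aggregate)
  target_q <- rlang::enquo(target)

  ranking <- if (filter == "mrmr") {
    mrmr_rank(data, !!target_q, bins = bins)
  } else {
    correlation_rank(data, !!target_q, method = filter)
  }
  candidate <- sfs_select(data, !!target_q, ranking, step = sfs_step,
                          folds = folds, ncomp = ncomp, shuffle_seed = seed,
                          aggregate = aggregate)

  parts <- split_target(data, !!target_q)
  if (length(candidate$features) == 1) {
    warn("candidate set has a single feature; swarm stage skipped.")
    rmse <- cv_pls(parts$X[, candidate$features, drop = FALSE], parts$y,
                   folds, 1, seed, aggregate, quiet = TRUE)$rmse
    swarm <- list(
      front = tibble::tibble(
        n_features = 1L, rmse = rmse,
        features = list(candidate$features), position = list(1)
      ),
      history = tibble::tibble(iteration = integer(0),
                               archive_size = integer(0),
                               best_rmse = numeric(0)),
      n_evaluations = 1L,
      config = list(optimizer = optimizer)
    )
  } else {
    swarm <- cmopso(data, !!target_q, features = candidate$features,
                    optimizer = optimizer, iterations = iterations,
                    pop_size = pop_size, archive_size = archive_size,
                    mesh = mesh, threshold = threshold, folds = folds,
                    ncomp = ncomp, shuffle_seed = seed,
                    aggregate = aggregate, w_max = w_max, w_min = w_min,
                    c1i = c1i, c1f = c1f, c2i = c2i, c2f = c2f,
                    literal_c2 = literal_c2, v_max = v_max, seed = seed)
  }

  # per-member out-of-fold metrics on the same folds
  metrics <- purrr::map_dfr(swarm$front$features, function(fs) {
    cv <- cv_pls(parts$X[, fs, drop = FALSE], parts$y, folds,
                 min(ncomp, length(fs)), seed, aggregate, quiet = TRUE)
    compute_metrics(parts$y, cv$pred)[, c("r2", "mae")]
  })
  front <- dplyr::bind_cols(
    swarm$front[, c("n_features", "rmse")], metrics,
    swarm$front[, "features", drop = FALSE]
  )

  structure(
    list(
      ranking = ranking,
      candidate = candidate,
      front = front,
      history = swarm$history,
      n_evaluations = swarm$n_evaluations,
      target = parts$target,
      n_features_total = ncol(parts$X),
      config = list(
        filter = filter, sfs_step = sfs_step, bins = bins,
        optimizer = optimizer, iterations = iterations,
        pop_size = pop_size, archive_size = archive_size, mesh = mesh,
        threshold = threshold, folds = folds, ncomp = ncomp,
        aggregate = aggregate, w_max = w_max, w_min = w_min,
        c1i = c1i, c1f = c1f, c2i = c2i, c2f = c2f,
        literal_c2 = literal_c2, v_max = v_max, seed = seed
      )
    ),
    class = "mcmopso_result"
  )
}

#' Repeat the pipeline across seeds and aggregate the fronts
#'
#' Benchmark-style aggregation: the pipeline is run `repeats` times with
#' seeds `seed, seed + 1, ...`; within each run the best (minimum) RMSE
#' per subset size is taken, then the mean and standard deviation across
#' runs are reported per size (sizes present in every run only appear
#' with their available runs counted).
#'
#' @inheritParams mcmopso
#' @param repeats Number of runs (default 10).
#' @return A list of class `mcmopso_repeat` with `summary` (tibble:
#'   `n_features`, `mean_rmse`, `sd_rmse`, `n_runs`) and `runs` (the
#'   individual `mcmopso_result` objects).
#' @export
mcmopso_repeat <- function(data, target, repeats = 10, seed = 1, ...) {
  target_q <- rlang::enquo(target)
  runs <- lapply(seq_len(repeats), function(r) {
    mcmopso(data, !!target_q, seed = seed + r - 1, ...)
  })
  per_run <- purrr::imap_dfr(runs, function(run, r) {
    run$front |>
      dplyr::group_by(.data$n_features) |>
      dplyr::summarise(rmse = min(.data$rmse), .groups = "drop") |>
      dplyr::mutate(run = r)
  })
  summary <- per_run |>
    dplyr::group_by(.data$n_features) |>
    dplyr::summarise(
      mean_rmse = mean(.data$rmse),
      sd_rmse = ifelse(dplyr::n() > 1, sd(.data$rmse), NA_real_),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
  structure(list(summary = summary, runs = runs), class = "mcmopso_repeat")
}

#' @export
print.mcmopso_result <- function(x, ...) {
  cat("Two-stage swarm feature selection (", x$config$filter, " + ",
      x$config$optimizer, ")\n", sep = "")
  cat("  features:", x$n_features_total,
      " -> candidate:", length(x$candidate$features),
      " -> front of", nrow(x$front), "subset(s)\n")
  print(dplyr::select(x$front, "n_features", "rmse", "r2", "mae"))
  invisible(x)
}

#' @export
print.mcmopso_repeat <- function(x, ...) {
  cat("Aggregated Pareto fronts over", length(x$runs), "runs\n")
  print(x$summary)
  invisible(x)
}
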