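#' @rdname sfs_select
#' @param x An `ss_candidate`.
#' @param ... Unused.
#' @export
tidy.ss_candidate <- function(x, ...) x$trace

#' @rdname sfs_select
#' @export
glance.ss_candidate <- function(x, ...) {
  tibble::tibble(
    n_candidate = length(x$features),
    rmse = x$rmse,
    n_evaluated = nrow(x$trace),
    step = x$step,
    folds = x$folds,
    ncomp = x$ncomp
  )
}

#' @rdname cmopso
#' @param x A `cmopso_result`.
#' @param ... Unused.
#' @export
tidy.cmopso_result <- function(x, ...) x$front

#' @rdname cmopso
#' @export
glance.cmopso_result <- function(x, ...) {
  tibble::tibble(
    front_size = nrow(x$front),
    best_rmse = min(x$front$rmse),
    smallest_subset = min(x$front$n_features),
    n_candidates = length(x$candidate_features),
    n_evaluations = x$n_evaluations,
    iterations = x$config$iterations,
    optimizer = x$config$optimizer
  )
}

#' @rdname mcmopso
#' @param x An `mcmopso_result`.
#' @param ... Unused.
#' @export
tidy.mcmopso_result <- function(x, ...) x$front

#' @rdname mcmopso
#' @export
glance.mcmopso_result <- function(x, ...) {
  best <- which.min(x$front$rmse)
  tibble::tibble(
    n_features_total = x$n_features_total,
    n_candidate = length(x$candidate$features),
    candidate_rmse = x$candidate$rmse,
    front_size = nrow(x$front),
    best_rmse = x$front$rmse[best],
    best_r2 = x$front$r2[best],
    best_n_features = x$front$n_features[best],
    filter = x$config$filter,
    optimizer = x$config$optimizer,
    seed = x$config$seed
  )
}

#' Plot the forward-search RMSE trace
#'
#' @param object An `ss_candidate`.
#' @param ... Unused.
#' @return A ggplot: CV RMSE against prefix size, with the chosen
#'   candidate size marked.
#' @export
autoplot.ss_candidate <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$size, y = .data$rmse)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = length(object$features),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Ranked prefix size", y = "CV RMSE",
                  title = "Sequential forward search",
                  subtitle = paste0("candidate = ", length(object$features),
                                    " features, RMSE = ",
                                    signif(object$rmse, 4))) +
    ggplot2::theme_minimal()
}

plot_front <- function(front, subtitle = NULL) {
  ggplot2::ggplot(front, ggplot2::aes(x = .data$n_features, y = .data$rmse)) +
    ggplot2::geom_step(direction = "hv", colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::labs(x = "Subset size (f1)", y = "CV RMSE (f2)",
                  title = "Pareto front", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' Plot a Pareto front
#'
#' @param object A `cmopso_result`.
#' @param ... Unused.
#' @return A ggplot of the archive in objective space (subset size
#'   against CV RMSE).
#' @export
autoplot.cmopso_result <- function(object, ...) {
  plot_front(object$front,
             subtitle = paste0(object$config$optimizer, ", ",
                               object$config$iterations, " iterations"))
}

#' @rdname autoplot.cmopso_result
#' @export
autoplot.mcmopso_result <- function(object, ...) {
  plot_front(object$front,
             subtitle = paste0(object$config$filter, " + ",
                               object$config$optimizer, "; candidate = ",
                               length(object$candidate$features), " of ",
                               object$n_features_total, " features"))
}
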