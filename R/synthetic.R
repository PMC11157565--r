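#' Simulate a high-dimensional small-sample regression dataset
#'
#' Generates a wide feature table with known ground truth, the regime
#' feature selectors face in omics regression: a handful of truly
#' relevant features, noisy redundant copies of them, and a large block
#' of irrelevant noise. Relevant features are i.i.d. standard normal;
#' each redundant feature is a relevant parent (assigned round-robin)
#' plus `N(0, redundancy_sd^2)` jitter; noise features are i.i.d.
#' standard normal, independent of the target. The target is the linear
#' model
#' \deqn{y = \sum_j \beta_j x_{rel,j} + \varepsilon,\qquad
#'       \varepsilon \sim N(0, noise\_sd^2).}
#'
#' @param n_samples Number of rows (samples).
#' @param n_relevant Number of truly relevant features.
#' @param n_redundant Number of noisy copies of relevant features
#'   (requires `n_relevant > 0`).
#' @param n_noise Number of irrelevant features.
#' @param effect_sizes Coefficients \eqn{\beta} of the relevant features
#'   (length `n_relevant`; default all 1).
#' @param noise_sd Standard deviation of the target noise (default 0.5).
#' @param redundancy_sd Standard deviation of the copy jitter
#'   (default 0.3; the parent-copy correlation is
#'   \eqn{1/\sqrt{1 + \sigma^2}}).
#' @param seed Integer seed; the dataset is fully determined by it.
#'
#' @return A list of class `hdss_sim`:
#'   \describe{
#'     \item{data}{tibble with `sample_id`, the feature columns
#'       (`rel_*`, `red_*`, `noise_*`) and the target column `y`.}
#'     \item{truth}{tibble with `feature`, `role`
#'       (relevant/redundant/noise) and `parent` (the copied relevant
#'       feature, `NA` otherwise).}
#'     \item{spec}{the generating parameters.}
#'   }
#' @examples
#' sim <- synth_hdss(n_samples = 30, n_relevant = 2, n_redundant = 2,
#'                   n_noise = 10, seed = 7)
#' dplyr::count(sim$truth, role)
#' @export
synth_hdss <- function(n_samples, n_relevant, n_redundant, n_noise,
                       effect_sizes = rep(1, n_relevant),
                       noise_sd = 0.5, redundancy_sd = 0.3, seed = 1) {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (n_relevant < 0 || n_redundant < 0 || n_noise < 0) {
    abort("feature counts must be non-negative.")
  }
  m <- n_relevant + n_redundant + n_noise
  if (m < 1) abort("at least one feature is required.")
  if (n_redundant > 0 && n_relevant == 0) {
    abort("redundant copies require at least one relevant feature.")
  }
  if (length(effect_sizes) != n_relevant) {
    abort("`effect_sizes` must have length `n_relevant`.")
  }
  if (noise_sd <= 0 || redundancy_sd <= 0) {
    abort("`noise_sd` and `redundancy_sd` must be positive.")
  }

  out <- with_local_seed(seed, {
    rel <- matrix(rnorm(n_samples * n_relevant), n_samples, n_relevant)
    parent <- if (n_redundant > 0) {
      rep(seq_len(n_relevant), length.out = n_redundant) # round-robin
    } else integer(0)
    red <- if (n_redundant > 0) {
      rel[, parent, drop = FALSE] +
        matrix(rnorm(n_samples * n_redundant, sd = redundancy_sd),
               n_samples, n_redundant)
    } else matrix(numeric(0), n_samples, 0)
    noise <- matrix(rnorm(n_samples * n_noise), n_samples, n_noise)
    y <- if (n_relevant > 0) drop(rel %*% effect_sizes) else numeric(n_samples)
    y <- y + rnorm(n_samples, sd = noise_sd)
    list(rel = rel, red = red, noise = noise, y = y, parent = parent)
  })

  rel_names <- if (n_relevant > 0) paste0("rel_", seq_len(n_relevant)) else character(0)
  red_names <- if (n_redundant > 0) paste0("red_", seq_len(n_redundant)) else character(0)
  noise_names <- if (n_noise > 0) paste0("noise_", seq_len(n_noise)) else character(0)

  X <- cbind(out$rel, out$red, out$noise)
  colnames(X) <- c(rel_names, red_names, noise_names)
  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples))),
    tibble::as_tibble(X),
    tibble::tibble(y = out$y)
  )
  truth <- tibble::tibble(
    feature = c(rel_names, red_names, noise_names),
    role = c(rep("relevant", n_relevant), rep("redundant", n_redundant),
             rep("noise", n_noise)),
    parent = c(rep(NA_character_, n_relevant),
               if (n_redundant > 0) rel_names[out$parent] else character(0),
               rep(NA_character_, n_noise))
  )
  structure(
    list(
      data = data,
      truth = truth,
      spec = list(
        n_samples = n_samples, n_relevant = n_relevant,
        n_redundant = n_redundant, n_noise = n_noise,
        effect_sizes = effect_sizes, noise_sd = noise_sd,
        redundancy_sd = redundancy_sd, seed = seed
      )
    ),
    class = "hdss_sim"
  )
}

#' Preset shapes at realistic metabolomics scales
#'
#' Named parameter sets reproducing the shape (sample and feature
#' counts) of the two metabolomics blocks the method was designed for: an
#' endogenous block of 54 samples by 10,283 features and an exogenous
#' block of 42 samples by 798 features, each with a small relevant core.
#'
#' @return A named list of argument lists for [synth_hdss()]; apply one
#'   with `do.call(synth_hdss, c(hdss_presets()[["exo-like"]], seed = 7))`.
#' @export
hdss_presets <- function() {
  list(
    `endo-like` = list(n_samples = 54, n_relevant = 8, n_redundant = 12,
                       n_noise = 10263),
    `exo-like` = list(n_samples = 42, n_relevant = 6, n_redundant = 8,
                      n_noise = 784)
  )
}

#' @export
print.hdss_sim <- function(x, ...) {
  cat("Synthetic HDSS regression dataset:",
      x$spec$n_samples, "samples x",
      x$spec$n_relevant + x$spec$n_redundant + x$spec$n_noise, "features",
      "(", x$spec$n_relevant, "relevant,", x$spec$n_redundant, "redundant,",
      x$spec$n_noise, "noise )\n")
  invisible(x)
}
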