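#' Discretize a numeric variable for histogram mutual-information estimation
#'
#' Integer-coded variables with at most `max_discrete` distinct values are
#' used as-is (one code per observed value); continuous variables are cut
#' into `bins` equal-width intervals over their observed range.
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins for continuous input, or a rule:
#'   `"auto"` (the default) uses \eqn{\max(2, \lceil n^{1/3}\rceil)} bins,
#'   `"sqrt"` uses \eqn{\lceil\sqrt n\rceil}. The cube-root rule is the
#'   default because the mutual-information estimator fills a
#'   `bins x bins` joint table: with \eqn{\sqrt n} bins per axis the joint
#'   table has about \eqn{n} cells (one observation each) and the plug-in
#'   estimate is dominated by small-sample bias and variance, while the
#'   cube-root rule keeps the joint cell count near \eqn{n^{2/3}}.
#' @param max_discrete Maximum number of distinct values for a vector to be
#'   treated as natively discrete (default 20).
#'
#' @return A list with integer `codes` in `1:n_levels`, `n_levels`, and
#'   `bin_edges` (empty for natively discrete input).
#' @export
discretize <- function(x, bins = "auto", max_discrete = 20L) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (anyNA(x)) abort("`x` must not contain missing values.")
  ux <- sort(unique(x))
  if (all(x == round(x)) && length(ux) <= max_discrete) {
    return(list(
      codes = match(x, ux),
      n_levels = length(ux),
      bin_edges = numeric(0)
    ))
  }
  if (identical(bins, "auto")) {
    bins <- max(2, ceiling(length(x)^(1 / 3)))
  } else if (identical(bins, "sqrt")) {
    bins <- ceiling(sqrt(length(x)))
  }
  bins <- max(1L, as.integer(bins))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(list(codes = rep(1L, length(x)), n_levels = 1L, bin_edges = rng))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  codes <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(codes = as.integer(codes), n_levels = bins, bin_edges = edges)
}

# Plug-in MI (nats) from two integer code vectors; the hot path shared by
# mi_estimate() and mrmr_rank().
mi_from_codes <- function(cx, lx, cy, ly, n) {
  joint <- tabulate((cx - 1L) * ly + cy, nbins = lx * ly)
  nz <- joint > 0L
  pj <- joint[nz] / n
  px <- tabulate(cx, nbins = lx) / n
  py <- tabulate(cy, nbins = ly) / n
  # marginal index of each nonzero joint cell
  ix <- ((which(nz) - 1L) %/% ly) + 1L
  iy <- ((which(nz) - 1L) %% ly) + 1L
  max(0, sum(pj * log(pj / (px[ix] * py[iy]))))
}

#' Plug-in mutual information between two variables
#'
#' Histogram (plug-in) estimate of the mutual information
#' \deqn{I(X;Y) = \sum_{x,y} \hat p(x,y) \ln \frac{\hat p(x,y)}{\hat p(x)\,\hat p(y)}}
#' in nats, over the nonzero joint cells. Continuous variables are
#' discretized into equal-width bins (see [discretize()]); integer-coded
#' variables with few levels are used as-is. A constant vector has zero
#' entropy on its side, so the estimate is 0.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @param bins Bin count for continuous variables, or a rule (`"auto"`,
#'   `"sqrt"`); see [discretize()].
#'
#' @return A single non-negative number (nats).
#' @examples
#' x <- rep(c(0, 1), 20)
#' mi_estimate(x, x) # = ln 2 for a balanced binary variable
#' @export
mi_estimate <- function(x, y, bins = "auto") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least 2 observations.")
  dx <- discretize(x, bins)
  dy <- discretize(y, bins)
  mi_from_codes(dx$codes, dx$n_levels, dy$codes, dy$n_levels, length(x))
}
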