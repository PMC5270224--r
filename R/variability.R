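#' Per-feature deviation statistics for one cell type
#'
#' For every feature computes the group mean, the unbiased variance
#' (denominator n - 1), the per-sample absolute deviations from the group
#' mean, and the MAD-from-mean (median of those absolute deviations). These
#' are the raw ingredients of both the moderated deviation test and the
#' mean-corrected variability score.
#'
#' @param values Numeric feature-by-sample matrix (log2 expression or
#'   M values) for the samples of one cell type.
#' @return List with `mean`, `var`, `mad` (named numeric vectors) and
#'   `absdev` (feature-by-sample matrix of absolute deviations).
#' @export
group_stats <- function(values) {
  values <- unclass(values)
  n <- ncol(values)
  if (n < 4)
    stop("group_stats requires at least 4 samples (variance too unstable)")
  mu <- rowMeans(values)
  centred <- values - mu
  v <- rowSums(centred ^ 2) / (n - 1)
  absdev <- abs(centred)
  mad <- apply(absdev, 1, stats::median)
  list(mean = mu, var = v, mad = mad, absdev = absdev)
}

#' Fit the mean-variance trend
#'
#' Fits a smooth positive expected-variance function f(mean) by robust LOWESS
#' of `log(var + eps)` on the mean, evaluated by linear interpolation on a
#' fixed grid and constant-extrapolated beyond the fitted mean range. The
#' returned function underlies the mean-corrected variability score
#' EV = var / f(mean).
#'
#' @param mu Per-feature means.
#' @param v Per-feature variances (same length).
#' @param span LOWESS span (fraction of points in each local fit).
#' @param iter Robustifying iterations.
#' @param eps Offset inside the log; also the positivity floor of f.
#' @param grid_n Number of interpolation grid points.
#' @return A function `f(mu)` returning expected variances, with attributes
#'   `grid` (data frame of grid mu / fitted variance) and `range` (fitted mu
#'   range).
#' @export
fit_mean_variance <- function(mu, v, span = 0.3, iter = 3,
                              eps = 1e-8, grid_n = 512) {
  if (length(mu) != length(v)) stop("'mu' and 'v' lengths differ")
  ok <- is.finite(mu) & is.finite(v)
  mu <- mu[ok]; v <- v[ok]
  if (length(unique(mu)) < 2)
    stop("need at least 2 distinct mean values to fit a trend")
  if (all(v == 0))
    stop("all variances are zero; no trend to fit")
  fit <- stats::lowess(mu, log(v + eps), f = span, iter = iter)
  grid_x <- seq(min(fit$x), max(fit$x), length.out = grid_n)
  grid_y <- stats::approx(fit$x, fit$y, xout = grid_x,
                          ties = mean, rule = 2)$y
  grid_f <- pmax(exp(grid_y), eps)
  f <- function(x) {
    stats::approx(grid_x, grid_f, xout = x, rule = 2)$y
  }
  attr(f, "grid") <- data.frame(mu = grid_x, expected_var = grid_f)
  attr(f, "range") <- range(grid_x)
  f
}

#' Mean-corrected variability score
#'
#' EV (expression) / MV (methylation): the ratio of the observed variance to
#' the variance expected at the feature's mean under the fitted trend,
#' removing the dependence of variability on the mean.
#'
#' @param v Per-feature variances.
#' @param f Expected-variance function from [fit_mean_variance()].
#' @param mu Per-feature means.
#' @return Numeric vector of variability scores (>= 0).
#' @export
compute_ev <- function(v, f, mu) {
  ev <- v / f(mu)
  names(ev) <- names(v)
  ev
}

#' Variability table for one matrix and cell type
#'
#' Convenience wrapper: [group_stats()], [fit_mean_variance()] and
#' [compute_ev()] for the samples of one cell type, returned as one row per
#' feature.
#'
#' @param values Feature-by-sample matrix for one cell type.
#' @param cell_type Label stored in the output.
#' @param ... Passed to [fit_mean_variance()].
#' @return List with `table` (data frame: feature_id, cell_type, mean, var,
#'   expected_var, ev, mad), `absdev` matrix and the trend function `f`.
#' @export
variability_table <- function(values, cell_type = "group", ...) {
  gs <- group_stats(values)
  f <- fit_mean_variance(gs$mean, gs$var, ...)
  ev <- compute_ev(gs$var, f, gs$mean)
  tab <- data.frame(
    feature_id = rownames(values),
    cell_type = cell_type,
    mean = gs$mean,
    var = gs$var,
    expected_var = f(gs$mean),
    ev = ev,
    mad = gs$mad,
    row.names = NULL
  )
  list(table = tab, absdev = gs$absdev, f = f)
}
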