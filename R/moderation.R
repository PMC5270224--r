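#' Estimate empirical-Bayes variance moderation parameters
#'
#' Fits the scaled inverse-chi-square prior of the moderated t framework by
#' the log-variance moment method: with
#' `e_g = log(s2_g) - digamma(df/2) + log(df/2)`, the prior degrees of
#' freedom d0 solve `trigamma(d0/2) = var(e) - trigamma(df/2)` (monotone
#' root finding on the trigamma function), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the observed
#' spread of `e` is at or below the sampling spread `trigamma(df/2)`, the
#' prior is degenerate: `d0 = Inf` and every posterior variance equals s0^2.
#'
#' @param s2 Per-feature sample variances (> 0 entries are used; zeros are
#'   dropped from the fit with a warning).
#' @param df Residual degrees of freedom of each s2 (single value).
#' @return List with `d0`, `s0_sq` and `df`.
#' @export
estimate_moderation <- function(s2, df) {
  if (length(df) != 1 || !is.finite(df) || df <= 0)
    stop("'df' must be a single positive number")
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("no positive variances: cannot estimate moderation parameters")
  if (sum(ok) < length(s2))
    warning(sprintf("%d zero/non-finite variances excluded from the fit",
                    length(s2) - sum(ok)))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- if (length(e) > 1) stats::var(e) else 0
  excess <- evar - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - excess,
                              lower = 1e-8, upper = 1e8,
                              tol = .Machine$double.eps ^ 0.5)$root
    d0 <- 2 * half_d0
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, df = df)
}

#' Posterior (moderated) variances
#'
#' Shrinks per-feature variances toward the prior:
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`. With `d0 = 0` this is the
#' unmoderated s2; with `d0 = Inf` it is s0^2 for every feature.
#'
#' @param s2 Per-feature sample variances.
#' @param params List with `d0`, `s0_sq`, `df` (see [estimate_moderation()]).
#' @return Numeric vector of posterior variances.
#' @export
moderate_var <- function(s2, params) {
  d0 <- params$d0
  if (is.infinite(d0)) return(rep(params$s0_sq, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * params$s0_sq + params$df * s2) / (d0 + params$df)
}
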