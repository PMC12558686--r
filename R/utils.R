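# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Solve the intercept of a logistic model for a marginal target
#'
#' Given realized linear-predictor offsets `eta`, finds `a` such that
#' `mean(plogis(a + eta)) == target`. Monotone in `a`, so uniroot is exact.
#' @noRd
calibrate_logit_intercept <- function(eta, target) {
  stopifnot(target > 0, target < 1)
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

#' Clip, then round to integer scores within a scale's range
#' @noRd
clip_score <- function(x, lo, hi) {
  pmin(hi, pmax(lo, round(x)))
}

#' Probability of the observed level of a binary variable
#' @noRd
prob_observed <- function(p1, obs) {
  ifelse(obs == 1L, p1, 1 - p1)
}

is_binary01 <- function(x) {
  v <- unique(x[!is.na(x)])
  length(v) <= 2 && all(v %in% c(0, 1))
}

#' Normal-scale interpolated empirical quantile of bootstrap replicates
#'
#' Rank `(B + 1) * alpha` with interpolation between adjacent order
#' statistics on the standard-normal quantile scale (the convention used
#' throughout the bootstrap literature for BCa endpoints).
#' @noRd
norm_interp_quantile <- function(t_sorted, alpha) {
  B <- length(t_sorted)
  vapply(alpha, function(a) {
    r <- (B + 1) * a
    if (r <= 1) return(t_sorted[1L])
    if (r >= B) return(t_sorted[B])
    lo <- floor(r)
    hi <- lo + 1
    # interpolate on the qnorm scale of the plotting positions
    g <- (stats::qnorm(a) - stats::qnorm(lo / (B + 1))) /
      (stats::qnorm(hi / (B + 1)) - stats::qnorm(lo / (B + 1)))
    (1 - g) * t_sorted[lo] + g * t_sorted[hi]
  }, numeric(1))
}
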