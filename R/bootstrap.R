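# Bias-corrected and accelerated (BCa) bootstrap over the full estimation
# pipeline, and E-value sensitivity statistics for unmeasured confounding.

#' BCa bootstrap confidence interval for a pipeline statistic
#'
#' Nonparametric bootstrap resampling subjects (rows) with replacement at
#' the original sample size. The statistic is re-evaluated from scratch
#' on every replicate — for weighted-pipeline statistics that means the
#' weight models are refitted inside each replicate, so the interval
#' reflects the full estimation uncertainty. The bias-correction z0 uses
#' the fraction of replicates below the point estimate (ties counted as
#' half below), the acceleration comes from jackknife skewness, and the
#' endpoints are BCa-adjusted order statistics with normal-scale
#' interpolation.
#'
#' @param data data.frame whose rows are the resampling units (subjects).
#' @param statistic `function(data, ...)` returning a single number.
#' @param B replicate count (default 5000 for release runs; smaller
#'   values are fine for testing, with wider Monte-Carlo error).
#' @param seed integer seed; resampling draws one `sample.int(n, n,
#'   replace = TRUE)` index vector per replicate, in order, so results
#'   are reproducible and independently re-derivable.
#' @param conf confidence level (default 0.95).
#' @param ... passed through to `statistic`.
#' @return An object of class `bca_bootstrap`: `t0`, `replicates`
#'   (failed fits excluded, count reported in `n_failed`), `ci`, `z0`,
#'   `acceleration`, `B`, `seed`.
#' @export
#' @examples
#' d <- data.frame(v = rexp(50))
#' bca_bootstrap(d, function(dd) mean(dd$v), B = 500, seed = 1)$ci
bca_bootstrap <- function(data, statistic, B = 5000L, seed = 1L, conf = 0.95, ...) {
  stopifnot(is.data.frame(data), is.function(statistic), B >= 1)
  n <- nrow(data)
  t0 <- statistic(data, ...)
  if (!is.numeric(t0) || length(t0) != 1) {
    stop("`statistic` must return a single number", call. = FALSE)
  }
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(statistic(data[idx, , drop = FALSE], ...),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(!is.finite(reps))
  if (n_failed > B / 2) {
    stop(sprintf("bootstrap failed: %d of %d replicates did not produce an estimate",
                 n_failed, B), call. = FALSE)
  }
  if (n_failed > 0.05 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed and were dropped",
                    n_failed, B), call. = FALSE)
  }
  t <- reps[is.finite(reps)]
  Beff <- length(t)

  if (stats::sd(t) == 0 && all(t == t0)) {
    # degenerate statistic: zero-width interval
    return(structure(
      list(t0 = t0, replicates = t, ci = c(t0, t0), z0 = 0, acceleration = 0,
           B = B, n_failed = n_failed, conf = conf, seed = as.integer(seed)),
      class = "bca_bootstrap"
    ))
  }

  prop_below <- (sum(t < t0) + 0.5 * sum(t == t0)) / Beff
  if (prop_below <= 0 || prop_below >= 1) {
    stop("all bootstrap replicates fall on one side of the point estimate; ",
         "BCa bias correction is undefined", call. = FALSE)
  }
  z0 <- stats::qnorm(prop_below)

  # acceleration from jackknife skewness of the statistic
  jk <- vapply(seq_len(n), function(i) {
    tryCatch(statistic(data[-i, , drop = FALSE], ...), error = function(e) NA_real_)
  }, numeric(1))
  jk <- jk[is.finite(jk)]
  d <- mean(jk) - jk
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)

  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zal <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  ci <- norm_interp_quantile(sort(t), adj)

  structure(
    list(t0 = t0, replicates = t, ci = ci, z0 = z0, acceleration = a,
         B = B, n_failed = n_failed, conf = conf, seed = as.integer(seed)),
    class = "bca_bootstrap"
  )
}

#' @export
print.bca_bootstrap <- function(x, ...) {
  cat(sprintf("BCa bootstrap (B = %d%s, seed %d)\n", x$B,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else "", x$seed))
  cat(sprintf("  estimate %.4f, %.0f%% CI [%.4f, %.4f]  (z0 %.4f, a %.4f)\n",
              x$t0, 100 * x$conf, x$ci[1], x$ci[2], x$z0, x$acceleration))
  invisible(x)
}

#' E-value for unmeasured confounding
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both the exposure and the
#' outcome to fully explain away an observed relative risk:
#' `RR* + sqrt(RR* (RR* - 1))` with `RR* = max(RR, 1/RR)`. Optionally
#' also computed for the confidence limit nearer the null (returning 1
#' if the interval crosses the null).
#'
#' @param rr observed relative risk (> 0; values below 1 are inverted).
#' @param ci_limit optional confidence limit nearer the null.
#' @return A list of class `evalue_result`: `rr`, `evalue`, and
#'   `evalue_ci` (NULL if no limit given).
#' @export
#' @examples
#' evalue(1.40)$evalue   # 2.15 at 2 d.p.
#' evalue(2)$evalue      # 2 + sqrt(2)
evalue <- function(rr, ci_limit = NULL) {
  if (!is.numeric(rr) || length(rr) != 1 || !is.finite(rr) || rr <= 0) {
    stop("`rr` must be a single positive number", call. = FALSE)
  }
  ev <- function(r) {
    rs <- max(r, 1 / r)
    rs + sqrt(rs * (rs - 1))
  }
  evc <- NULL
  if (!is.null(ci_limit) && is.finite(ci_limit)) {
    crosses <- (rr >= 1 && ci_limit <= 1) || (rr < 1 && ci_limit >= 1)
    evc <- if (crosses) 1 else ev(ci_limit)
  }
  structure(list(rr = rr, evalue = ev(rr), evalue_ci = evc),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("E-value %.2f for RR %.3f", x$evalue, x$rr))
  if (!is.null(x$evalue_ci)) cat(sprintf(" (CI limit: %.2f)", x$evalue_ci))
  cat("\n")
  invisible(x)
}
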