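# Weighted marginal structural outcome models: pooled modified Poisson
# (log link, robust sandwich variance) for the binary outcome, weighted
# least squares for the continuous score, and the excess-relative-risk
# decomposition of the total effect into direct and mediated parts.

#' Build one analysis row per subject for the outcome models
#'
#' Collapses the two exposure and mediator waves into cumulative
#' variables. Under the default mean coding `cum_x` is the mean of the
#' wave-1/2 indicators (0, 0.5 or 1), so the exponentiated exposure
#' coefficient is the always-vs-never contrast reported as a single
#' relative risk; sum coding (0, 1, 2) is available.
#'
#' @param cohort a coded cohort ([code_cohort()]).
#' @param weights optional `stabilized_weights` with `sw_trunc` or
#'   `sw_total`; merged by `id` into an `sw` column.
#' @param coding `"mean"` (default) or `"sum"` cumulative coding.
#' @param require_uncensored restrict to subjects observed through wave 3
#'   (default); set `FALSE` for best/worst-case dropout re-analyses.
#' @return A data.frame with `id`, `cum_x`, `cum_m`, `cum_tils` (mean
#'   TILS score, for continuous-mediator analyses), `y_bin`, `cesd_3`
#'   and, if weights were given, `sw`.
#' @export
build_analysis_rows <- function(cohort, weights = NULL,
                                coding = c("mean", "sum"),
                                require_uncensored = TRUE) {
  coding <- match.arg(coding)
  rows <- if (require_uncensored) cohort$c_3 == 1L else rep(TRUE, nrow(cohort))
  d <- cohort[rows, , drop = FALSE]
  miss <- is.na(d$x_1) | is.na(d$x_2) | is.na(d$m_1) | is.na(d$m_2)
  if (any(miss)) {
    stop(sprintf(paste0("subject id %s lacks an exposure or mediator value at some wave; ",
                        "impute or complete before building analysis rows"),
                 d$id[which(miss)[1]]), call. = FALSE)
  }
  div <- if (coding == "mean") 2 else 1
  out <- data.frame(
    id = d$id,
    cum_x = (d$x_1 + d$x_2) / div,
    cum_m = (d$m_1 + d$m_2) / div,
    cum_tils = (d$tils_1 + d$tils_2) / div,
    y_bin = d$y_bin,
    cesd_3 = d$cesd_3
  )
  if (!is.null(weights)) {
    wcol <- if ("sw_trunc" %in% names(weights)) "sw_trunc" else "sw_total"
    out$sw <- weights[[wcol]][match(out$id, weights$id)]
  }
  out
}

msm_result <- function(model, link, coef, robust_se, conf_level, n_effective,
                       weights_used) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  eff <- if (link == "log") exp(coef) else coef
  lo <- if (link == "log") exp(coef - z * robust_se) else coef - z * robust_se
  hi <- if (link == "log") exp(coef + z * robust_se) else coef + z * robust_se
  structure(
    list(model = model, link = link, coef = coef, robust_se = robust_se,
         effect = eff, ci_low = lo, ci_high = hi,
         conf_level = conf_level, n_effective = n_effective,
         weights_used = weights_used),
    class = "msm_result"
  )
}

fit_msm_glm <- function(rows, weights, include_mediator, family, outcome_col,
                        mediator_col = "cum_m", conf_level = 0.95,
                        vcov_type = "HC0") {
  if (is.null(weights)) weights <- rows$sw %||% rep(1, nrow(rows))
  if (length(weights) != nrow(rows)) {
    stop("weights must have one entry per analysis row", call. = FALSE)
  }
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("analysis weights must be positive and complete", call. = FALSE)
  }
  y <- rows[[outcome_col]]
  if (length(unique(y)) < 2L) {
    stop("degenerate fit: outcome is constant in the analysis rows", call. = FALSE)
  }
  d <- data.frame(y = y, cum_x = rows$cum_x, .w = weights)
  form <- y ~ cum_x
  if (include_mediator) {
    d$cum_m <- rows[[mediator_col]]
    form <- y ~ cum_x + cum_m
  }
  fit <- stats::glm(form, family = family, data = d, weights = .w,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) stop("outcome model did not converge", call. = FALSE)
  vc <- sandwich::vcovHC(fit, type = vcov_type)
  msm_result(
    model = if (include_mediator) "direct" else "total",
    link = family$link,
    coef = stats::coef(fit),
    robust_se = sqrt(diag(vc)),
    conf_level = conf_level,
    n_effective = nrow(d),
    weights_used = if ("sw" %in% names(rows)) "stabilized" else "supplied"
  )
}

#' Fit the weighted pooled Poisson (log-link) marginal structural model
#'
#' Modified Poisson regression of the binary wave-3 outcome on cumulative
#' exposure (total-effect model) or on cumulative exposure and cumulative
#' mediator (direct-effect model), weighted by the stabilized weights,
#' with heteroskedasticity-robust (sandwich) standard errors. With mean
#' cumulative coding, `exp(coef)` on `cum_x` is the always-vs-never
#' relative risk.
#'
#' @param rows analysis rows from [build_analysis_rows()].
#' @param weights numeric weights (defaults to the `sw` column of `rows`;
#'   unit weights if absent).
#' @param include_mediator add the cumulative mediator (direct-effect
#'   model)?
#' @param conf_level confidence level for Wald intervals (default 0.95).
#' @param vcov_type sandwich estimator type (default `"HC0"`, the basic
#'   heteroskedasticity-consistent form; one independent unit per
#'   subject, a single terminal outcome needs no clustering).
#' @return An object of class `msm_result` with coefficients, robust
#'   SEs, exponentiated effects and Wald confidence intervals.
#' @export
fit_msm_binary <- function(rows, weights = NULL, include_mediator = FALSE,
                           conf_level = 0.95, vcov_type = "HC0") {
  y <- rows$y_bin
  if (all(y == 0, na.rm = TRUE) || all(y == 1, na.rm = TRUE)) {
    stop("degenerate fit: all outcomes are identical", call. = FALSE)
  }
  # quasipoisson likelihood = poisson scores without the non-integer warning;
  # inference comes from the sandwich variance either way
  fit_msm_glm(rows, weights, include_mediator,
              family = stats::quasipoisson(link = "log"),
              outcome_col = "y_bin",
              conf_level = conf_level, vcov_type = vcov_type)
}

#' Fit the weighted linear (identity-link) marginal structural model
#'
#' Weighted least-squares regression of the continuous outcome score on
#' cumulative exposure (and cumulative mediator score, for the direct
#' model) with sandwich standard errors; effects are mean differences in
#' score units.
#'
#' @inheritParams fit_msm_binary
#' @param mediator_col mediator column for the direct model:
#'   `"cum_tils"` (mean TILS score, default) or `"cum_m"`.
#' @return An object of class `msm_result` (identity link).
#' @export
fit_msm_continuous <- function(rows, weights = NULL, include_mediator = FALSE,
                               mediator_col = "cum_tils",
                               conf_level = 0.95, vcov_type = "HC0") {
  fit_msm_glm(rows, weights, include_mediator,
              family = stats::gaussian(),
              outcome_col = "cesd_3", mediator_col = mediator_col,
              conf_level = conf_level, vcov_type = vcov_type)
}

#' @export
print.msm_result <- function(x, ...) {
  lab <- if (x$link == "log") "RR" else "MD"
  cat(sprintf("Marginal structural model (%s effect, %s link), n = %d\n",
              x$model, x$link, x$n_effective))
  for (nm in names(x$coef)) {
    cat(sprintf("  %-11s beta %8.4f (robust SE %.4f)  %s %6.3f [%.3f, %.3f]\n",
                nm, x$coef[nm], x$robust_se[nm], lab, x$effect[nm],
                x$ci_low[nm], x$ci_high[nm]))
  }
  invisible(x)
}

#' Decompose the total effect into direct and mediated components
#'
#' On the excess-relative-risk scale: the proportion transmitted
#' directly is `(RR_direct - 1) / (RR_total - 1)` and the proportion
#' mediated is `(RR_total - RR_direct) / (RR_total - 1)`; the two sum to
#' 100% by construction. The mediator's own relative risk is the
#' exponentiated cumulative-mediator coefficient of the direct model.
#' When the total relative risk does not exceed 1 the proportions are
#' undefined and reported as such (no NaN propagation).
#'
#' @param total an `msm_result` from the total-effect model (log link).
#' @param direct an `msm_result` from the direct-effect model.
#' @param evalues compute E-values for each relative risk (default TRUE)?
#' @return An object of class `mediation_summary`: `total_rr`,
#'   `direct_rr`, `mediator_rr`, `proportion_direct`,
#'   `proportion_mediated` (percent), per-effect E-values, and a
#'   `proportions_defined` flag.
#' @export
#' @examples
#' # a closed-form check: RRs 1.5 (total) and 1.4 (direct)
#' t0 <- structure(list(model = "total", link = "log",
#'   coef = c(`(Intercept)` = -2, cum_x = log(1.5)),
#'   robust_se = c(0.1, 0.1), effect = c(exp(-2), 1.5),
#'   ci_low = c(NA, NA), ci_high = c(NA, NA), conf_level = 0.95,
#'   n_effective = 100L, weights_used = "unit"), class = "msm_result")
#' d0 <- t0; d0$model <- "direct"
#' d0$coef <- c(`(Intercept)` = -2, cum_x = log(1.4), cum_m = log(1.2))
#' d0$robust_se <- c(0.1, 0.1, 0.1); d0$effect <- c(exp(-2), 1.4, 1.2)
#' d0$ci_low <- d0$ci_high <- rep(NA, 3)
#' decompose_effects(t0, d0)$proportion_mediated  # 20%
decompose_effects <- function(total, direct, evalues = TRUE) {
  stopifnot(inherits(total, "msm_result"), inherits(direct, "msm_result"))
  if (total$link != "log" || direct$link != "log") {
    stop("decomposition is defined on the relative-risk (log-link) scale; ",
         "convert mean differences with md_to_rr() first", call. = FALSE)
  }
  if (!"cum_m" %in% names(direct$coef)) {
    stop("`direct` must be the mediator-adjusted model", call. = FALSE)
  }
  mediation_summary_from_rr(
    total_rr = unname(total$effect["cum_x"]),
    direct_rr = unname(direct$effect["cum_x"]),
    mediator_rr = unname(direct$effect["cum_m"]),
    total_ci = unname(c(total$ci_low["cum_x"], total$ci_high["cum_x"])),
    direct_ci = unname(c(direct$ci_low["cum_x"], direct$ci_high["cum_x"])),
    mediator_ci = unname(c(direct$ci_low["cum_m"], direct$ci_high["cum_m"])),
    evalues = evalues
  )
}

# shared constructor: excess-relative-risk decomposition from bare RRs
# (used for Rubin-pooled and mean-difference-converted effects too)
mediation_summary_from_rr <- function(total_rr, direct_rr, mediator_rr,
                                      total_ci = c(NA_real_, NA_real_),
                                      direct_ci = c(NA_real_, NA_real_),
                                      mediator_ci = c(NA_real_, NA_real_),
                                      evalues = TRUE) {
  defined <- is.finite(total_rr) && total_rr > 1
  if (defined) {
    p_dir <- (direct_rr - 1) / (total_rr - 1) * 100
    p_med <- (total_rr - direct_rr) / (total_rr - 1) * 100
  } else {
    p_dir <- NA_real_
    p_med <- NA_real_
  }
  ev <- NULL
  if (evalues) {
    near_null <- function(rr, ci) if (is.finite(rr) && rr < 1) ci[2] else ci[1]
    ev <- list(total = evalue(total_rr, ci_limit = near_null(total_rr, total_ci)),
               direct = evalue(direct_rr, ci_limit = near_null(direct_rr, direct_ci)),
               mediator = evalue(mediator_rr, ci_limit = near_null(mediator_rr, mediator_ci)))
  }
  structure(
    list(total_rr = total_rr, direct_rr = direct_rr, mediator_rr = mediator_rr,
         proportion_direct = p_dir, proportion_mediated = p_med,
         proportions_defined = defined, evalues = ev,
         ci = list(total = total_ci, direct = direct_ci, mediator = mediator_ci)),
    class = "mediation_summary"
  )
}

#' @export
print.mediation_summary <- function(x, ...) {
  cat("Mediation decomposition (excess relative risk scale)\n")
  cat(sprintf("  total RR %.3f, direct RR %.3f, mediator RR %.3f\n",
              x$total_rr, x$direct_rr, x$mediator_rr))
  if (x$proportions_defined) {
    cat(sprintf("  proportion direct %.2f%%, proportion mediated %.2f%%\n",
                x$proportion_direct, x$proportion_mediated))
  } else {
    cat("  proportions undefined (total RR does not exceed 1)\n")
  }
  if (!is.null(x$evalues)) {
    cat(sprintf("  E-values: total %.2f, direct %.2f, mediator %.2f\n",
                x$evalues$total$evalue, x$evalues$direct$evalue,
                x$evalues$mediator$evalue))
  }
  invisible(x)
}

#' Convert a mean difference to an approximate relative risk
#'
#' Standard approximate conversion from a standardized mean difference
#' to a relative risk: `RR = exp(scaling * mean_diff / reference_sd)`
#' with the conventional scaling 0.91. Used to put continuous-outcome
#' sensitivity analyses on the relative-risk scale for E-values and
#' decomposition.
#'
#' @param mean_diff mean difference in outcome-score units.
#' @param reference_sd reference standard deviation of the outcome score
#'   (the analysis sample's SD among the unexposed is a natural choice).
#' @param scaling conversion constant; default 0.91.
#' @return The approximate relative risk.
#' @export
#' @examples
#' md_to_rr(0, 5)            # 1
#' md_to_rr(5, 5)            # exp(0.91) = 2.484
md_to_rr <- function(mean_diff, reference_sd, scaling = 0.91) {
  if (!is.numeric(reference_sd) || any(reference_sd <= 0)) {
    stop("`reference_sd` must be positive", call. = FALSE)
  }
  exp(scaling * mean_diff / reference_sd)
}
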