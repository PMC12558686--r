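# Stabilized inverse-probability weighting engine: numerator/denominator
# probability models for exposure, mediator and censoring at each wave,
# weight components, their cumulative product, truncation and diagnostics.

L0_COLS <- c("female", "ethnicity", "low_education", "housing")
lt_cols <- function(wave) {
  paste(c("age", "mobility", "cerebrovascular", "coronary", "diabetes",
          "cancer", "support"), wave, sep = "_")
}

#' Specification of one stabilized-weight model pair
#'
#' A numerator model conditions the probability of the current exposure,
#' mediator or censoring state on treatment/mediator history only; the
#' denominator model adds the time-invariant and current time-varying
#' confounders. The component weight is the ratio of the two predicted
#' probabilities of the observed state.
#'
#' @param target `"exposure"`, `"mediator"` or `"censoring"`.
#' @param wave wave of the modeled state (exposure/mediator: 1 or 2;
#'   censoring: 2 or 3, the wave the subject is observed *into*).
#' @param response name of the 0/1 response column.
#' @param numerator character vector of history covariate columns (may
#'   be empty: intercept-only numerator).
#' @param denominator covariates of the denominator model; must contain
#'   every numerator covariate.
#' @param at_risk name of a 0/1 column restricting the fitting sample
#'   (`NULL` = everyone). Censoring models at wave t are fitted among
#'   subjects still observed at wave t-1.
#' @return An object of class `weight_model_spec`.
#' @export
weight_model_spec <- function(target = c("exposure", "mediator", "censoring"),
                              wave, response, numerator, denominator,
                              at_risk = NULL) {
  target <- match.arg(target)
  if (!all(numerator %in% denominator)) {
    stop("numerator covariates must be a subset of denominator covariates", call. = FALSE)
  }
  structure(
    list(target = target, wave = as.integer(wave), response = response,
         numerator = numerator, denominator = denominator, at_risk = at_risk,
         label = sprintf("%s (wave %d)", target, wave)),
    class = "weight_model_spec"
  )
}

#' Default weight-model specifications for a coded three-wave cohort
#'
#' Six model pairs: exposure and mediator at waves 1 and 2, censoring
#' into waves 2 and 3. Numerators condition only on history terms that
#' also appear in the weighted outcome models — exposure history for the
#' exposure and censoring weights, exposure plus mediator history for
#' the mediator weights. (A numerator term absent from the outcome model
#' would leave that dependence in the pseudo-population and break the
#' marginalization the MSM performs; this is why prior mediator values
#' sit in the exposure/censoring *denominators*, where they are
#' confounders, but not in their numerators.) Wave-1 numerators condition
#' on nothing beyond the within-wave exposure (there is no wave-0
#' history); denominators add the baseline covariates, the mediator
#' history, and the current wave's time-varying covariates.
#'
#' @return A list of six [weight_model_spec()] objects.
#' @export
default_weight_specs <- function() {
  list(
    x1 = weight_model_spec("exposure", 1L, "x_1",
                           numerator = character(0),
                           denominator = c(L0_COLS, lt_cols(1))),
    x2 = weight_model_spec("exposure", 2L, "x_2",
                           numerator = "x_1",
                           denominator = c("x_1", "m_1", L0_COLS, lt_cols(2)),
                           at_risk = "c_2"),
    m1 = weight_model_spec("mediator", 1L, "m_1",
                           numerator = "x_1",
                           denominator = c("x_1", L0_COLS, lt_cols(1))),
    m2 = weight_model_spec("mediator", 2L, "m_2",
                           numerator = c("x_2", "x_1", "m_1"),
                           denominator = c("x_2", "x_1", "m_1", L0_COLS, lt_cols(2)),
                           at_risk = "c_2"),
    c2 = weight_model_spec("censoring", 2L, "c_2",
                           numerator = "x_1",
                           denominator = c("x_1", "m_1", L0_COLS, lt_cols(1))),
    c3 = weight_model_spec("censoring", 3L, "c_3",
                           numerator = c("x_2", "x_1"),
                           denominator = c("x_2", "x_1", "m_1", "m_2", L0_COLS, lt_cols(2)),
                           at_risk = "c_2")
  )
}

# Logistic fit on a covariate-column design, via glm.fit for speed inside
# replicate loops. Constant columns are dropped (bootstrap resamples can
# lose a factor level); aliased coefficients predict as zero, matching glm.
fit_logit <- function(data, response, covs, label) {
  y <- data[[response]]
  if (length(y) < 2L) {
    stop(sprintf("weight model %s: at-risk set has fewer than 2 subjects", label),
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop(sprintf("weight model %s: response is constant in the at-risk set", label),
         call. = FALSE)
  }
  if (length(covs) == 0L) {
    X <- matrix(1, nrow = length(y), ncol = 1L,
                dimnames = list(NULL, "(Intercept)"))
  } else {
    df <- data[covs]
    df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
    X <- stats::model.matrix(~ ., data = df)
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) > 0))
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged) {
    stop(sprintf("weight model %s did not converge", label), call. = FALSE)
  }
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    stop(sprintf("weight model %s: fitted probabilities of 0 or 1 (possible separation)",
                 label), call. = FALSE)
  }
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  list(coef = beta, fitted = as.numeric(stats::plogis(X %*% beta)))
}

#' Fit the numerator and denominator weight models
#'
#' Fits one logistic numerator/denominator model pair per specification,
#' each restricted to the subjects at risk at that wave and to rows with
#' complete covariates (impute first if item missingness remains).
#'
#' @param cohort a coded cohort ([code_cohort()]).
#' @param specs list of [weight_model_spec()]; default
#'   [default_weight_specs()].
#' @return An object of class `weight_model_fits`: per spec, the at-risk
#'   subject ids, observed responses, and predicted probabilities
#'   `p_num`, `p_den` of the response being 1.
#' @export
fit_weight_models <- function(cohort, specs = default_weight_specs()) {
  fits <- lapply(specs, function(sp) {
    rows <- if (is.null(sp$at_risk)) rep(TRUE, nrow(cohort)) else cohort[[sp$at_risk]] == 1L
    need <- unique(c(sp$response, sp$denominator))
    cc <- stats::complete.cases(cohort[need])
    sub <- cohort[rows & cc, , drop = FALSE]
    fn <- fit_logit(sub, sp$response, sp$numerator, paste(sp$label, "numerator"))
    fd <- fit_logit(sub, sp$response, sp$denominator, paste(sp$label, "denominator"))
    list(spec = sp, ids = sub$id, response = sub[[sp$response]],
         p_num = fn$fitted, p_den = fd$fitted,
         coef_num = fn$coef, coef_den = fd$coef)
  })
  structure(fits, class = "weight_model_fits")
}

#' Compute per-wave stabilized weight components
#'
#' Each component is the numerator probability of the subject's observed
#' state divided by the denominator probability of that state. For
#' censoring models the state is "remained observed", so only uncensored
#' subjects carry a component; subjects carry components only up to their
#' censoring wave.
#'
#' @param fits a [fit_weight_models()] result.
#' @param cohort the coded cohort the models were fitted on.
#' @return A `stabilized_weights` data.frame: `id`, `c_2`, `c_3` and one
#'   component column per model (`sw_x_1`, `sw_x_2`, `sw_m_1`, `sw_m_2`,
#'   `sw_c_2`, `sw_c_3`); `NA` where a subject was not at risk.
#' @export
compute_component_weights <- function(fits, cohort) {
  w <- data.frame(id = cohort$id, c_2 = cohort$c_2, c_3 = cohort$c_3)
  for (f in fits) {
    sp <- f$spec
    col <- sprintf("sw_%s_%d",
                   c(exposure = "x", mediator = "m", censoring = "c")[[sp$target]],
                   sp$wave)
    num_obs <- prob_observed(f$p_num, f$response)
    den_obs <- prob_observed(f$p_den, f$response)
    if (any(den_obs == 0)) {
      stop(sprintf("positivity violation: zero denominator probability in %s", sp$label),
           call. = FALSE)
    }
    comp <- num_obs / den_obs
    keep <- if (sp$target == "censoring") f$response == 1L else rep(TRUE, length(comp))
    w[[col]] <- NA_real_
    w[[col]][match(f$ids[keep], w$id)] <- comp[keep]
  }
  structure(w, class = c("stabilized_weights", "data.frame"),
            fits = fits, stage = "components")
}

#' Combine weight components into the total stabilized weight
#'
#' Multiplies the per-wave exposure, censoring and (optionally) mediator
#' components into `sw_total` for the analysis set of subjects observed
#' through wave 3. Dropping the mediator components gives the weighting
#' variant sometimes preferred for the total-effect model; the default
#' mirrors a single combined weight used for both outcome models.
#'
#' @param w component weights from [compute_component_weights()].
#' @param include_mediator multiply in the mediator components?
#' @param include_censoring multiply in the censoring components? Set to
#'   `FALSE` for best/worst-case dropout re-analyses in which censored
#'   subjects re-enter the analysis set.
#' @param partial_ok if `TRUE`, missing components (subjects censored
#'   before a wave, under `include_censoring = FALSE`) contribute a
#'   factor of 1 instead of raising an error.
#' @return `w` with an `sw_total` column (NA outside the analysis set).
#' @export
combine_weights <- function(w, include_mediator = TRUE,
                            include_censoring = TRUE, partial_ok = FALSE) {
  comp_cols <- c("sw_x_1", "sw_x_2",
                 if (include_mediator) c("sw_m_1", "sw_m_2"),
                 if (include_censoring) c("sw_c_2", "sw_c_3"))
  comp_cols <- intersect(comp_cols, names(w))
  in_set <- if (include_censoring) w$c_3 == 1L else rep(TRUE, nrow(w))
  mat <- as.matrix(w[comp_cols])
  if (!partial_ok && any(is.na(mat[in_set, ]))) {
    bad <- w$id[in_set][rowSums(is.na(mat[in_set, , drop = FALSE])) > 0][1]
    stop(sprintf("missing weight component for uncensored subject id %s", bad),
         call. = FALSE)
  }
  if (partial_ok) mat[is.na(mat)] <- 1
  w$sw_total <- NA_real_
  w$sw_total[in_set] <- apply(mat[in_set, , drop = FALSE], 1, prod)
  attr(w, "stage") <- "combined"
  attr(w, "components_used") <- comp_cols
  w
}

#' Truncate stabilized weights at an upper percentile or absolute cap
#'
#' Caps the total stabilized weight at the given empirical percentile
#' (linear-interpolation definition) or at an explicit absolute value, to
#' limit the influence of extreme weights. Values at or below the
#' threshold are unchanged. Optionally also floors at a lower percentile
#' for symmetric truncation.
#'
#' @param w a `stabilized_weights` data.frame with `sw_total`, or a bare
#'   positive numeric vector.
#' @param upper_percentile percentile in (0.5, 1] (or (50, 100] on the
#'   percent scale) at which to cap; default 0.95.
#' @param cap absolute cap overriding the percentile, if supplied.
#' @param lower_percentile optional lower percentile to floor at.
#' @return The input with an `sw_trunc` column and
#'   `attr(, "truncation")` recording the thresholds.
#' @export
truncate_weights <- function(w, upper_percentile = 0.95, cap = NULL,
                             lower_percentile = NULL) {
  bare <- is.numeric(w) && is.null(dim(w))
  if (bare) w <- data.frame(id = seq_along(w), sw_total = as.numeric(w))
  sw <- w$sw_total
  ok <- !is.na(sw)
  if (any(sw[ok] <= 0)) stop("weights must be positive", call. = FALSE)
  if (is.null(cap)) {
    if (upper_percentile > 1) upper_percentile <- upper_percentile / 100
    if (upper_percentile <= 0.5 || upper_percentile > 1) {
      stop("`upper_percentile` must lie in (0.5, 1]", call. = FALSE)
    }
    cap <- stats::quantile(sw[ok], upper_percentile, type = 7, names = FALSE)
  }
  floor_val <- NULL
  if (!is.null(lower_percentile)) {
    if (lower_percentile > 1) lower_percentile <- lower_percentile / 100
    floor_val <- stats::quantile(sw[ok], lower_percentile, type = 7, names = FALSE)
  }
  tr <- pmin(sw, cap)
  if (!is.null(floor_val)) tr <- pmax(tr, floor_val)
  w$sw_trunc <- tr
  attr(w, "truncation") <- list(threshold = cap, lower = floor_val,
                                percentile_method = "linear interpolation (type 7)")
  w
}

#' Distribution and positivity diagnostics for stabilized weights
#'
#' Reports mean, SD and extreme percentiles (1st/99th, plus 5th/95th) of
#' the total stabilized weight before and after truncation, and, per
#' weight model, the fraction of denominator-model predicted
#' probabilities outside the positivity bounds.
#'
#' @param w combined (optionally truncated) `stabilized_weights`.
#' @param fits the [fit_weight_models()] result (taken from `attr(w,
#'   "fits")` if present).
#' @param prob_low,prob_high positivity bounds on predicted
#'   probabilities; defaults 0.05 and 0.95.
#' @param alarm flag the report when any model's out-of-bounds fraction
#'   exceeds this level (default 0.05).
#' @return A `weight_diagnostics` list: `before`, `after` (each mean,
#'   sd, p01, p05, p95, p99), `positivity` data.frame, `flagged`, and
#'   the raw weight vector (`sw_total`) for external plotting.
#' @export
weight_diagnostics <- function(w, fits = attr(w, "fits"),
                               prob_low = 0.05, prob_high = 0.95, alarm = 0.05) {
  summ <- function(v) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.01, 0.05, 0.95, 0.99), type = 7, names = FALSE)
    list(mean = mean(v), sd = stats::sd(v),
         p01 = q[1], p05 = q[2], p95 = q[3], p99 = q[4])
  }
  pos <- NULL
  if (!is.null(fits)) {
    pos <- do.call(rbind, lapply(fits, function(f) {
      data.frame(model = f$spec$label,
                 frac_below = mean(f$p_den < prob_low),
                 frac_above = mean(f$p_den > prob_high))
    }))
    rownames(pos) <- NULL
  }
  flagged <- !is.null(pos) && any(pos$frac_below + pos$frac_above > alarm)
  structure(
    list(before = summ(w$sw_total),
         after = if ("sw_trunc" %in% names(w)) summ(w$sw_trunc) else NULL,
         truncation = attr(w, "truncation"),
         positivity = pos, bounds = c(prob_low, prob_high),
         alarm = alarm, flagged = flagged,
         sw_total = w$sw_total[!is.na(w$sw_total)]),
    class = "weight_diagnostics"
  )
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  line <- function(s, lab) {
    cat(sprintf("  %-7s mean %.3f, sd %.3f, p01 %.3f, p99 %.3f\n",
                lab, s$mean, s$sd, s$p01, s$p99))
  }
  cat("Stabilized weight diagnostics\n")
  line(x$before, "raw:")
  if (!is.null(x$after)) line(x$after, "capped:")
  if (!is.null(x$truncation)) {
    cat(sprintf("  truncation threshold: %.4f\n", x$truncation$threshold))
  }
  if (!is.null(x$positivity)) {
    cat(sprintf("  predicted probabilities outside (%.2f, %.2f):\n",
                x$bounds[1], x$bounds[2]))
    for (i in seq_len(nrow(x$positivity))) {
      cat(sprintf("    %-18s %.2f%% below, %.2f%% above\n", x$positivity$model[i],
                  100 * x$positivity$frac_below[i], 100 * x$positivity$frac_above[i]))
    }
  }
  cat(if (x$flagged) "  FLAGGED: positivity alarm exceeded\n" else "  positivity: no alarm\n")
  invisible(x)
}

#' Fit, combine and truncate stabilized weights in one call
#'
#' Convenience wrapper chaining [fit_weight_models()],
#' [compute_component_weights()], [combine_weights()] and
#' [truncate_weights()].
#'
#' @inheritParams fit_weight_models
#' @inheritParams combine_weights
#' @param truncate upper truncation percentile, or `NULL` to skip.
#' @return A combined, truncated `stabilized_weights` data.frame with
#'   the model fits attached.
#' @export
stabilized_weights <- function(cohort, specs = default_weight_specs(),
                               include_mediator = TRUE, truncate = 0.95) {
  fits <- fit_weight_models(cohort, specs)
  w <- compute_component_weights(fits, cohort)
  w <- combine_weights(w, include_mediator = include_mediator)
  if (!is.null(truncate)) w <- truncate_weights(w, upper_percentile = truncate)
  attr(w, "fits") <- fits
  w
}
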