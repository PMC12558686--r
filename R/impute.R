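# Missing-data machinery: chained-equations multiple imputation with
# posterior-draw logistic models and predictive mean matching, Rubin's-rules
# pooling, and deterministic best/worst-case outcome completion for
# subjects lost to follow-up.

# Design matrix from predictor columns, characters as factors, constant
# columns dropped (keeps chains alive when a bootstrap/subset loses a level).
impute_design <- function(data, cols) {
  df <- data[cols]
  df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
  X <- stats::model.matrix(~ ., data = df)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) > 0))
  X[, keep, drop = FALSE]
}

draw_beta <- function(X, fit_coef, XtWX_inv, sigma = 1) {
  L <- tryCatch(chol(XtWX_inv), error = function(e) NULL)
  if (is.null(L)) return(fit_coef)
  fit_coef + sigma * as.numeric(t(L) %*% stats::rnorm(length(fit_coef)))
}

# One logistic imputation sweep for a binary column: posterior draw of the
# coefficients, then Bernoulli draws for the missing cells. Falls back to an
# observed-margin draw (with a warning) if the sub-model cannot be fitted.
impute_logreg <- function(y, X, mis) {
  obs <- !mis
  fit <- tryCatch({
    f <- suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE], y[obs],
                                         family = stats::binomial()))
    if (!f$converged || any(is.na(f$coefficients))) NULL else f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic imputation sub-model did not converge; drawing from the observed margin",
            call. = FALSE)
    return(stats::rbinom(sum(mis), 1L, mean(y[obs])))
  }
  W <- fit$weights
  XtWX <- crossprod(X[obs, , drop = FALSE] * sqrt(W))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  beta <- fit$coefficients
  if (!is.null(V)) beta <- draw_beta(X, beta, V)
  p <- stats::plogis(as.numeric(X[mis, , drop = FALSE] %*% beta))
  stats::rbinom(sum(mis), 1L, p)
}

# Predictive-mean-matching sweep for a numeric column: Bayesian linear
# sub-model, then each missing cell borrows the observed value of one of
# its `donors` nearest neighbours on the predicted scale.
impute_pmm <- function(y, X, mis, donors = 5L) {
  obs <- !mis
  qrX <- qr(X[obs, , drop = FALSE])
  rank_ok <- qrX$rank == ncol(X)
  beta_hat <- qr.coef(qrX, y[obs])
  beta_hat[is.na(beta_hat)] <- 0
  res <- y[obs] - as.numeric(X[obs, , drop = FALSE] %*% beta_hat)
  df <- max(sum(obs) - ncol(X), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta_hat
  if (rank_ok) {
    V <- chol2inv(chol(crossprod(X[obs, , drop = FALSE])))
    beta_star <- draw_beta(X, beta_hat, V, sigma = sqrt(sigma2))
  }
  yhat_obs <- as.numeric(X[obs, , drop = FALSE] %*% beta_hat)
  yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% beta_star)
  y_obs <- y[obs]
  k <- min(donors, length(y_obs))
  vapply(yhat_mis, function(v) {
    idx <- order(abs(yhat_obs - v))[seq_len(k)]
    y_obs[idx[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells of an analysis table by iterated column-wise
#' conditional models: a Bayesian-draw logistic model for binary
#' columns and predictive mean matching (5 donors) for numeric scores,
#' sweeping the columns with missingness in a fixed order (the column
#' order of `data`, which for cohort tables should follow the causal
#' ordering covariates, exposure, mediator, outcome). Every other
#' column, including the outcome, serves as a predictor in each
#' sub-model. Observed cells are never altered.
#'
#' @param data data.frame to impute; columns with missingness must be
#'   numeric (binary 0/1 or scores). Restrict to subjects retained
#'   through follow-up before calling (the missing-at-random assumption
#'   is conditional on remaining observed).
#' @param m number of completed datasets (default 10).
#' @param seed integer seed; the full set of chains is reproducible.
#' @param max_iter chained sweeps per dataset (default 10).
#' @return An object of class `imputation_set`: `datasets` (list of m
#'   completed data.frames), `m`, `seed`, `max_iter`, and `method_map`
#'   naming the method used per imputed column.
#' @export
impute_chained <- function(data, m = 10L, seed = 1L, max_iter = 10L) {
  stopifnot(is.data.frame(data), m >= 1, max_iter >= 1)
  na_mat <- is.na(data)
  target_cols <- names(data)[colSums(na_mat) > 0]
  all_missing <- names(data)[colSums(na_mat) == nrow(data)]
  if (length(all_missing)) {
    stop(sprintf("column `%s` is 100%% missing and cannot be imputed", all_missing[1]),
         call. = FALSE)
  }
  method_map <- vapply(target_cols, function(j) {
    col <- data[[j]]
    if (!is.numeric(col)) {
      stop(sprintf("column `%s` has missing values but is not numeric", j), call. = FALSE)
    }
    if (is_binary01(col)) "logreg" else "pmm"
  }, character(1))

  set.seed(as.integer(seed))
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    cur <- data
    if (length(target_cols)) {
      # initialize missing cells from the observed margins
      for (j in target_cols) {
        mis <- na_mat[, j]
        cur[[j]][mis] <- sample(data[[j]][!mis], sum(mis), replace = TRUE)
      }
      for (it in seq_len(max_iter)) {
        for (j in target_cols) {
          mis <- na_mat[, j]
          X <- impute_design(cur, setdiff(names(data), j))
          cur[[j]][mis] <- if (method_map[[j]] == "logreg") {
            impute_logreg(cur[[j]], X, mis)
          } else {
            impute_pmm(cur[[j]], X, mis)
          }
        }
      }
    }
    datasets[[k]] <- cur
  }
  structure(
    list(datasets = datasets, m = as.integer(m), seed = as.integer(seed),
         max_iter = as.integer(max_iter), method_map = as.list(method_map)),
    class = "imputation_set"
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d completed datasets (%d chained sweeps, seed %d)\n",
              x$m, x$max_iter, x$seed))
  if (length(x$method_map)) {
    cat("  methods:", paste(names(x$method_map), unlist(x$method_map),
                            sep = ":", collapse = ", "), "\n")
  } else cat("  no missing cells; datasets are copies of the input\n")
  invisible(x)
}

#' Write an imputation set as CSV files plus a JSON manifest
#'
#' One `imputation_<k>.csv` per completed dataset and a
#' `manifest.json` recording the seed, sweep count and per-column
#' method, so an imputation run can be audited or reused outside R.
#'
#' @param imp an [impute_chained()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(imp, dir) {
  stopifnot(inherits(imp, "imputation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(imp$m)) {
    utils::write.csv(imp$datasets[[k]],
                     file.path(dir, sprintf("imputation_%02d.csv", k)),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(
    list(m = imp$m, seed = imp$seed, max_iter = imp$max_iter,
         method_map = imp$method_map),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance adds the within-imputation variance and the
#' between-imputation variance inflated by (1 + 1/m). Degrees of freedom
#' follow the classical Rubin formula. Pool ratio effects on the log
#' scale and back-transform.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances numeric vector of their squared standard errors.
#' @param conf_level confidence level for the t interval.
#' @return An object of class `pooled_estimate`: `estimate`,
#'   `within_var`, `between_var`, `total_var`, `se`, `df`, `ci_low`,
#'   `ci_high`, `m`.
#' @export
#' @examples
#' rubin_pool(c(1, 2), c(0.5, 0.5))$total_var  # 0.5 + 1.5 * 0.5 = 1.25
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  if (length(estimates) != length(variances)) {
    stop("`estimates` and `variances` must have the same length", call. = FALSE)
  }
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs at least 2 imputations", call. = FALSE)
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  qbar <- mean(estimates)
  wvar <- mean(variances)
  bvar <- stats::var(estimates)
  tvar <- wvar + (1 + 1 / m) * bvar
  df <- if (bvar > 0) (m - 1) * (1 + wvar / ((1 + 1 / m) * bvar))^2 else Inf
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(estimate = qbar, within_var = wvar, between_var = bvar,
         total_var = tvar, se = sqrt(tvar), df = df,
         ci_low = qbar - tq * sqrt(tvar), ci_high = qbar + tq * sqrt(tvar),
         m = m, conf_level = conf_level),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over m = %d imputations\n", x$m))
  cat(sprintf("  estimate %.4f (SE %.4f), %.0f%% CI [%.4f, %.4f], df %.1f\n",
              x$estimate, x$se, 100 * x$conf_level, x$ci_low, x$ci_high, x$df))
  cat(sprintf("  within var %.5f, between var %.5f, total var %.5f\n",
              x$within_var, x$between_var, x$total_var))
  invisible(x)
}

#' Best/worst-case outcome completion for subjects lost to follow-up
#'
#' Deterministic missing-not-at-random sensitivity completion: every
#' subject censored before wave 3 is assigned outcome 0 (best case:
#' no dropout developed the outcome) or 1 (worst case: all did), and
#' re-enters the analysis set. Wave-2 exposure/mediator values missing
#' because the subject had already dropped out are carried forward from
#' wave 1. Re-fit the outcome models with exposure/mediator weights only
#' (`combine_weights(..., include_censoring = FALSE, partial_ok =
#' TRUE)`), since censoring is no longer a selection event.
#'
#' @param cohort a coded binary-mode cohort ([code_cohort()]).
#' @param scenario `"best"` or `"worst"`.
#' @return The cohort with `y_bin` completed for censored subjects, a
#'   `mnar_completed` indicator column, and `attr(, "mnar_scenario")`.
#' @export
mnar_complete <- function(cohort, scenario = c("best", "worst")) {
  scenario <- match.arg(scenario)
  rules <- attr(cohort, "rules")
  if (!is.null(rules) && rules$mode == "continuous") {
    stop("best/worst-case completion is defined for the binary outcome only", call. = FALSE)
  }
  if (!"y_bin" %in% names(cohort)) {
    stop("cohort must be coded (code_cohort()) before MNAR completion", call. = FALSE)
  }
  censored <- cohort$c_3 == 0L
  fill <- if (scenario == "best") 0L else 1L
  cohort$y_bin[censored] <- fill
  carry <- censored
  cohort$x_2[carry & is.na(cohort$x_2)] <- cohort$x_1[carry & is.na(cohort$x_2)]
  cohort$m_2[carry & is.na(cohort$m_2)] <- cohort$m_1[carry & is.na(cohort$m_2)]
  cohort$tils_2[carry & is.na(cohort$tils_2)] <- cohort$tils_1[carry & is.na(cohort$tils_2)]
  cohort$mnar_completed <- as.integer(censored)
  attr(cohort, "mnar_scenario") <- scenario
  cohort
}
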