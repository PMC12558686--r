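# End-to-end orchestration: cohort I/O, configuration, the analysis blocks
# (primary + sensitivity variants), and a structured run report.

LONG_COLS <- c("id", "wave", "female", "ethnicity", "low_education", "housing",
               "cognitive_flag", "age", "mobility", "cerebrovascular", "coronary",
               "diabetes", "cancer", "support", "chew_group", "tils", "cesd",
               "observed")

#' Write a cohort as a long-format CSV
#'
#' One row per subject-wave with the columns listed in the package's
#' data dictionary (`inst/extdata/cohort-data-dictionary.tsv`); missing
#' values are written as empty fields. Round-trips through
#' [validate_cohort_csv()].
#'
#' @param cohort an `msm_cohort` wide table.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  per_wave <- function(w) {
    data.frame(
      id = cohort$id, wave = w,
      female = cohort$female, ethnicity = cohort$ethnicity,
      low_education = cohort$low_education, housing = cohort$housing,
      cognitive_flag = cohort$cognitive_flag,
      age = cohort[[paste0("age_", w)]],
      mobility = cohort[[paste0("mobility_", w)]],
      cerebrovascular = cohort[[paste0("cerebrovascular_", w)]],
      coronary = cohort[[paste0("coronary_", w)]],
      diabetes = cohort[[paste0("diabetes_", w)]],
      cancer = cohort[[paste0("cancer_", w)]],
      support = cohort[[paste0("support_", w)]],
      chew_group = if (w < 3) cohort[[paste0("chew_group_", w)]] else NA,
      tils = if (w < 3) cohort[[paste0("tils_", w)]] else NA,
      cesd = if (w == 1) cohort$cesd_1 else if (w == 3) cohort$cesd_3 else NA,
      observed = if (w == 1) 1L else cohort[[paste0("c_", w)]],
      stringsAsFactors = FALSE
    )
  }
  long <- rbind(per_wave(1L), per_wave(2L), per_wave(3L))
  long <- long[order(long$id, long$wave), LONG_COLS]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a long-format cohort CSV
#'
#' Checks the column set, score ranges (chew group 1..6, TILS 0..12,
#' CES-D 0..22, social support 0..60, binary indicators), wave-1
#' completeness of the observation indicator, and monotone censoring
#' (once unobserved, never observed again), naming offending subjects.
#'
#' @param path CSV written by [write_cohort_csv()] or following the data
#'   dictionary.
#' @return A wide `msm_cohort` data.frame.
#' @export
validate_cohort_csv <- function(path) {
  long <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  unknown <- setdiff(names(long), LONG_COLS)
  if (length(unknown)) {
    stop(sprintf("unknown column(s) in cohort CSV: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing_cols <- setdiff(LONG_COLS, names(long))
  if (length(missing_cols)) {
    stop(sprintf("cohort CSV lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  check_range <- function(col, lo, hi, label) {
    bad <- !is.na(long[[col]]) & (long[[col]] < lo | long[[col]] > hi)
    if (any(bad)) {
      stop(sprintf("%s out of range [%s, %s] for subject id(s) %s (column `%s`)",
                   label, lo, hi,
                   paste(unique(long$id[bad])[1:min(5, sum(bad))], collapse = ", "),
                   col), call. = FALSE)
    }
  }
  check_range("chew_group", 1, 6, "chewing group")
  check_range("tils", 0, 12, "TILS score")
  check_range("cesd", 0, 22, "CES-D score")
  check_range("support", 0, 60, "social support score")
  for (col in c("female", "low_education", "cognitive_flag", "mobility",
                "cerebrovascular", "coronary", "diabetes", "cancer", "observed")) {
    check_range(col, 0, 1, col)
  }
  wide <- long[long$wave == 1,
               c("id", "female", "ethnicity", "low_education", "housing", "cognitive_flag")]
  if (any(is.na(long$observed[long$wave == 1])) || any(long$observed[long$wave == 1] != 1)) {
    stop("every subject must be observed at wave 1", call. = FALSE)
  }
  for (w in 1:3) {
    lw <- long[long$wave == w, ]
    lw <- lw[match(wide$id, lw$id), ]
    for (col in c("age", "mobility", "cerebrovascular", "coronary", "diabetes",
                  "cancer", "support")) {
      wide[[paste0(col, "_", w)]] <- lw[[col]]
    }
    if (w < 3) {
      wide[[paste0("chew_group_", w)]] <- lw$chew_group
      wide[[paste0("tils_", w)]] <- lw$tils
    }
    if (w == 1) wide$cesd_1 <- lw$cesd
    if (w == 3) wide$cesd_3 <- lw$cesd
    if (w > 1) wide[[paste0("c_", w)]] <- lw$observed
  }
  non_mono <- wide$c_2 == 0 & wide$c_3 == 1
  if (any(non_mono, na.rm = TRUE)) {
    stop(sprintf("non-monotone censoring (unobserved at wave 2 but observed at wave 3) for subject id(s) %s",
                 paste(wide$id[which(non_mono)][1:min(5, sum(non_mono))], collapse = ", ")),
         call. = FALSE)
  }
  wide <- wide[, c("id", "female", "ethnicity", "low_education", "housing", "cognitive_flag",
                   paste0("age_", 1:3), paste0("mobility_", 1:3),
                   paste0("cerebrovascular_", 1:3), paste0("coronary_", 1:3),
                   paste0("diabetes_", 1:3), paste0("cancer_", 1:3),
                   paste0("support_", 1:3), "chew_group_1", "chew_group_2",
                   "tils_1", "tils_2", "cesd_1", "c_2", "c_3", "cesd_3")]
  rownames(wide) <- NULL
  structure(wide, class = c("msm_cohort", "data.frame"))
}

#' Configuration for an end-to-end pipeline run
#'
#' @param input_csv path to a long-format cohort CSV, or `NULL` to
#'   simulate from `params` (exactly one source must be given).
#' @param params a [generator_params()] object (ignored if `input_csv`
#'   is given).
#' @param rules [coding_rules()] for the primary block.
#' @param truncate upper weight-truncation percentile (default 0.95).
#' @param prob_bounds positivity bounds for diagnostics.
#' @param mediator_weights_in_total use the single combined stabilized
#'   weight (exposure x mediator x censoring) for the total-effect model
#'   too (default), or exposure x censoring only.
#' @param cum_coding cumulative exposure/mediator coding, `"mean"` or
#'   `"sum"`.
#' @param mi list: `enabled`, `m`, `max_iter`, `seed` (auto-filled from
#'   `seed` when NULL).
#' @param bootstrap list: `enabled`, `B`, `seed`.
#' @param variants character subset of `"lenient_exposure"`,
#'   `"strict_mediator"`, `"baseline_exclusion"`, `"continuous"`,
#'   `"mnar_best"`, `"mnar_worst"`; the primary block always runs.
#' @param seed master seed; all stage seeds are resolved from it and
#'   echoed in the report.
#' @param out_dir directory for the JSON report and CSV artifacts
#'   (`NULL` = return the report only).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, params = NULL,
                            rules = coding_rules(),
                            truncate = 0.95, prob_bounds = c(0.05, 0.95),
                            mediator_weights_in_total = TRUE,
                            cum_coding = "mean",
                            mi = list(enabled = FALSE, m = 10L, max_iter = 5L, seed = NULL),
                            bootstrap = list(enabled = FALSE, B = 5000L, seed = NULL),
                            variants = character(),
                            seed = 1L, out_dir = NULL) {
  if (is.null(input_csv) == is.null(params)) {
    stop("exactly one input source (`input_csv` or `params`) must be supplied",
         call. = FALSE)
  }
  known <- c("lenient_exposure", "strict_mediator", "baseline_exclusion",
             "continuous", "mnar_best", "mnar_worst")
  bad <- setdiff(variants, known)
  if (length(bad)) stop(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  mi <- utils::modifyList(list(enabled = FALSE, m = 10L, max_iter = 5L, seed = NULL), mi)
  bootstrap <- utils::modifyList(list(enabled = FALSE, B = 5000L, seed = NULL), bootstrap)
  if (is.null(mi$seed)) mi$seed <- as.integer(seed) + 1L
  if (is.null(bootstrap$seed)) bootstrap$seed <- as.integer(seed) + 2L
  structure(
    list(input_csv = input_csv, params = params, rules = rules,
         truncate = truncate, prob_bounds = prob_bounds,
         mediator_weights_in_total = mediator_weights_in_total,
         cum_coding = cum_coding, mi = mi, bootstrap = bootstrap,
         variants = variants, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# columns the weight models and outcome models touch, for complete-case
# filtering of the analysis set
analysis_columns <- function() {
  c("x_1", "x_2", "m_1", "m_2", "y_bin", L0_COLS, lt_cols(1), lt_cols(2))
}

#' Drop uncensored subjects with incomplete analysis variables
#'
#' Complete-case restriction for analyses without multiple imputation:
#' subjects observed through wave 3 must be complete on every column the
#' weight and outcome models use; censored subjects stay (they inform
#' the censoring models, which complete-case per model). The number of
#' subjects dropped is recorded in `attr(, "n_incomplete_dropped")`.
#'
#' @param coded a coded cohort ([code_cohort()]).
#' @param continuous use the continuous-mode column set (CES-D and TILS
#'   scores instead of the binary outcome)?
#' @return The filtered cohort.
#' @export
complete_case_filter <- function(coded, continuous = FALSE) {
  cols <- analysis_columns()
  if (continuous) cols <- c(setdiff(cols, "y_bin"), "cesd_3", "tils_1", "tils_2")
  cc <- stats::complete.cases(coded[cols])
  drop <- coded$c_3 == 1L & !cc
  out <- coded[!drop, , drop = FALSE]
  attr(out, "rules") <- attr(coded, "rules")
  attr(out, "n_incomplete_dropped") <- sum(drop)
  out
}

# weights for the two outcome models under the configured variant
weights_for_models <- function(coded, cfg, include_censoring = TRUE,
                               partial_ok = FALSE) {
  fits <- fit_weight_models(coded)
  comp <- compute_component_weights(fits, coded)
  direct_w <- combine_weights(comp, include_mediator = TRUE,
                              include_censoring = include_censoring,
                              partial_ok = partial_ok)
  total_w <- if (cfg$mediator_weights_in_total) direct_w else
    combine_weights(comp, include_mediator = FALSE,
                    include_censoring = include_censoring,
                    partial_ok = partial_ok)
  direct_w <- truncate_weights(direct_w, upper_percentile = cfg$truncate)
  total_w <- truncate_weights(total_w, upper_percentile = cfg$truncate)
  attr(direct_w, "fits") <- fits
  list(total = total_w, direct = direct_w, fits = fits)
}

fit_both_models <- function(rows_total, rows_direct) {
  list(total = fit_msm_binary(rows_total, include_mediator = FALSE),
       direct = fit_msm_binary(rows_direct, include_mediator = TRUE))
}

block_counts <- function(elig_attr, coded, n_incomplete = 0L) {
  n_cens <- sum(coded$c_3 == 0L)
  list(
    n_input = elig_attr$n_input,
    excluded_baseline_csds = elig_attr$excluded_baseline_csds,
    excluded_missing_baseline = elig_attr$excluded_missing_baseline_exposure +
      elig_attr$excluded_missing_baseline_outcome,
    n_eligible = elig_attr$n_retained,
    n_censored = n_cens,
    n_incomplete_dropped = n_incomplete,
    n_analyzed = sum(coded$c_3 == 1L)
  )
}

# one complete-case binary analysis block
run_binary_block <- function(cohort, rules, cfg, label, bootstrap = FALSE) {
  elig <- apply_eligibility(cohort, rules)
  coded <- code_cohort(elig, rules)
  coded <- complete_case_filter(coded)
  w <- weights_for_models(coded, cfg)
  rows_t <- build_analysis_rows(coded, w$total, coding = cfg$cum_coding)
  rows_d <- build_analysis_rows(coded, w$direct, coding = cfg$cum_coding)
  fits <- fit_both_models(rows_t, rows_d)
  summary <- decompose_effects(fits$total, fits$direct)
  diag <- weight_diagnostics(w$direct, fits = w$fits,
                             prob_low = cfg$prob_bounds[1], prob_high = cfg$prob_bounds[2])
  boot <- NULL
  if (bootstrap) {
    stat <- function(d) {
      d$id <- seq_len(nrow(d))  # resampled subjects need unique ids
      cd <- code_cohort(d, rules)
      cd <- complete_case_filter(cd)
      ww <- weights_for_models(cd, cfg)
      rr <- build_analysis_rows(cd, ww$total, coding = cfg$cum_coding)
      fit_msm_binary(rr)$coef[["cum_x"]]
    }
    bb <- bca_bootstrap(elig, stat, B = cfg$bootstrap$B, seed = cfg$bootstrap$seed)
    boot <- list(total_log_rr = bb$t0, ci_rr = exp(bb$ci), z0 = bb$z0,
                 acceleration = bb$acceleration, B = bb$B, n_failed = bb$n_failed,
                 seed = bb$seed)
  }
  list(label = label, mode = "binary", mi = FALSE,
       counts = block_counts(attr(elig, "eligibility"), coded,
                             attr(coded, "n_incomplete_dropped")),
       estimates = summary, models = fits, weight_diagnostics = diag,
       bootstrap = boot)
}

mi_impute_frame <- function(coded) {
  c("female", "ethnicity", "low_education", "housing",
    "age_1", "mobility_1", "support_1",
    "cerebrovascular_1", "coronary_1", "diabetes_1", "cancer_1",
    "mobility_2", "support_2",
    "chew_group_1", "chew_group_2", "tils_1", "tils_2", "cesd_3")
}

# binary analysis with chained-equations MI among subjects observed
# through wave 3, Rubin pooling on the log-RR scale
run_mi_block <- function(cohort, rules, cfg, label) {
  elig <- apply_eligibility(cohort, rules)
  coded <- code_cohort(elig, rules)
  unc <- coded$c_3 == 1L
  frame_cols <- mi_impute_frame(coded)
  imp <- impute_chained(coded[unc, frame_cols], m = cfg$mi$m,
                        seed = cfg$mi$seed, max_iter = cfg$mi$max_iter)
  per_imp <- lapply(imp$datasets, function(dk) {
    ck <- coded
    for (col in frame_cols) ck[[col]][unc] <- dk[[col]]
    ck <- code_cohort(ck, rules)            # recode x/m from imputed scores
    ck <- complete_case_filter(ck)          # censored rows may stay incomplete
    w <- weights_for_models(ck, cfg)
    rows_t <- build_analysis_rows(ck, w$total, coding = cfg$cum_coding)
    rows_d <- build_analysis_rows(ck, w$direct, coding = cfg$cum_coding)
    f <- fit_both_models(rows_t, rows_d)
    c(b_tot = unname(f$total$coef["cum_x"]),
      v_tot = unname(f$total$robust_se["cum_x"])^2,
      b_dir = unname(f$direct$coef["cum_x"]),
      v_dir = unname(f$direct$robust_se["cum_x"])^2,
      b_med = unname(f$direct$coef["cum_m"]),
      v_med = unname(f$direct$robust_se["cum_m"])^2,
      n = f$total$n_effective)
  })
  est <- do.call(rbind, per_imp)
  pool_t <- rubin_pool(est[, "b_tot"], est[, "v_tot"])
  pool_d <- rubin_pool(est[, "b_dir"], est[, "v_dir"])
  pool_m <- rubin_pool(est[, "b_med"], est[, "v_med"])
  summary <- mediation_summary_from_rr(
    exp(pool_t$estimate), exp(pool_d$estimate), exp(pool_m$estimate),
    total_ci = exp(c(pool_t$ci_low, pool_t$ci_high)),
    direct_ci = exp(c(pool_d$ci_low, pool_d$ci_high)),
    mediator_ci = exp(c(pool_m$ci_low, pool_m$ci_high))
  )
  list(label = label, mode = "binary", mi = TRUE, m = cfg$mi$m,
       counts = block_counts(attr(elig, "eligibility"), coded, 0L),
       estimates = summary,
       pooled = list(total = pool_t, direct = pool_d, mediator = pool_m),
       n_effective = round(mean(est[, "n"])))
}

# continuous-score sensitivity block: identity-link weighted regression,
# mean differences converted to approximate RRs
run_continuous_block <- function(cohort, cfg, label) {
  rules <- cfg$rules
  rules$mode <- "continuous"
  elig <- apply_eligibility(cohort, rules)
  coded <- code_cohort(elig, rules)
  coded <- complete_case_filter(coded, continuous = TRUE)
  w <- weights_for_models(coded, cfg)
  rows_t <- build_analysis_rows(coded, w$total, coding = cfg$cum_coding)
  rows_d <- build_analysis_rows(coded, w$direct, coding = cfg$cum_coding)
  total <- fit_msm_continuous(rows_t, include_mediator = FALSE)
  direct <- fit_msm_continuous(rows_d, include_mediator = TRUE,
                               mediator_col = "cum_tils")
  ref_sd <- stats::sd(rows_t$cesd_3[rows_t$cum_x == 0])
  md_x <- unname(total$effect["cum_x"])
  md_x_dir <- unname(direct$effect["cum_x"])
  md_m <- unname(direct$effect["cum_m"])
  rr <- list(total = md_to_rr(md_x, ref_sd),
             direct = md_to_rr(md_x_dir, ref_sd),
             mediator = md_to_rr(md_m, ref_sd))
  summary <- mediation_summary_from_rr(
    rr$total, rr$direct, rr$mediator,
    total_ci = md_to_rr(c(total$ci_low["cum_x"], total$ci_high["cum_x"]), ref_sd),
    direct_ci = md_to_rr(c(direct$ci_low["cum_x"], direct$ci_high["cum_x"]), ref_sd),
    mediator_ci = md_to_rr(c(direct$ci_low["cum_m"], direct$ci_high["cum_m"]), ref_sd)
  )
  list(label = label, mode = "continuous", mi = FALSE,
       counts = block_counts(attr(elig, "eligibility"), coded,
                             attr(coded, "n_incomplete_dropped")),
       mean_differences = list(total = md_x, direct = md_x_dir,
                               mediator_per_point = md_m, reference_sd = ref_sd),
       estimates = summary, models = list(total = total, direct = direct))
}

# best/worst-case dropout completion: censored subjects re-enter with the
# scenario outcome; exposure/mediator weights retained, censoring weights
# dropped
run_mnar_block <- function(cohort, rules, cfg, scenario, label) {
  elig <- apply_eligibility(cohort, rules)
  coded <- code_cohort(elig, rules)
  keep <- !is.na(coded$x_1) & !is.na(coded$m_1) &
    !(coded$c_2 == 1L & (is.na(coded$x_2) | is.na(coded$m_2))) &
    !(coded$c_3 == 1L & is.na(coded$y_bin))
  coded <- coded[keep, , drop = FALSE]
  attr(coded, "rules") <- rules
  completed <- mnar_complete(coded, scenario)
  w <- weights_for_models(completed, cfg, include_censoring = FALSE,
                          partial_ok = TRUE)
  rows_t <- build_analysis_rows(completed, w$total, coding = cfg$cum_coding,
                                require_uncensored = FALSE)
  rows_d <- build_analysis_rows(completed, w$direct, coding = cfg$cum_coding,
                                require_uncensored = FALSE)
  fits <- fit_both_models(rows_t, rows_d)
  summary <- decompose_effects(fits$total, fits$direct)
  counts <- block_counts(attr(elig, "eligibility"), coded, sum(!keep))
  counts$n_analyzed <- nrow(completed)
  list(label = label, mode = "binary", mi = FALSE, scenario = scenario,
       counts = counts, estimates = summary, models = fits)
}

#' Run the full analysis pipeline
#'
#' Executes eligibility screening, coding, stabilized weighting, the
#' total- and direct-effect marginal structural models, effect
#' decomposition and E-values for the primary analysis and every
#' requested sensitivity variant (lenient exposure coding, strict
#' mediator threshold, baseline cognitive-flag exclusion, continuous
#' scores, best/worst-case dropout completion), with optional
#' chained-equations multiple imputation and BCa bootstrap for the
#' primary block.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `msm_report`: resolved configuration and
#'   seeds, per-block subject-count ledgers, estimates, weight
#'   diagnostics, and a plain-text log. If `config$out_dir` is set, a
#'   JSON report, weight/analysis-row CSVs and the log are also written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  cohort <- if (!is.null(config$input_csv)) {
    note("input: cohort CSV %s", config$input_csv)
    validate_cohort_csv(config$input_csv)
  } else {
    note("input: synthetic cohort (n = %d, generator seed %d)",
         config$params$n_subjects, config$params$seed)
    generate_cohort(config$params)
  }
  note("seeds: master %d, mi %d, bootstrap %d",
       config$seed, config$mi$seed, config$bootstrap$seed)

  blocks <- list()
  primary_rules <- config$rules
  blocks$primary <- if (config$mi$enabled) {
    run_mi_block(cohort, primary_rules, config, "primary")
  } else {
    run_binary_block(cohort, primary_rules, config, "primary",
                     bootstrap = config$bootstrap$enabled)
  }
  for (v in config$variants) {
    blocks[[v]] <- switch(
      v,
      lenient_exposure = {
        r <- primary_rules; r$exposure_rule <- "lenient"
        run_binary_block(cohort, r, config, "lenient exposure coding")
      },
      strict_mediator = {
        r <- primary_rules; r$mediator_threshold <- 4L
        run_binary_block(cohort, r, config, "strict mediator threshold (TILS >= 4)")
      },
      baseline_exclusion = {
        sub <- cohort[cohort$cognitive_flag == 0L, , drop = FALSE]
        run_binary_block(sub, primary_rules, config, "baseline cognitive-flag exclusion")
      },
      continuous = run_continuous_block(cohort, config, "continuous scores"),
      mnar_best = run_mnar_block(cohort, primary_rules, config, "best",
                                 "best-case dropout completion"),
      mnar_worst = run_mnar_block(cohort, primary_rules, config, "worst",
                                  "worst-case dropout completion")
    )
    note("block `%s` completed (n analyzed = %d)", v, blocks[[v]]$counts$n_analyzed)
  }
  note("block `primary` completed (n analyzed = %d)", blocks$primary$counts$n_analyzed)

  for (b in blocks) {
    flag <- isTRUE(b$weight_diagnostics$flagged)
    if (flag) note("WARNING: positivity alarm in block `%s`", b$label)
  }

  report <- structure(
    list(config = config, blocks = blocks, log = log,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "msm_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_block_json <- function(b) {
  est <- b$estimates
  out <- list(
    label = b$label, mode = b$mode, mi = b$mi, counts = b$counts,
    total_rr = est$total_rr, direct_rr = est$direct_rr,
    mediator_rr = est$mediator_rr,
    proportion_direct = est$proportion_direct,
    proportion_mediated = est$proportion_mediated,
    proportions_defined = est$proportions_defined,
    ci = lapply(est$ci, unname),
    evalues = if (!is.null(est$evalues)) {
      lapply(est$evalues, function(e) list(point = e$evalue, ci = e$evalue_ci))
    }
  )
  if (!is.null(b$weight_diagnostics)) {
    d <- b$weight_diagnostics
    out$weights <- list(before = d$before, after = d$after,
                        truncation_threshold = d$truncation$threshold,
                        positivity = d$positivity, flagged = d$flagged)
  }
  if (!is.null(b$mean_differences)) out$mean_differences <- b$mean_differences
  if (!is.null(b$bootstrap)) out$bootstrap <- b$bootstrap
  if (!is.null(b$scenario)) out$scenario <- b$scenario
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  json <- list(
    seeds = list(master = cfg$seed, mi = cfg$mi$seed, bootstrap = cfg$bootstrap$seed),
    settings = list(truncate = cfg$truncate,
                    prob_bounds = cfg$prob_bounds,
                    mediator_weights_in_total = cfg$mediator_weights_in_total,
                    cum_coding = cfg$cum_coding,
                    exposure_rule = cfg$rules$exposure_rule,
                    mediator_threshold = cfg$rules$mediator_threshold,
                    outcome_threshold = cfg$rules$outcome_threshold),
    blocks = lapply(report$blocks, report_block_json),
    timestamp = report$timestamp
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.msm_report <- function(x, ...) {
  cat("Marginal structural mediation analysis report\n")
  for (b in x$blocks) {
    est <- b$estimates
    cat(sprintf("\n  [%s]%s  n analyzed = %d\n", b$label,
                if (isTRUE(b$mi)) sprintf(" (MI, m = %d)", b$m) else "",
                b$counts$n_analyzed))
    cat(sprintf("    total RR %.3f [%.3f, %.3f]; direct RR %.3f; mediator RR %.3f\n",
                est$total_rr, est$ci$total[1], est$ci$total[2],
                est$direct_rr, est$mediator_rr))
    if (est$proportions_defined) {
      cat(sprintf("    proportion mediated %.2f%% (direct %.2f%%)\n",
                  est$proportion_mediated, est$proportion_direct))
    }
  }
  invisible(x)
}
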