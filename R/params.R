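#' Parameters for the synthetic three-wave cohort generator
#'
#' Bundles the marginal calibration targets, the structural (causal-arrow)
#' coefficients and nuisance settings that define a synthetic cohort of
#' community-dwelling older adults followed over three survey waves. The
#' default margins reproduce the wave-1 profile of a Singaporean ageing
#' panel (female fraction, ethnicity mix, education, public-housing type,
#' age 70.4 (SD 7.1), social-support score 30.2 (SD 12.6), chewing
#' disability 16.8%, loneliness 41.7%), and the default structural
#' coefficients are calibrated so that the counterfactual oracle
#' ([true_effects()]) reports a true total relative risk of roughly 1.5
#' with a positive mediated path through loneliness.
#'
#' Structural links are logistic for binary nodes and linear-Gaussian for
#' the latent depressive-symptom score; the exposure/mediator/censoring
#' arrows carry log-odds coefficients, the outcome arrows are in CES-D
#' score points (the binary outcome is the score thresholded at 7, so one
#' cohort serves both the binary and the continuous analysis).
#'
#' @param n_subjects number of subjects at wave 1.
#' @param seed integer seed governing every draw of the generator.
#' @param margins named list of marginal targets; any subset may be
#'   supplied to override the defaults listed above. Prevalences must lie
#'   in (0, 1), standard deviations must be positive, and the `ethnicity`
#'   and `housing` probability vectors must each sum to 1.
#' @param coef named list of structural coefficients, one per causal
#'   arrow of the generator's graph (see Details); any subset overrides
#'   the defaults. All must be finite.
#' @param miss_rate MCAR missingness rate applied to time-varying
#'   covariates and the mediator score at observed waves.
#' @param miss_baseline MCAR missingness rate applied to baseline
#'   exposure and baseline outcome-screening score (these subjects are
#'   excluded before imputation by [apply_eligibility()]).
#'
#' @details
#' The causal graph has arrows L→X, L→M, L→C, X→M, X→C, X(t−1)→X(t),
#' M(t−1)→M(t), M(t−1)→X(t) (exposure–mediator feedback), and
#' \{X, M, L\}→Y; no arrow leaves Y. The confounder block L acts through a
#' scalar frailty score, a fixed linear combination of sex, education,
#' housing, age, mobility difficulty, chronic conditions and (inverse)
#' social support, so that main-effects logistic weight models are
#' correctly specified for data from this generator.
#'
#' Coefficient names: `l_x`, `x_x`, `m_x` (exposure model), `l_m`, `x_m`,
#' `m_m` (mediator model), `l_c`, `x_c` (retention model, positive =
#' more likely to remain observed), and `x_y`, `m_y`, `l_y`,
#' `outcome_sd` (latent CES-D model, score points).
#'
#' @return An object of class `generator_params` (a validated list).
#' @seealso [generate_cohort()], [true_effects()]
#' @export
#' @examples
#' p <- generator_params(n_subjects = 500, seed = 7)
#' p$margins$exposure_w1
generator_params <- function(n_subjects = 2000,
                             seed = 1L,
                             margins = list(),
                             coef = list(),
                             miss_rate = 0.03,
                             miss_baseline = 0.01) {
  def_margins <- list(
    female = 0.535,
    ethnicity = c(Chinese = 0.760, Malay = 0.153, Indian = 0.077, Others = 0.010),
    low_education = 0.676,
    housing = c(hdb_1_2 = 0.067, hdb_3 = 0.271, hdb_4_5_private = 0.662),
    age_mean = 70.4, age_sd = 7.1,
    support_mean = 30.2, support_sd = 12.6,
    mobility = 0.295,
    cerebrovascular = 0.021, coronary = 0.055, diabetes = 0.217, cancer = 0.019,
    exposure_w1 = 0.168,
    mediator_w1 = 0.417,
    baseline_csds = 0.162,
    outcome_w3 = 0.103,
    cognitive_flag = 0.10,
    retain_w2 = 0.80,
    retain_w3 = 0.75,
    w2_exposure_base = 0.15,
    w2_mediator_base = 0.30
  )
  def_coef <- list(
    l_x = 0.6, x_x = 1.6, m_x = 0.4,
    l_m = 0.7, x_m = 0.55, m_m = 1.4,
    l_c = -0.5, x_c = -0.35,
    x_y = 0.55, m_y = 1.2, l_y = 1.0,
    outcome_sd = 3.0
  )
  unknown <- setdiff(names(margins), names(def_margins))
  if (length(unknown)) stop_field(paste0("margins$", unknown[1]), "unknown margin name")
  unknown <- setdiff(names(coef), names(def_coef))
  if (length(unknown)) stop_field(paste0("coef$", unknown[1]), "unknown coefficient name")
  def_margins[names(margins)] <- margins
  def_coef[names(coef)] <- coef
  p <- structure(
    list(n_subjects = n_subjects, seed = as.integer(seed),
         margins = def_margins, coef = def_coef,
         miss_rate = miss_rate, miss_baseline = miss_baseline),
    class = "generator_params"
  )
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  m <- p$margins
  if (!is.numeric(p$n_subjects) || length(p$n_subjects) != 1 ||
      is.na(p$n_subjects) || p$n_subjects < 1) {
    stop_field("n_subjects", "must be a positive count")
  }
  prev <- c("female", "low_education", "mobility", "cerebrovascular", "coronary",
            "diabetes", "cancer", "exposure_w1", "mediator_w1", "baseline_csds",
            "outcome_w3", "cognitive_flag", "retain_w2", "retain_w3",
            "w2_exposure_base", "w2_mediator_base")
  for (nm in prev) {
    v <- m[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop_field(paste0("margins$", nm), "prevalence target must lie in (0, 1)")
    }
  }
  for (nm in c("age_sd", "support_sd")) {
    if (!is.numeric(m[[nm]]) || m[[nm]] <= 0) {
      stop_field(paste0("margins$", nm), "standard deviation must be > 0")
    }
  }
  for (nm in c("ethnicity", "housing")) {
    v <- m[[nm]]
    if (any(v <= 0) || abs(sum(v) - 1) > 1e-8) {
      stop_field(paste0("margins$", nm), "category probabilities must be positive and sum to 1")
    }
  }
  for (nm in names(p$coef)) {
    v <- p$coef[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop_field(paste0("coef$", nm), "coefficient must be a finite number")
    }
  }
  if (p$coef$outcome_sd <= 0) stop_field("coef$outcome_sd", "must be > 0")
  for (nm in c("miss_rate", "miss_baseline")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1) stop_field(nm, "must lie in [0, 1)")
  }
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n_subjects: %d   seed: %d\n", x$n_subjects, x$seed))
  cat(sprintf("  wave-1 targets: exposure %.3f, mediator %.3f, baseline CSDS %.3f\n",
              x$margins$exposure_w1, x$margins$mediator_w1, x$margins$baseline_csds))
  cat(sprintf("  retention: %.2f (wave 2), %.2f (wave 3); outcome target %.3f\n",
              x$margins$retain_w2, x$margins$retain_w3, x$margins$outcome_w3))
  cat("  structural coefficients:\n")
  cf <- unlist(x$coef)
  cat(sprintf("    %s\n", paste(names(cf), format(cf, digits = 3), sep = "=", collapse = " ")))
  invisible(x)
}

#' Serialize generator parameters to a flat key = value config file
#'
#' Writes one `path.style.key = value` line per scalar (vector margins are
#' expanded per category), so a parameter set can be stored next to the
#' cohort CSV it produced and read back with [read_generator_config()].
#'
#' @param params a [generator_params()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(params, path) {
  stopifnot(inherits(params, "generator_params"))
  flat <- c(
    n_subjects = params$n_subjects, seed = params$seed,
    miss_rate = params$miss_rate, miss_baseline = params$miss_baseline,
    unlist(list(margins = params$margins)),
    unlist(list(coef = params$coef))
  )
  lines <- sprintf("%s = %s", names(flat),
                   vapply(flat, function(v) format(v, digits = 17), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read generator parameters back from a flat config file
#'
#' @param path file written by [write_generator_config()].
#' @return A validated [generator_params()] object.
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  names(vals) <- keys
  pick <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, "."))
    out <- as.list(vals[sel])
    names(out) <- sub(paste0("^", prefix, "\\."), "", keys[sel])
    out
  }
  margins <- pick("margins")
  coef <- pick("coef")
  # re-fold category vectors
  fold <- function(lst, stem) {
    sel <- startsWith(names(lst), paste0(stem, "."))
    if (!any(sel)) return(lst)
    v <- unlist(lst[sel])
    names(v) <- sub(paste0("^", stem, "\\."), "", names(lst)[sel])
    lst <- lst[!sel]
    lst[[stem]] <- v
    lst
  }
  margins <- fold(fold(margins, "ethnicity"), "housing")
  generator_params(
    n_subjects = vals[["n_subjects"]], seed = vals[["seed"]],
    margins = margins, coef = coef,
    miss_rate = vals[["miss_rate"]], miss_baseline = vals[["miss_baseline"]]
  )
}
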