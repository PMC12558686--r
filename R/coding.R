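# Operationalization: dichotomization rules for exposure, mediator and
# outcome, baseline eligibility screening, and attaching coded columns to a
# cohort table.

#' Dichotomization rules for exposure, mediator and outcome
#'
#' @param exposure_rule `"strict"` (primary): only subjects able to chew
#'   the toughest food group (group 1) count as having no chewing
#'   disability. `"lenient"` (sensitivity): groups 1 and 2 both count as
#'   no disability.
#' @param mediator_threshold TILS score at or above which a subject is
#'   coded lonely; 1 (any loneliness, primary) or 4 ("mostly lonely",
#'   sensitivity). Any integer in 0..12 is accepted.
#' @param outcome_threshold CES-D score defining clinically significant
#'   depressive symptoms (CSDS); default 7. Integer in 0..22.
#' @param mode `"binary"` (primary; dichotomized mediator and outcome,
#'   baseline-CSDS subjects excluded) or `"continuous"` (sensitivity;
#'   CES-D and TILS analyzed as scores, no baseline-outcome exclusion).
#' @return An object of class `coding_rules`.
#' @export
#' @examples
#' coding_rules()                                   # primary analysis
#' coding_rules(exposure_rule = "lenient")          # broader no-disability
#' coding_rules(mediator_threshold = 4)             # "mostly lonely"
coding_rules <- function(exposure_rule = c("strict", "lenient"),
                         mediator_threshold = 1L,
                         outcome_threshold = 7L,
                         mode = c("binary", "continuous")) {
  exposure_rule <- match.arg(exposure_rule)
  mode <- match.arg(mode)
  if (!is.numeric(mediator_threshold) || mediator_threshold != round(mediator_threshold) ||
      mediator_threshold < 0 || mediator_threshold > 12) {
    stop_field("mediator_threshold", "must be an integer in 0..12 (TILS range)")
  }
  if (!is.numeric(outcome_threshold) || outcome_threshold != round(outcome_threshold) ||
      outcome_threshold < 0 || outcome_threshold > 22) {
    stop_field("outcome_threshold", "must be an integer in 0..22 (CES-D range)")
  }
  structure(
    list(exposure_rule = exposure_rule,
         mediator_threshold = as.integer(mediator_threshold),
         outcome_threshold = as.integer(outcome_threshold),
         mode = mode),
    class = "coding_rules"
  )
}

#' @export
print.coding_rules <- function(x, ...) {
  cat(sprintf("Coding rules: exposure %s, mediator TILS >= %d, outcome CES-D >= %d, mode %s\n",
              x$exposure_rule, x$mediator_threshold, x$outcome_threshold, x$mode))
  invisible(x)
}

#' Code chewing disability from the ordinal food-toughness group
#'
#' Group 1 denotes ability to chew the toughest foods. Under the strict
#' (primary) rule only group 1 counts as no disability; under the lenient
#' rule groups 1 and 2 do.
#'
#' @param chew_group integer vector in 1..6 (NA allowed, passed through).
#' @param rule `"strict"` or `"lenient"`.
#' @return Integer 0/1 vector: 1 = chewing disability.
#' @export
#' @examples
#' code_exposure(c(1, 2, 6), "strict")   # 0 1 1
#' code_exposure(c(1, 2, 6), "lenient")  # 0 0 1
code_exposure <- function(chew_group, rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  bad <- !is.na(chew_group) & !(chew_group %in% 1:6)
  if (any(bad)) {
    stop(sprintf("chewing group out of range 1..6 at position %d (value %s)",
                 which(bad)[1], format(chew_group[which(bad)[1]])), call. = FALSE)
  }
  cut <- if (rule == "strict") 1L else 2L
  as.integer(chew_group > cut)
}

#' Code loneliness from the TILS score
#'
#' @param tils integer vector in 0..12 (NA allowed).
#' @param threshold score at or above which a subject is coded lonely.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' code_mediator(0:4, threshold = 1)  # 0 1 1 1 1
#' code_mediator(0:4, threshold = 4)  # 0 0 0 0 1
code_mediator <- function(tils, threshold = 1L) {
  bad <- !is.na(tils) & !(tils %in% 0:12)
  if (any(bad)) {
    stop(sprintf("TILS score out of range 0..12 at position %d (value %s)",
                 which(bad)[1], format(tils[which(bad)[1]])), call. = FALSE)
  }
  as.integer(tils >= threshold)
}

#' Code clinically significant depressive symptoms from the CES-D score
#'
#' @param cesd integer vector in 0..22 (NA allowed).
#' @param threshold score at or above which a subject is coded positive.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' code_outcome(c(6, 7, 22), threshold = 7)  # 0 1 1
code_outcome <- function(cesd, threshold = 7L) {
  bad <- !is.na(cesd) & !(cesd %in% 0:22)
  if (any(bad)) {
    stop(sprintf("CES-D score out of range 0..22 at position %d (value %s)",
                 which(bad)[1], format(cesd[which(bad)[1]])), call. = FALSE)
  }
  as.integer(cesd >= threshold)
}

#' Apply baseline eligibility screening
#'
#' In binary mode, drops subjects positive for the outcome at baseline
#' (CES-D at or above the outcome threshold), subjects with missing
#' baseline outcome-screening score, and subjects with missing baseline
#' exposure — all before any imputation. In continuous mode only
#' missing-baseline-exposure subjects are dropped, so subjects with
#' early-onset or preexisting depressive symptoms stay in the analysis.
#' Exclusion counts are attached so attrition is auditable.
#'
#' @param cohort an `msm_cohort` (or compatible data.frame with
#'   `cesd_1` and `chew_group_1` columns).
#' @param rules a [coding_rules()] object.
#' @return The filtered cohort with an `attr(, "eligibility")` list:
#'   `n_input`, `excluded_baseline_csds`, `excluded_missing_baseline_outcome`,
#'   `excluded_missing_baseline_exposure`, `n_retained`.
#' @export
apply_eligibility <- function(cohort, rules = coding_rules()) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("cesd_1", "chew_group_1") %in% names(cohort))) {
    stop("cohort must have baseline `cesd_1` and `chew_group_1` columns", call. = FALSE)
  }
  n0 <- nrow(cohort)
  miss_x <- is.na(cohort$chew_group_1)
  if (rules$mode == "binary") {
    miss_y <- is.na(cohort$cesd_1)
    base_pos <- !miss_y & cohort$cesd_1 >= rules$outcome_threshold
    drop <- miss_x | miss_y | base_pos
    counts <- list(
      n_input = n0,
      excluded_baseline_csds = sum(base_pos & !miss_x),
      excluded_missing_baseline_outcome = sum(miss_y & !miss_x),
      excluded_missing_baseline_exposure = sum(miss_x),
      n_retained = sum(!drop)
    )
  } else {
    drop <- miss_x
    counts <- list(
      n_input = n0,
      excluded_baseline_csds = 0L,
      excluded_missing_baseline_outcome = 0L,
      excluded_missing_baseline_exposure = sum(miss_x),
      n_retained = sum(!drop)
    )
  }
  if (!any(!drop)) stop("no subjects remain after eligibility screening", call. = FALSE)
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eligibility") <- counts
  attr(out, "params") <- attr(cohort, "params")
  class(out) <- unique(c("msm_cohort", class(out)))
  out
}

#' Attach coded analysis columns to a cohort
#'
#' Adds the binary exposure (`x_1`, `x_2`), mediator (`m_1`, `m_2`) and
#' wave-3 outcome (`y_bin`) columns implied by a set of coding rules.
#' Continuous analyses use the raw `cesd_3` and `tils_*` columns
#' alongside the same exposure coding.
#'
#' @param cohort an `msm_cohort`.
#' @param rules a [coding_rules()] object.
#' @return The cohort with coded columns appended and the rules attached
#'   as `attr(, "rules")`.
#' @export
code_cohort <- function(cohort, rules = coding_rules()) {
  cohort$x_1 <- code_exposure(cohort$chew_group_1, rules$exposure_rule)
  cohort$x_2 <- code_exposure(cohort$chew_group_2, rules$exposure_rule)
  cohort$m_1 <- code_mediator(cohort$tils_1, rules$mediator_threshold)
  cohort$m_2 <- code_mediator(cohort$tils_2, rules$mediator_threshold)
  cohort$y_bin <- code_outcome(cohort$cesd_3, rules$outcome_threshold)
  attr(cohort, "rules") <- rules
  class(cohort) <- unique(c("msm_cohort", class(cohort)))
  cohort
}
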