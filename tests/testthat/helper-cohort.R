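# Shared fixtures: small synthetic cohorts built in code at test time.

# generator parameters without item missingness (most tests exercise the
# complete-data path; missingness is injected explicitly where tested)
clean_params <- function(n, seed, ...) {
  generator_params(n_subjects = n, seed = seed, miss_rate = 0,
                   miss_baseline = 0, ...)
}

# generate -> screen -> code in one step
make_coded <- function(n, seed, rules = coding_rules(), ...) {
  coh <- generate_cohort(clean_params(n, seed, ...))
  code_cohort(apply_eligibility(coh, rules), rules)
}

# total and direct RR estimates from one coded cohort
fit_total_direct <- function(coded, truncate = NULL, include_mediator = TRUE) {
  w <- stabilized_weights(coded, truncate = truncate,
                          include_mediator = include_mediator)
  rows <- build_analysis_rows(coded, w)
  list(total = fit_msm_binary(rows),
       direct = fit_msm_binary(rows, include_mediator = TRUE),
       weights = w, rows = rows)
}

# a tiny hand-built coded cohort for arithmetic-level tests
toy_coded <- function(x1, x2, m1, m2, y, sw = NULL) {
  n <- length(x1)
  d <- data.frame(id = seq_len(n), x_1 = x1, x_2 = x2, m_1 = m1, m_2 = m2,
                  tils_1 = m1, tils_2 = m2, y_bin = y,
                  cesd_3 = ifelse(y == 1, 10, 3), c_3 = 1L)
  if (!is.null(sw)) attr(d, "sw") <- sw
  d
}
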