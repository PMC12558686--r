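# Synthetic three-wave cohort generator and its counterfactual oracle.
#
# All stochastic structure lives in simulate_waves(): one vectorized pass in
# causal order (L_t -> X_t -> M_t -> C_{t+1}, outcome at wave 3). Uniform
# draws for the binary structural equations are kept so that true_effects()
# can replay the same subjects under interventions on the exposure (common
# random numbers), which is what makes the oracle an exact counterfactual of
# the observational cohort rather than an independent simulation.

# Fixed loadings of the scalar frailty score through which the confounder
# block acts on exposure, mediator, censoring and outcome. A linear
# combination of the measured covariates, so main-effects logistic weight
# models are correctly specified for generated data.
frailty_score <- function(female, low_education, housing, age, mobility,
                          cerebrovascular, coronary, diabetes, cancer, support) {
  0.30 * female + 0.40 * low_education + 0.25 * (housing == "hdb_1_2") +
    0.30 * (age - 70) / 10 + 0.50 * mobility +
    0.25 * cerebrovascular + 0.20 * coronary + 0.20 * diabetes + 0.15 * cancer +
    0.35 * (30 - support) / 12
}

draw_categorical <- function(u, probs) {
  findInterval(u, cumsum(probs), left.open = TRUE) + 1L
}

# Conditional distribution of the ordinal chewing group given disability
# status: group 1 = can chew the toughest foods (no disability); disabled
# subjects are spread over the five softer groups.
CHEW_GROUP_PROBS <- c(0.35, 0.25, 0.20, 0.12, 0.08)

draw_chew_group <- function(x, u) {
  grp <- rep(1L, length(x))
  grp[x == 1L] <- 1L + draw_categorical(u[x == 1L], CHEW_GROUP_PROBS)
  grp
}

# Positive part of the loneliness score (hurdle model): subjects above the
# "any loneliness" hurdle get a TILS score in 1..12 with a right tail that
# leaves roughly a quarter of them at the stricter "mostly lonely" cut (>= 4).
draw_tils <- function(m, z) {
  tils <- integer(length(m))
  pos <- m == 1L
  tils[pos] <- pmin(12L, 1L + as.integer(round(abs(z[pos])) ))
  tils
}

# One full structural pass for n subjects. RNG must already be seeded.
simulate_waves <- function(params, n) {
  mg <- params$margins
  cf <- params$coef

  # ---- time-invariant block ----
  female <- stats::rbinom(n, 1L, mg$female)
  ethnicity <- names(mg$ethnicity)[draw_categorical(stats::runif(n), mg$ethnicity)]
  low_education <- stats::rbinom(n, 1L, mg$low_education)
  housing <- names(mg$housing)[draw_categorical(stats::runif(n), mg$housing)]

  # ---- wave 1 covariates ----
  age1 <- round(stats::rnorm(n, mg$age_mean, mg$age_sd), 1)
  u_mob1 <- stats::runif(n)
  eta_mob1 <- 0.5 * (age1 - mg$age_mean) / 10
  a_mob1 <- calibrate_logit_intercept(eta_mob1, mg$mobility)
  mobility1 <- as.integer(u_mob1 < stats::plogis(a_mob1 + eta_mob1))
  cerebro1 <- stats::rbinom(n, 1L, mg$cerebrovascular)
  coronary1 <- stats::rbinom(n, 1L, mg$coronary)
  diabetes1 <- stats::rbinom(n, 1L, mg$diabetes)
  cancer1 <- stats::rbinom(n, 1L, mg$cancer)
  support1 <- clip_score(stats::rnorm(n, mg$support_mean, mg$support_sd), 0, 60)
  score1 <- frailty_score(female, low_education, housing, age1, mobility1,
                          cerebro1, coronary1, diabetes1, cancer1, support1)

  # ---- baseline depressive-symptom screen (pre-exposure covariate) ----
  eps_b <- stats::rnorm(n, 0, 2.8)
  eta_b <- 1.6 * score1
  # choose the latent location so the baseline CSDS fraction hits its target
  mu_b <- 6.5 - stats::quantile(eta_b + eps_b, 1 - mg$baseline_csds, type = 1, names = FALSE)
  cesd1 <- clip_score(mu_b + eta_b + eps_b, 0, 22)

  # ---- wave 1 exposure and mediator ----
  u_x1 <- stats::runif(n)
  eta_x1 <- cf$l_x * score1
  a_x1 <- calibrate_logit_intercept(eta_x1, mg$exposure_w1)
  x1 <- as.integer(u_x1 < stats::plogis(a_x1 + eta_x1))
  u_grp1 <- stats::runif(n)

  u_m1 <- stats::runif(n)
  eta_m1 <- cf$x_m * x1 + cf$l_m * score1
  a_m1 <- calibrate_logit_intercept(eta_m1, mg$mediator_w1)
  m1 <- as.integer(u_m1 < stats::plogis(a_m1 + eta_m1))
  z_tils1 <- stats::rnorm(n, 0, 2.2)

  u_cog <- stats::runif(n)
  eta_cog <- 0.6 * score1
  a_cog <- calibrate_logit_intercept(eta_cog, mg$cognitive_flag)
  cognitive_flag <- as.integer(u_cog < stats::plogis(a_cog + eta_cog))

  # ---- censoring into wave 2 ----
  u_c2 <- stats::runif(n)
  eta_c2 <- cf$l_c * score1 + cf$x_c * x1
  a_c2 <- calibrate_logit_intercept(eta_c2, mg$retain_w2)
  c2 <- as.integer(u_c2 < stats::plogis(a_c2 + eta_c2))

  # ---- wave 2 covariates (generated for everyone; masked later) ----
  age2 <- age1 + 2
  u_mob2 <- stats::runif(n)
  mobility2 <- as.integer(u_mob2 < stats::plogis(
    stats::qlogis(0.15) + 1.8 * mobility1 + 0.25 * (age2 - mg$age_mean) / 10))
  cerebro2 <- pmax(cerebro1, as.integer(stats::runif(n) < 0.012))
  coronary2 <- pmax(coronary1, as.integer(stats::runif(n) < 0.020))
  diabetes2 <- pmax(diabetes1, as.integer(stats::runif(n) < 0.035))
  cancer2 <- pmax(cancer1, as.integer(stats::runif(n) < 0.012))
  support2 <- clip_score(0.75 * support1 + 0.25 * mg$support_mean + stats::rnorm(n, 0, 6), 0, 60)
  score2 <- frailty_score(female, low_education, housing, age2, mobility2,
                          cerebro2, coronary2, diabetes2, cancer2, support2)

  # ---- wave 2 exposure and mediator (with mediator->exposure feedback) ----
  u_x2 <- stats::runif(n)
  a_x2 <- stats::qlogis(mg$w2_exposure_base)
  x2 <- as.integer(u_x2 < stats::plogis(a_x2 + cf$x_x * x1 + cf$m_x * m1 + cf$l_x * score2))
  u_grp2 <- stats::runif(n)

  u_m2 <- stats::runif(n)
  a_m2 <- stats::qlogis(mg$w2_mediator_base)
  m2 <- as.integer(u_m2 < stats::plogis(a_m2 + cf$x_m * x2 + cf$m_m * m1 + cf$l_m * score2))
  z_tils2 <- stats::rnorm(n, 0, 2.2)

  # ---- censoring into wave 3 (calibrated among those still observed) ----
  u_c3 <- stats::runif(n)
  eta_c3 <- cf$l_c * score2 + cf$x_c * x2
  a_c3 <- calibrate_logit_intercept(eta_c3[c2 == 1L], mg$retain_w3)
  c3 <- c2 * as.integer(u_c3 < stats::plogis(a_c3 + eta_c3))

  # ---- wave 3 covariates ----
  age3 <- age2 + 3.5
  u_mob3 <- stats::runif(n)
  mobility3 <- as.integer(u_mob3 < stats::plogis(
    stats::qlogis(0.18) + 1.8 * mobility2 + 0.25 * (age3 - mg$age_mean) / 10))
  cerebro3 <- pmax(cerebro2, as.integer(stats::runif(n) < 0.012))
  coronary3 <- pmax(coronary2, as.integer(stats::runif(n) < 0.020))
  diabetes3 <- pmax(diabetes2, as.integer(stats::runif(n) < 0.035))
  cancer3 <- pmax(cancer2, as.integer(stats::runif(n) < 0.012))
  support3 <- clip_score(0.75 * support2 + 0.25 * mg$support_mean + stats::rnorm(n, 0, 6), 0, 60)

  # ---- terminal outcome: latent CES-D score, thresholded at 7 ----
  eps_y <- stats::rnorm(n, 0, cf$outcome_sd)
  eta_y <- cf$x_y * (x1 + x2) / 2 + cf$m_y * (m1 + m2) / 2 + cf$l_y * score2
  mu_y <- 6.5 - stats::quantile(eta_y + eps_y, 1 - mg$outcome_w3, type = 1, names = FALSE)
  cesd3 <- clip_score(mu_y + eta_y + eps_y, 0, 22)

  list(
    female = female, ethnicity = ethnicity, low_education = low_education,
    housing = housing, cognitive_flag = cognitive_flag,
    age1 = age1, age2 = age2, age3 = age3,
    mobility1 = mobility1, mobility2 = mobility2, mobility3 = mobility3,
    cerebro1 = cerebro1, cerebro2 = cerebro2, cerebro3 = cerebro3,
    coronary1 = coronary1, coronary2 = coronary2, coronary3 = coronary3,
    diabetes1 = diabetes1, diabetes2 = diabetes2, diabetes3 = diabetes3,
    cancer1 = cancer1, cancer2 = cancer2, cancer3 = cancer3,
    support1 = support1, support2 = support2, support3 = support3,
    score1 = score1, score2 = score2,
    x1 = x1, x2 = x2, m1 = m1, m2 = m2, c2 = c2, c3 = c3,
    u_grp1 = u_grp1, u_grp2 = u_grp2, z_tils1 = z_tils1, z_tils2 = z_tils2,
    u_m1 = u_m1, u_m2 = u_m2, eps_y = eps_y,
    cesd1 = cesd1, cesd3 = cesd3,
    intercepts = list(a_m1 = a_m1, a_m2 = a_m2, mu_y = mu_y)
  )
}

#' Generate a synthetic three-wave cohort
#'
#' Simulates a long-followed cohort of older adults with a time-varying
#' ordinal chewing-ability exposure (six food-toughness groups), a
#' time-varying loneliness mediator (TILS score, 0–12), informative
#' monotone dropout, and a terminal depressive-symptom outcome (CES-D
#' score 0–22, clinically significant at 7 or above). Within each wave
#' variables are generated in causal order (covariates, then exposure,
#' then mediator, then next-wave censoring); the outcome is generated at
#' wave 3 only. Identical parameters and seed always give an identical
#' table.
#'
#' @param params a [generator_params()] object.
#' @return A wide `data.frame` of class `msm_cohort`, one row per
#'   subject, with time-invariant covariates, per-wave covariate columns
#'   (`_1`, `_2`, `_3`), `chew_group_1/2`, `tils_1/2`, the baseline
#'   screening score `cesd_1`, censoring indicators `c_2`, `c_3` (1 =
#'   observed at that wave), and the wave-3 outcome score `cesd_3`.
#'   Columns measured at a wave the subject did not attend are `NA`;
#'   additional item-level missingness follows `params$miss_rate`. The
#'   parameters used are attached as `attr(, "params")`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_params(n_subjects = 300, seed = 1))
#' mean(coh$c_3)                       # fraction followed through wave 3
#' table(coh$chew_group_1, useNA = "ifany")
generate_cohort <- function(params) {
  validate_generator_params(params)
  n <- as.integer(params$n_subjects)
  set.seed(params$seed)
  s <- simulate_waves(params, n)

  chew1 <- draw_chew_group(s$x1, s$u_grp1)
  chew2 <- draw_chew_group(s$x2, s$u_grp2)
  tils1 <- draw_tils(s$m1, s$z_tils1)
  tils2 <- draw_tils(s$m2, s$z_tils2)

  d <- data.frame(
    id = seq_len(n),
    female = s$female, ethnicity = s$ethnicity,
    low_education = s$low_education, housing = s$housing,
    cognitive_flag = s$cognitive_flag,
    age_1 = s$age1, age_2 = s$age2, age_3 = s$age3,
    mobility_1 = s$mobility1, mobility_2 = s$mobility2, mobility_3 = s$mobility3,
    cerebrovascular_1 = s$cerebro1, cerebrovascular_2 = s$cerebro2, cerebrovascular_3 = s$cerebro3,
    coronary_1 = s$coronary1, coronary_2 = s$coronary2, coronary_3 = s$coronary3,
    diabetes_1 = s$diabetes1, diabetes_2 = s$diabetes2, diabetes_3 = s$diabetes3,
    cancer_1 = s$cancer1, cancer_2 = s$cancer2, cancer_3 = s$cancer3,
    support_1 = s$support1, support_2 = s$support2, support_3 = s$support3,
    chew_group_1 = chew1, chew_group_2 = chew2,
    tils_1 = tils1, tils_2 = tils2,
    cesd_1 = s$cesd1,
    c_2 = s$c2, c_3 = s$c3,
    cesd_3 = s$cesd3,
    stringsAsFactors = FALSE
  )

  # mask measurements at waves the subject did not attend (age is derived
  # from the baseline interview date, so it stays known)
  w2_cols <- c("mobility_2", "cerebrovascular_2", "coronary_2", "diabetes_2",
               "cancer_2", "support_2", "chew_group_2", "tils_2")
  w3_cols <- c("mobility_3", "cerebrovascular_3", "coronary_3", "diabetes_3",
               "cancer_3", "support_3", "cesd_3")
  d[d$c_2 == 0L, w2_cols] <- NA
  d[d$c_3 == 0L, w3_cols] <- NA

  # MCAR item missingness among attended waves
  inject <- function(col, rate, observed) {
    hit <- observed & (stats::runif(n) < rate)
    d[[col]][hit] <<- NA
    invisible(NULL)
  }
  obs2 <- d$c_2 == 1L
  inject("mobility_1", params$miss_rate, TRUE)
  inject("support_1", params$miss_rate, TRUE)
  inject("tils_1", params$miss_rate, TRUE)
  inject("mobility_2", params$miss_rate, obs2)
  inject("support_2", params$miss_rate, obs2)
  inject("tils_2", params$miss_rate, obs2)
  inject("chew_group_2", params$miss_rate, obs2)
  inject("chew_group_1", params$miss_baseline, TRUE)
  inject("cesd_1", params$miss_baseline, TRUE)

  structure(d, class = c("msm_cohort", "data.frame"), params = params)
}

#' Oracle marginal causal contrasts from the generator's potential outcomes
#'
#' Replays the generator's structural equations on a fresh Monte-Carlo
#' population under interventions, with censoring removed and common
#' random numbers across arms: always exposed at both waves, never
#' exposed, and (for the direct contrast) always exposed with the
#' mediator path held at its natural never-exposed value — a randomized-
#' interventional analogue of the natural direct effect. The resulting
#' risk ratios are the estimands the weighted marginal structural models
#' target, so they serve as ground truth for validating the pipeline.
#'
#' Risks are computed in the study-eligible population (baseline
#' depressive-symptom score below `eligibility_threshold`, a pre-exposure
#' covariate), matching the population the fitted models analyze.
#'
#' @param params a [generator_params()] object.
#' @param n_mc counterfactual population size (at least 1000).
#' @param seed seed for the Monte-Carlo population (independent of
#'   `params$seed`).
#' @param eligibility_threshold baseline CES-D score at or above which a
#'   subject is excluded (default 7, the primary coding rule); `NULL`
#'   for the whole population.
#' @return A list of class `true_effects`: `true_total_rr`,
#'   `true_direct_rr`, the three arm risks, delta-method Monte-Carlo
#'   standard errors `mc_se_total` / `mc_se_direct`, and `n_mc` (the
#'   eligible population size).
#' @export
#' @examples
#' te <- true_effects(generator_params(), n_mc = 20000, seed = 42)
#' te$true_total_rr
true_effects <- function(params, n_mc = 1e5, seed = 1L, eligibility_threshold = 7) {
  validate_generator_params(params)
  if (n_mc < 1000) stop("`n_mc` must be at least 1000", call. = FALSE)
  n <- as.integer(n_mc)
  set.seed(as.integer(seed))
  s <- simulate_waves(params, n)
  cf <- params$coef
  ic <- s$intercepts
  elig <- if (is.null(eligibility_threshold)) rep(TRUE, n) else
    s$cesd1 < eligibility_threshold
  n_elig <- sum(elig)

  m_path <- function(x) {
    m1 <- as.integer(s$u_m1 < stats::plogis(ic$a_m1 + cf$x_m * x + cf$l_m * s$score1))
    m2 <- as.integer(s$u_m2 < stats::plogis(
      stats::qlogis(params$margins$w2_mediator_base) +
        cf$x_m * x + cf$m_m * m1 + cf$l_m * s$score2))
    cbind(m1, m2)
  }
  outcome_risk <- function(x, m) {
    lat <- ic$mu_y + cf$x_y * x + cf$m_y * (m[, 1] + m[, 2]) / 2 +
      cf$l_y * s$score2 + s$eps_y
    mean(lat[elig] >= 6.5)
  }

  m0 <- m_path(0L)
  m1 <- m_path(1L)
  p0 <- outcome_risk(0, m0)
  p1 <- outcome_risk(1, m1)
  pd <- outcome_risk(1, m0)  # exposed, mediator held at never-exposed path
  if (p0 <= 0) {
    stop("degenerate estimand: zero outcome risk in the never-exposed arm", call. = FALSE)
  }
  se_log <- function(pa) sqrt((1 - pa) / (n_elig * pa) + (1 - p0) / (n_elig * p0))
  structure(
    list(
      true_total_rr = p1 / p0,
      true_direct_rr = pd / p0,
      risk_never = p0, risk_always = p1, risk_direct = pd,
      mc_se_total = (p1 / p0) * se_log(p1),
      mc_se_direct = (pd / p0) * se_log(pd),
      n_mc = n_elig, seed = as.integer(seed)
    ),
    class = "true_effects"
  )
}

#' @export
print.true_effects <- function(x, ...) {
  cat("Oracle counterfactual contrasts (n_mc =", x$n_mc, ")\n")
  cat(sprintf("  true total RR:  %.4f (MC SE %.4f)\n", x$true_total_rr, x$mc_se_total))
  cat(sprintf("  true direct RR: %.4f (MC SE %.4f)\n", x$true_direct_rr, x$mc_se_direct))
  cat(sprintf("  arm risks: never %.4f, always %.4f, direct %.4f\n",
              x$risk_never, x$risk_always, x$risk_direct))
  invisible(x)
}

#' @export
print.msm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic three-wave cohort: %d subjects\n", nrow(x)))
  cat(sprintf("  observed at wave 2: %d; through wave 3: %d\n",
              sum(x$c_2), sum(x$c_3)))
  cat(sprintf("  wave-1 chewing disability (group > 1): %.1f%%; loneliness (TILS >= 1): %.1f%%\n",
              100 * mean(x$chew_group_1 > 1, na.rm = TRUE),
              100 * mean(x$tils_1 >= 1, na.rm = TRUE)))
  cat(sprintf("  %d columns (see the data dictionary in inst/extdata)\n", ncol(x)))
  invisible(x)
}
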