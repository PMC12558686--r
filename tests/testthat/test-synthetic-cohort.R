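# Synthetic cohort generator: determinism, marginal calibration, score
# ranges, censoring structure, and the counterfactual oracle.

test_that("identical parameters and seed give byte-identical tables", {
  p <- generator_params(n_subjects = 400, seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_cohort(generator_params(n_subjects = 400, seed = 8))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("null structural coefficients reproduce the margin targets", {
  null_coef <- list(l_x = 0, x_x = 0, m_x = 0, l_m = 0, x_m = 0, m_m = 0,
                    l_c = 0, x_c = 0, x_y = 0, m_y = 0, l_y = 0)
  p <- clean_params(10000, 3, coef = null_coef,
                    margins = list(exposure_w1 = 0.5))
  coh <- generate_cohort(p)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(coh$chew_group_1 > 1) - 0.5), 3 * se)
})

test_that("wave-1 margins are calibrated to the target profile at n = 20000", {
  coh <- generate_cohort(clean_params(20000, 5))
  se <- function(p) sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(coh$female) - 0.535), 3 * se(0.535))
  expect_lt(abs(mean(coh$tils_1 >= 1) - 0.417), 3 * se(0.417))
  expect_lt(abs(mean(coh$chew_group_1 > 1) - 0.168), 3 * se(0.168))
  expect_lt(abs(mean(coh$cesd_1 >= 7) - 0.162), 3 * se(0.162))
})

test_that("generated tables satisfy the structural invariants", {
  coh <- generate_cohort(generator_params(n_subjects = 3000, seed = 11))
  # monotone censoring, exhaustively
  expect_true(all(coh$c_3 <= coh$c_2))
  expect_true(all(coh$c_2 %in% 0:1) && all(coh$c_3 %in% 0:1))
  # score ranges
  expect_true(all(coh$tils_1 %in% 0:12 | is.na(coh$tils_1)))
  expect_true(all(coh$tils_2 %in% 0:12 | is.na(coh$tils_2)))
  expect_true(all(coh$cesd_1 %in% 0:22 | is.na(coh$cesd_1)))
  expect_true(all(coh$cesd_3 %in% 0:22 | is.na(coh$cesd_3)))
  for (w in 1:3) {
    s <- coh[[paste0("support_", w)]]
    expect_true(all(s >= 0 & s <= 60, na.rm = TRUE))
  }
  expect_true(all(coh$chew_group_1 %in% 1:6 | is.na(coh$chew_group_1)))
  # wave-2/3 measurements are missing for subjects not observed there
  expect_true(all(is.na(coh$chew_group_2[coh$c_2 == 0])))
  expect_true(all(is.na(coh$cesd_3[coh$c_3 == 0])))
  # exposure/mediator columns exist at waves 1-2 only, outcome at wave 3 only
  expect_false(any(c("chew_group_3", "tils_3", "cesd_2") %in% names(coh)))
})

test_that("wave-3 parameters do not reach back into earlier waves", {
  base <- clean_params(800, 13)
  alt <- clean_params(800, 13, coef = list(x_y = 2.5, m_y = 0.1),
                      margins = list(outcome_w3 = 0.3))
  a <- generate_cohort(base)
  b <- generate_cohort(alt)
  w12 <- setdiff(names(a), c("cesd_3", grep("_3$", names(a), value = TRUE)))
  expect_identical(a[w12], b[w12])
})

test_that("invalid parameters fail naming the offending field", {
  expect_error(generator_params(margins = list(exposure_w1 = 1.2)),
               "margins\\$exposure_w1")
  expect_error(generator_params(coef = list(x_y = Inf)), "coef\\$x_y")
  expect_error(generator_params(n_subjects = 0), "n_subjects")
  expect_error(generator_params(margins = list(nonsense = 0.5)), "nonsense")
})

test_that("oracle contrasts are null when the exposure has no effect", {
  p <- clean_params(1000, 1, coef = list(x_y = 0, x_m = 0))
  te <- true_effects(p, n_mc = 60000, seed = 2)
  expect_lt(abs(te$true_total_rr - 1), 3 * te$mc_se_total)
})

test_that("a purely mediated effect shows in the total but not the direct contrast", {
  p <- clean_params(1000, 1, coef = list(x_y = 0, x_m = 0.8, m_y = 1.5))
  te <- true_effects(p, n_mc = 80000, seed = 3)
  expect_gt(te$true_total_rr, 1 + 3 * te$mc_se_total)
  expect_lt(abs(te$true_direct_rr - 1), 3 * te$mc_se_direct)
})

test_that("the oracle total effect is monotone in the direct-effect coefficient", {
  rrs <- vapply(c(0, 0.4, 0.8, 1.2), function(b) {
    true_effects(clean_params(1000, 1, coef = list(x_y = b)),
                 n_mc = 120000, seed = 4)$true_total_rr
  }, numeric(1))
  expect_true(all(diff(rrs) > 0))
})

test_that("Monte-Carlo standard errors shrink at the root-n rate", {
  p <- clean_params(1000, 1)
  a <- true_effects(p, n_mc = 20000, seed = 5)
  b <- true_effects(p, n_mc = 80000, seed = 5)
  # quadrupling the population should halve the SE
  expect_lt(abs(b$mc_se_total / a$mc_se_total - 0.5), 0.2 * 0.5)
  expect_error(true_effects(p, n_mc = 100, seed = 1), "at least 1000")
})
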