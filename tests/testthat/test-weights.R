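# Stabilized weighting engine: stabilization identity, component
# arithmetic, combination, truncation, and diagnostics.

# hand-built fits object for arithmetic-level tests
fake_fit <- function(target, wave, ids, response, p_num, p_den) {
  spec <- weight_model_spec(target, wave, response = "x",
                            numerator = character(0), denominator = character(0))
  list(spec = spec, ids = ids, response = response, p_num = p_num, p_den = p_den)
}

test_that("numerator = denominator specification gives weights of exactly 1", {
  coded <- make_coded(1500, 23)
  specs <- default_weight_specs()
  ident <- lapply(specs, function(sp) {
    sp$numerator <- sp$denominator  # same model on both sides
    sp
  })
  fits <- fit_weight_models(coded, ident)
  w <- compute_component_weights(fits, coded)
  comp <- as.matrix(w[grep("^sw_", names(w))])
  expect_true(all(abs(comp[!is.na(comp)] - 1) < 1e-12))
  wt <- combine_weights(w)
  expect_true(all(abs(wt$sw_total[!is.na(wt$sw_total)] - 1) < 1e-10))
})

test_that("a component is the ratio of observed-level probabilities", {
  cohort <- data.frame(id = 1:2, c_2 = 1L, c_3 = 1L)
  fits <- list(fake_fit("exposure", 1, ids = 1:2, response = c(1L, 0L),
                        p_num = c(0.8, 0.8), p_den = c(0.5, 0.5)))
  w <- compute_component_weights(fits, cohort)
  expect_equal(w$sw_x_1, c(0.8 / 0.5, 0.2 / 0.5))
})

test_that("zero denominator probability raises a positivity error, not a clip", {
  cohort <- data.frame(id = 1, c_2 = 1L, c_3 = 1L)
  fits <- list(fake_fit("exposure", 1, ids = 1, response = 1L,
                        p_num = 0.5, p_den = 0))
  expect_error(compute_component_weights(fits, cohort), "positivity")
})

test_that("combination is the exact product of the stored components", {
  w <- data.frame(id = 1, c_2 = 1L, c_3 = 1L,
                  sw_x_1 = 1.2, sw_x_2 = 0.9, sw_m_1 = 1.1, sw_m_2 = 1.0,
                  sw_c_2 = 1.0, sw_c_3 = 1.25)
  class(w) <- c("stabilized_weights", "data.frame")
  expect_equal(combine_weights(w)$sw_total, 1.485)
  # six unit components give exactly 1
  w1 <- w; w1[grep("^sw_", names(w1))] <- 1
  expect_equal(combine_weights(w1)$sw_total, 1)
  # censored subject missing a component is a consistency error
  w2 <- w; w2$sw_m_2 <- NA
  expect_error(combine_weights(w2), "missing weight component")
})

test_that("total- and direct-model weights differ by exactly the mediator product", {
  coded <- make_coded(2000, 29)
  fits <- fit_weight_models(coded)
  comp <- compute_component_weights(fits, coded)
  w_all <- combine_weights(comp, include_mediator = TRUE)
  w_xc <- combine_weights(comp, include_mediator = FALSE)
  ok <- !is.na(w_all$sw_total)
  med_prod <- comp$sw_m_1 * comp$sw_m_2
  expect_equal(w_all$sw_total[ok] / w_xc$sw_total[ok], med_prod[ok],
               tolerance = 1e-12)
  # recomputing the full product from stored components matches sw_total
  full <- comp$sw_x_1 * comp$sw_x_2 * comp$sw_m_1 * comp$sw_m_2 *
    comp$sw_c_2 * comp$sw_c_3
  expect_equal(w_all$sw_total[ok], full[ok], tolerance = 1e-12)
})

test_that("correctly specified weights are centered at 1 and components are too", {
  coded <- make_coded(5000, 31)
  fits <- fit_weight_models(coded)
  comp <- compute_component_weights(fits, coded)
  for (col in grep("^sw_", names(comp), value = TRUE)) {
    expect_lt(abs(mean(comp[[col]], na.rm = TRUE) - 1), 0.05)
  }
  w <- combine_weights(comp)
  expect_lt(abs(mean(w$sw_total, na.rm = TRUE) - 1), 0.1)
})

test_that("exposure is unconfounded when the generator says so", {
  # with the confounder->exposure arrow switched off, every covariate
  # coefficient of the wave-1 denominator model should be null
  coded <- make_coded(10000, 37, coef = list(l_x = 0))
  sp <- default_weight_specs()$x1
  fit <- glm(reformulate(sp$denominator, "x_1"), binomial(), data = coded)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  expect_true(all(abs(cf[, "Estimate"]) < 3 * cf[, "Std. Error"] + 1e-8))
})

test_that("degenerate at-risk sets raise fitting errors", {
  coded <- make_coded(300, 41)
  one <- coded[1, , drop = FALSE]
  expect_error(fit_weight_models(one, default_weight_specs()["x1"]),
               "fewer than 2")
  const <- coded
  const$x_1 <- 1L
  expect_error(fit_weight_models(const, default_weight_specs()["x1"]),
               "constant")
})

test_that("truncation caps from above and records its threshold", {
  w <- truncate_weights(rep(1, 5), upper_percentile = 0.95)
  expect_equal(w$sw_trunc, rep(1, 5))
  expect_equal(attr(w, "truncation")$threshold, 1)
  w2 <- truncate_weights(c(1, 1, 1, 1, 100), cap = 2)
  expect_equal(w2$sw_trunc, c(1, 1, 1, 1, 2))
  v <- rexp(200) + 0.1
  w3 <- truncate_weights(v, upper_percentile = 0.9)
  expect_true(all(w3$sw_trunc <= v))
  expect_lte(mean(w3$sw_trunc), mean(v))
  expect_true(all(w3$sw_trunc[v <= attr(w3, "truncation")$threshold] ==
                    v[v <= attr(w3, "truncation")$threshold]))
  expect_error(truncate_weights(c(-1, 1)), "positive")
  expect_error(truncate_weights(v, upper_percentile = 0.3), "0.5")
})

test_that("diagnostics count out-of-bounds probabilities and summarize weights", {
  cohort <- data.frame(id = 1:3, c_2 = 1L, c_3 = 1L)
  fits <- list(fake_fit("exposure", 1, ids = 1:3, response = c(1L, 1L, 1L),
                        p_num = c(0.5, 0.5, 0.5), p_den = c(0.01, 0.5, 0.97)))
  w <- combine_weights(compute_component_weights(fits, cohort),
                       include_mediator = FALSE, include_censoring = FALSE,
                       partial_ok = TRUE)
  d <- weight_diagnostics(w, fits = fits)
  expect_equal(d$positivity$frac_below, 1 / 3)
  expect_equal(d$positivity$frac_above, 1 / 3)
  expect_true(d$flagged)
  ones <- data.frame(id = 1:4, sw_total = 1)
  d1 <- weight_diagnostics(ones, fits = NULL)
  expect_equal(d1$before$mean, 1)
  expect_equal(d1$before$sd, 0)
  expect_equal(d1$before$p01, 1)
  expect_equal(d1$before$p99, 1)
})

test_that("a well-specified cohort stays below the positivity alarm", {
  coded <- make_coded(5000, 43)
  w <- stabilized_weights(coded)
  d <- weight_diagnostics(w)
  expect_false(d$flagged)
  expect_true(all(d$positivity$frac_below + d$positivity$frac_above < 0.05))
})
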