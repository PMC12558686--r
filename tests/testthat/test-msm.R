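# Weighted outcome models: cumulative coding, saturated-model equivalence
# with hand-computed risk ratios, the identity-link variant, and the
# excess-relative-risk decomposition.

test_that("cumulative coding averages (or sums) the two waves", {
  d <- toy_coded(x1 = c(1, 0, 1), x2 = c(1, 0, 1), m1 = c(0, 1, 1),
                 m2 = c(1, 1, 1), y = c(1, 0, 0))
  rows <- build_analysis_rows(d)
  expect_equal(rows$cum_x, c(1, 0, 1))
  expect_equal(rows$cum_m, c(0.5, 1, 1))
  rows_sum <- build_analysis_rows(d, coding = "sum")
  expect_equal(rows_sum$cum_x, c(2, 0, 2))
  d2 <- d; d2$x_2[1] <- NA
  expect_error(build_analysis_rows(d2), "lacks an exposure or mediator")
})

test_that("the saturated log-link fit reproduces the hand-computed risk ratio", {
  # 10 exposed with 4 events vs 10 unexposed with 2 events: RR = 2
  d <- toy_coded(x1 = rep(c(1, 0), each = 10), x2 = rep(c(1, 0), each = 10),
                 m1 = 0, m2 = 0,
                 y = c(rep(1, 4), rep(0, 6), rep(1, 2), rep(0, 8)))
  rows <- build_analysis_rows(d)
  fit <- fit_msm_binary(rows)
  expect_equal(fit$effect[["cum_x"]], 2, tolerance = 1e-8)
  # uniform within-group weights cancel from the risk ratio
  w <- ifelse(rows$cum_x == 1, 2, 1)
  fit_w <- fit_msm_binary(rows, weights = w)
  expect_equal(fit_w$effect[["cum_x"]], 2, tolerance = 1e-8)
})

test_that("weighted 2x2 tables match hand-computed weighted risk ratios", {
  set.seed(99)
  for (i in 1:5) {
    n <- 40
    cum_x <- rep(c(0, 1), each = n / 2)
    y <- rbinom(n, 1, 0.2 + 0.3 * cum_x)
    if (length(unique(y[cum_x == 0])) < 2) y[1:2] <- c(0, 1)
    if (length(unique(y[cum_x == 1])) < 2) y[n / 2 + 1:2] <- c(0, 1)
    w <- runif(n, 0.5, 3)
    rows <- data.frame(id = 1:n, cum_x = cum_x, cum_m = 0, cum_tils = 0,
                       y_bin = y, cesd_3 = y)
    fit <- fit_msm_binary(rows, weights = w)
    hand <- weighted.mean(y[cum_x == 1], w[cum_x == 1]) /
      weighted.mean(y[cum_x == 0], w[cum_x == 0])
    expect_equal(fit$effect[["cum_x"]], hand, tolerance = 1e-8)
  }
})

test_that("degenerate outcomes raise errors", {
  d <- toy_coded(x1 = c(1, 0), x2 = c(1, 0), m1 = 0, m2 = 0, y = c(1, 1))
  rows <- build_analysis_rows(d)
  expect_error(fit_msm_binary(rows), "identical|constant")
  rows$cesd_3 <- 5
  expect_error(fit_msm_continuous(rows), "constant")
})

test_that("the identity-link model recovers a noiseless linear outcome exactly", {
  rows <- data.frame(id = 1:30, cum_x = rep(c(0, 0.5, 1), 10), cum_m = 0,
                     cum_tils = 0, y_bin = 0, cesd_3 = NA)
  rows$cesd_3 <- 3 + 2 * rows$cum_x
  rows$y_bin <- as.integer(rows$cesd_3 >= 4)
  fit <- fit_msm_continuous(rows)
  expect_equal(fit$effect[["cum_x"]], 2, tolerance = 1e-10)
  # rescaling all weights leaves the coefficients unchanged
  set.seed(1)
  rows$cesd_3 <- rows$cesd_3 + rnorm(30)
  w <- runif(30, 0.5, 2)
  f1 <- fit_msm_continuous(rows, weights = w)
  f2 <- fit_msm_continuous(rows, weights = 7 * w)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
})

test_that("a zero-effect continuous model estimates a null mean difference", {
  set.seed(2)
  rows <- data.frame(id = 1:400, cum_x = rep(c(0, 1), 200), cum_m = 0,
                     cum_tils = 0, y_bin = 0, cesd_3 = rnorm(400, 5, 2))
  fit <- fit_msm_continuous(rows)
  expect_lt(abs(fit$effect[["cum_x"]]), 3 * fit$robust_se[["cum_x"]])
})

fake_msm <- function(model, rr_x, rr_m = NULL) {
  coefs <- c(`(Intercept)` = -2, cum_x = log(rr_x))
  if (!is.null(rr_m)) coefs <- c(coefs, cum_m = log(rr_m))
  structure(list(model = model, link = "log", coef = coefs,
                 robust_se = rep(0.1, length(coefs)),
                 effect = exp(coefs), ci_low = exp(coefs - 0.2),
                 ci_high = exp(coefs + 0.2), conf_level = 0.95,
                 n_effective = 100L, weights_used = "unit"),
            class = "msm_result")
}

test_that("the excess-relative-risk decomposition matches closed forms", {
  s <- decompose_effects(fake_msm("total", 1.5), fake_msm("direct", 1.5, 1.2))
  expect_equal(s$proportion_mediated, 0)
  s <- decompose_effects(fake_msm("total", 1.5), fake_msm("direct", 1.0, 1.2))
  expect_equal(s$proportion_mediated, 100)
  s <- decompose_effects(fake_msm("total", 1.48), fake_msm("direct", 1.40, 1.26))
  expect_equal(s$proportion_mediated, (1.48 - 1.40) / 0.48 * 100, tolerance = 1e-10)
  expect_equal(s$proportion_mediated, 16.6667, tolerance = 1e-4)
})

test_that("decomposition proportions always close to 100 and handle RR <= 1", {
  set.seed(3)
  for (i in 1:20) {
    tot <- runif(1, 1.01, 3)
    dir <- runif(1, 0.8, tot)
    s <- decompose_effects(fake_msm("total", tot), fake_msm("direct", dir, 1.1))
    expect_equal(s$proportion_direct + s$proportion_mediated, 100,
                 tolerance = 1e-9)
  }
  s <- decompose_effects(fake_msm("total", 0.95), fake_msm("direct", 0.9, 1.1))
  expect_false(s$proportions_defined)
  expect_true(is.na(s$proportion_mediated) && is.na(s$proportion_direct))
})

test_that("mean differences convert to approximate relative risks", {
  expect_equal(md_to_rr(0, 5), 1)
  expect_equal(md_to_rr(5, 5), exp(0.91))
  mds <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(md_to_rr(mds, 3)) > 0))
  expect_error(md_to_rr(1, 0), "positive")
})

test_that("the full pipeline attenuates the direct effect below the total", {
  coded <- make_coded(4000, 47)
  f <- fit_total_direct(coded)
  expect_gt(f$total$effect[["cum_x"]], f$direct$effect[["cum_x"]])
  s <- decompose_effects(f$total, f$direct)
  expect_true(s$proportions_defined)
  expect_equal(s$proportion_direct + s$proportion_mediated, 100)
})
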