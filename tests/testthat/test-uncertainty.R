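# E-values and the BCa bootstrap.

test_that("E-values match the closed form at two-decimal precision", {
  expect_equal(round(evalue(1.40)$evalue, 2), 2.15)
  expect_equal(round(evalue(1.29)$evalue, 2), 1.90)
  expect_equal(evalue(1)$evalue, 1)
  expect_equal(evalue(2)$evalue, 2 + sqrt(2))
})

test_that("E-values are inversion-symmetric and monotone above the null", {
  rrs <- c(0.2, 0.5, 0.8, 1.3, 2, 5)
  for (r in rrs) expect_equal(evalue(r)$evalue, evalue(1 / r)$evalue)
  up <- vapply(seq(1, 4, by = 0.25), function(r) evalue(r)$evalue, numeric(1))
  expect_true(all(diff(up) >= 0))
  expect_error(evalue(0), "positive")
  expect_error(evalue(-2), "positive")
})

test_that("the CI E-value is 1 when the interval crosses the null", {
  expect_equal(evalue(1.4, ci_limit = 0.99)$evalue_ci, 1)
  expect_gt(evalue(1.4, ci_limit = 1.05)$evalue_ci, 1)
  expect_equal(evalue(0.7, ci_limit = 1.02)$evalue_ci, 1)
})

test_that("a constant statistic yields a degenerate zero-width interval", {
  d <- data.frame(v = rnorm(30))
  b <- bca_bootstrap(d, function(dd) 3.5, B = 50, seed = 1)
  expect_equal(b$ci, c(3.5, 3.5))
  expect_equal(b$z0, 0)
  expect_equal(b$acceleration, 0)
})

test_that("BCa intervals match an independent brute-force implementation", {
  set.seed(77)
  d <- data.frame(v = rexp(150, 0.5))
  b <- bca_bootstrap(d, function(dd) mean(dd$v), B = 2000, seed = 42)
  o <- brute_force_bca(d$v, B = 2000, seed = 42)
  expect_equal(round(b$ci, 3), round(o$ci, 3))
  expect_equal(b$z0, o$z0, tolerance = 1e-10)
  expect_equal(b$acceleration, o$a, tolerance = 1e-10)
})

test_that("BCa agrees with the boot package on the same replicate set", {
  skip_if_not_installed("boot")
  set.seed(88)
  x <- rexp(120, 1)
  d <- data.frame(v = x)
  b <- bca_bootstrap(d, function(dd) mean(dd$v), B = 4000, seed = 9)
  bo <- boot::boot(x, function(z, i) mean(z[i]), R = 4000)
  ci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  # different resample streams: agreement to Monte-Carlo resolution
  expect_lt(max(abs(b$ci - ci)), 0.15 * sd(x) / sqrt(length(x)) * 4)
})

test_that("BCa reduces to the percentile interval when z0 = 0 and a = 0", {
  set.seed(5)
  d <- data.frame(v = rnorm(60))
  b <- bca_bootstrap(d, function(dd) mean(dd$v), B = 4000, seed = 3)
  perc <- quantile(b$replicates, c(0.025, 0.975), names = FALSE)
  # symmetric statistic: z0 and a are near zero, so the intervals align
  expect_lt(abs(b$z0), 0.08)
  expect_lt(max(abs(b$ci - perc)), 0.25 * sd(b$replicates))
})

test_that("failed replicates are reported and excessive failure is an error", {
  d <- data.frame(v = rnorm(30))
  make_flaky <- function(fail_every) {
    cnt <- 0
    function(dd) {
      cnt <<- cnt + 1
      if (cnt > 1 && cnt %% fail_every == 0) stop("unstable fit")
      mean(dd$v)
    }
  }
  # most replicates fail: hard error
  expect_error(bca_bootstrap(d, make_flaky(1), B = 100, seed = 1),
               "did not produce")
  # a noticeable minority fails: warning, interval still produced
  expect_warning(b <- bca_bootstrap(d, make_flaky(8), B = 100, seed = 1),
                 "failed")
  expect_true(b$n_failed > 0 && is.finite(b$ci[1]))
})

test_that("BCa intervals attain near-nominal coverage for a skewed mean", {
  hits <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    set.seed(9000 + i)
    x <- rexp(40, 1)
    b <- bca_bootstrap(data.frame(v = x), function(dd) mean(dd$v),
                       B = 399, seed = i)
    hits <- hits + (b$ci[1] <= 1 && 1 <= b$ci[2])
  }
  expect_gte(hits / reps, 0.85)
  expect_lte(hits / reps, 0.995)
})
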