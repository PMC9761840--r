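test_that("two symmetric groups determine the probit line exactly", {
  fit <- fit_probit(c(1, 10), c(100, 100), c(25, 75))
  # MLE passes through both empirical probits
  expect_equal(fit$intercept, qnorm(0.25), tolerance = 1e-6)
  expect_equal(fit$slope, qnorm(0.75) - qnorm(0.25), tolerance = 1e-6)
  el <- effective_level(fit, 0.5)
  expect_equal(el$estimate, 10^0.5, tolerance = 1e-6)
  expect_true(el$lower95 < el$estimate && el$estimate < el$upper95)
})

test_that("Fieller fiducial limits agree with a parametric bootstrap", {
  fit <- fit_probit(c(1, 10), c(100, 100), c(25, 75))
  el <- effective_level(fit, 0.5)
  # two-group probit has a closed form: resample counts, invert the line
  set.seed(42)
  B <- 10000
  d1 <- rbinom(B, 100, 0.25); d2 <- rbinom(B, 100, 0.75)
  ok <- d1 > 0 & d1 < 100 & d2 > 0 & d2 < 100
  y1 <- qnorm(d1[ok] / 100); y2 <- qnorm(d2[ok] / 100)
  boot <- quantile(10^(-y1 / (y2 - y1)), c(0.025, 0.975))
  expect_equal(el$lower95, unname(boot[1]), tolerance = 0.05)
  expect_equal(el$upper95, unname(boot[2]), tolerance = 0.05)
})

test_that("ML fit matches a grid-search likelihood oracle on simulated data", {
  set.seed(77)
  levels <- 10^seq(0.4, 1.6, length.out = 5)
  p <- pnorm(4 * (log10(levels) - 1))
  d <- rbinom(5, 1000, p)
  fit <- fit_probit(levels, rep(1000, 5), d)
  oracle <- grid_probit(levels, rep(1000, 5), d,
                        b0_range = c(-8, 0), b1_range = c(1, 8))
  expect_equal(fit$intercept, unname(oracle["b0"]), tolerance = 0.02)
  expect_equal(fit$slope, unname(oracle["b1"]), tolerance = 0.02)
  # and recovers the truth at this sample size
  expect_lt(abs(fit$slope - 4), 0.3)
  expect_lt(abs(effective_level(fit, 0.5)$estimate / 10 - 1), 0.05)
})

test_that("noise-free probit-line data are recovered to 1e-6", {
  levels <- c(0.5, 1, 2, 4, 8, 16)
  b0 <- -1.2; b1 <- 2.5
  n <- rep(1e6, length(levels))
  d <- n * pnorm(b0 + b1 * log10(levels)) # exact expected counts
  fit <- fit_probit(levels, n, d)
  expect_equal(fit$intercept, b0, tolerance = 1e-6)
  expect_equal(fit$slope, b1, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-6)
})

test_that("separation and degenerate inputs raise informative errors", {
  expect_error(fit_probit(c(1, 10), c(10, 10), c(10, 10)), "did not converge")
  expect_error(fit_probit(c(1, 10), c(10, 10), c(0, 0)), "did not converge")
  expect_error(fit_probit(c(1, 10), c(10, 10), c(0, 10)), "separation")
  expect_error(fit_probit(c(5, 5), c(10, 10), c(2, 8)), "2 distinct levels")
  fit <- fit_probit(c(1, 10), c(100, 100), c(25, 75))
  expect_error(effective_level(fit, 0), "strictly in")
  down <- fit_probit(c(1, 10), c(100, 100), c(75, 25))
  expect_error(effective_level(down, 0.5), "slope must be positive")
})

test_that("effective levels invert the line, increase in p, and obey symmetry", {
  # construct a fit with a known line: probit(p) = 1 + 4*log10(level)
  lv <- 10^seq(-1, 0.5, length.out = 6)
  n <- rep(1e6, 6)
  fit <- fit_probit(lv, n, n * pnorm(1 + 4 * log10(lv)))
  expect_equal(effective_level(fit, 0.5)$estimate, 10^(-1 / 4),
               tolerance = 1e-6)
  ps <- c(0.05, 0.15, 0.35, 0.5, 0.6, 0.9)
  est <- vapply(ps, function(p) effective_level(fit, p)$estimate, numeric(1))
  expect_true(all(diff(est) > 0))
  # relabelling dead/alive flips the line; ED50 is unchanged
  flip <- fit_probit(lv, n, n * pnorm(-(1 + 4 * log10(lv))))
  expect_error(effective_level(flip, 0.5), "positive") # slope < 0 by design
  # symmetry of the percentile grid around ED50 on the log scale
  tab <- lc_at_percents(fit, c(5, 50, 95))
  expect_equal(tab$estimate[1] * tab$estimate[3], tab$estimate[2]^2,
               tolerance = 1e-8)
  # percentile inversion equals a bisection oracle
  ed15 <- effective_level(fit, 0.15)$estimate
  expect_equal(ed15, bisect_ed(0.15, fit$intercept, fit$slope),
               tolerance = 1e-9)
})

test_that("point estimates agree with MASS::dose.p on a real-shaped dataset", {
  skip_if_not_installed("MASS")
  set.seed(5)
  lv <- c(0.25, 0.4, 0.55, 0.7, 1.0)
  d <- rbinom(5, 20, pnorm(3 * log10(lv / 0.5)))
  fit <- fit_probit(lv, rep(20, 5), d)
  g <- glm(cbind(d, 20 - d) ~ log10(lv), family = binomial("probit"))
  dp <- MASS::dose.p(g, p = 0.5)
  expect_equal(log10(effective_level(fit, 0.5)$estimate),
               unname(as.numeric(dp)), tolerance = 1e-6)
})

test_that("heterogeneity inflates the interval width when chi2/df > 1", {
  set.seed(9)
  lv <- 10^seq(-0.5, 0.5, length.out = 6)
  n <- rep(50, 6)
  # overdispersed data: mix of two shifted lines
  d <- rbinom(6, n, pnorm(2.5 * log10(lv) + rep(c(-0.6, 0.6), 3)))
  fit <- fit_probit(lv, n, d)
  expect_gt(fit$heterogeneity, 1)
  el <- effective_level(fit, 0.5)
  naive <- fit
  naive$chi2 <- 0; naive$heterogeneity <- 0
  el0 <- effective_level(naive, 0.5)
  expect_gt(log(el$upper95 / el$lower95), log(el0$upper95 / el0$lower95))
})
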