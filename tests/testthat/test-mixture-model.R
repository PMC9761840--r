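test_that("component concentrations split the total by exact ratio weights", {
  spec <- mixture_spec(c("atrazine", "chlorpyrifos"), c(33.95, 1))
  ci <- component_concentrations(spec, 8)
  expect_equal(unname(ci), 8 * c(33.95, 1) / 34.95, tolerance = 1e-12)
  expect_equal(sum(ci), 8, tolerance = 1e-12)
  expect_equal(unname(component_concentrations(
    mixture_spec("x", 3), 5)), 5)
  quat <- mixture_spec(letters[1:4], c(1.299, 0.360, 0.0132, 0.001))
  cq <- component_concentrations(quat, 8)
  expect_equal(unname(cq), 8 * c(1.299, 0.360, 0.0132, 0.001) / 1.6732,
               tolerance = 1e-12)
  expect_equal(sum(cq), 8, tolerance = 1e-9)
  expect_error(component_concentrations(spec, 0), "positive")
})

test_that("lethal-time addition is a reciprocal concentration-weighted sum", {
  expect_equal(lethal_time_addition(1, 100), 100)
  ci <- c(3.885551, 0.114449); lt <- c(13034, 7069)
  expect_equal(lethal_time_addition(ci, lt), 1 / sum(ci / lt))
  # permutation invariance
  expect_equal(lethal_time_addition(rev(ci), rev(lt)),
               lethal_time_addition(ci, lt))
  expect_error(lethal_time_addition(numeric(0), numeric(0)), "at least one")
  expect_error(lethal_time_addition(c(1, 2), c(100, 0)), "positive")
})

test_that("lethal-time addition is bounded by min(LTi/Ci) and decreases as components are added", {
  set.seed(21)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    ci <- runif(k, 0.01, 20)
    lt <- runif(k, 1, 5000)
    mix <- lethal_time_addition(ci, lt)
    expect_lte(mix, min(lt / ci))
    # adding any extra component strictly decreases the mixture LT50
    extra_c <- runif(1, 0.01, 20); extra_lt <- runif(1, 1, 5000)
    expect_lt(lethal_time_addition(c(ci, extra_c), c(lt, extra_lt)), mix)
  }
})

test_that("hyperbolic mortality has the Michaelis-Menten shape", {
  expect_equal(hyperbolic_mortality(0, 156.62), 0)
  expect_identical(hyperbolic_mortality(156.62, 156.62), 50)
  expect_equal(hyperbolic_mortality(96, 156.62), 100 * 96 / 252.62)
  expect_equal(round_half_up(hyperbolic_mortality(96, 156.62)), 38)
  t <- seq(0, 500, by = 10)
  p <- hyperbolic_mortality(t, 80)
  expect_true(all(diff(p) > 0))
  expect_true(all(p < 100))
  expect_equal(hyperbolic_mortality(40, 80, p100 = 60), 20) # ceiling scales
  expect_error(hyperbolic_mortality(-1, 80), "domain")
})

test_that("the mixture prediction curve reproduces the published catfish series", {
  pred <- cs_prediction("catfish", "atrazine-chlorpyrifos",
                        c(4, 8, 12, 16, 20))
  expect_equal(pred$lt50$lt50_mix, c(3181.6, 156.62, 26.88, 7.70, 2.92),
               tolerance = 0.002)
  expect_true(all(diff(pred$lt50$lt50_mix) < 0)) # monotone in total conc
  # time-resolved mortality at 8 mg/L rounds to the published integers
  m8 <- pred$mortality[pred$mortality$total == 8, ]
  expect_equal(round_half_up(m8$percent), c(13, 23, 31, 38))
})

test_that("predicted LC50 by probit and by inversion agree on symmetric series", {
  # single-component spec makes LT50mix(C) log-linear, so choosing totals
  # geometric around C* (where LT50mix = 96) gives probit-symmetric
  # mortalities and both extraction methods must return C* exactly
  a <- 8; b <- -1.5
  cstar <- exp((log(96) - a) / (b - 1)) # LT(C)/C = 96
  spec <- mixture_spec("solo", 1)
  coeffs <- list(solo = ltc_regression(a, b))
  totals <- cstar * 2^seq(-2, 2)
  pred <- predict_mixture_lt50_curve(spec, coeffs, totals)
  expect_equal(hm_predicted_lc50(pred, method = "invert")$estimate, cstar,
               tolerance = 1e-6)
  expect_equal(hm_predicted_lc50(pred, method = "probit")$estimate, cstar,
               tolerance = 1e-6)
})

test_that("probit and root-solve mixture LC50s agree on the case study", {
  pred <- cs_prediction("catfish", "atrazine-chlorpyrifos",
                        c(4, 8, 12, 16, 20))
  lc_probit <- hm_predicted_lc50(pred, t = 96, method = "probit")$estimate
  lc_invert <- hm_predicted_lc50(pred, t = 96, method = "invert")$estimate
  expect_lt(abs(lc_probit / lc_invert - 1), 0.15)
})

test_that("mixture prediction validates its inputs", {
  spec <- mixture_spec(c("a", "b"), c(1, 1))
  coeffs <- list(a = ltc_regression(5, -2))
  expect_error(predict_mixture_lt50_curve(spec, coeffs, 4), "coefficients")
  coeffs$b <- ltc_regression(4, -1.5)
  expect_error(predict_mixture_lt50_curve(spec, coeffs, -4), "positive")
  pred <- predict_mixture_lt50_curve(spec, coeffs, c(1, 2))
  expect_s3_class(pred, "mixture_prediction")
  expect_named(pred$lt50,
               c("total", "conc_a", "conc_b", "lt50_a", "lt50_b", "lt50_mix"))
})
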