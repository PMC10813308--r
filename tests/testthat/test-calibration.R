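make_4pl_curve <- function(lower = 0.55, upper = 0.999, midpoint = 80,
                           s = 1.6, conc = c(1, 5, 10, 20, 30, 50, 100, 500, 1000),
                           noise_sd = 0, seed = 1) {
  z <- lower + (upper - lower) /
    (1 + exp(s * (log10(conc) - log10(midpoint))))
  if (noise_sd > 0) {
    set.seed(seed)
    z <- z + rnorm(length(z), 0, noise_sd)
  }
  structure(
    data.frame(concentration_ng_per_ml = conc, mean_zncc = z,
               sd_zncc = noise_sd, n = 10),
    class = c("correlation_curve", "data.frame")
  )
}

test_that("noise-free 4PL parameters are recovered to 1e-6", {
  curve <- make_4pl_curve()
  fit <- fit_logistic(curve)
  expect_equal(fit$lower_asymptote, 0.55, tolerance = 1e-6)
  expect_equal(fit$upper_asymptote, 0.999, tolerance = 1e-6)
  expect_equal(fit$midpoint, 80, tolerance = 1e-6)
  expect_equal(fit$slope_factor, 1.6, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("a flat curve is flagged degenerate", {
  curve <- make_4pl_curve()
  curve$mean_zncc <- rep(0.8, nrow(curve))
  expect_error(fit_logistic(curve), "fit-failure")
})

test_that("too few points is an insufficient-data error", {
  curve <- make_4pl_curve(conc = c(1, 10, 100))
  expect_error(fit_logistic(curve), "insufficient-data")
})

test_that("the fitted logistic is monotone over the data span", {
  curve <- make_4pl_curve(noise_sd = 0.005)
  fit <- fit_logistic(curve)
  grid <- 10^seq(0, 3, length.out = 200)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("an exact line is recovered with |slope| 0.0012", {
  conc <- c(1, 5, 10, 20, 30, 50)
  curve <- structure(
    data.frame(concentration_ng_per_ml = conc,
               mean_zncc = 1 - 0.0012 * conc, sd_zncc = 0, n = 10),
    class = c("correlation_curve", "data.frame"))
  fit <- fit_linear_sensitivity(curve)
  expect_equal(fit$sensitivity, 0.0012, tolerance = 1e-14)
  expect_equal(fit$slope, -0.0012, tolerance = 1e-14)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("two points define the line exactly with r-squared one", {
  curve <- structure(
    data.frame(concentration_ng_per_ml = c(5, 40),
               mean_zncc = c(0.99, 0.95), sd_zncc = 0, n = 1),
    class = c("correlation_curve", "data.frame"))
  fit <- fit_linear_sensitivity(curve)
  expect_equal(fit$slope, (0.95 - 0.99) / 35, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_linear_sensitivity(curve, c_min = 1, c_max = 4),
               "insufficient-data")
})

test_that("the sensitivity estimator is unbiased under additive noise", {
  conc <- c(1, 5, 10, 20, 30, 50)
  true_slope <- -0.0012
  sigma <- 0.002
  est <- replicate(300, {
    z <- 1 + true_slope * conc + rnorm(length(conc), 0, sigma)
    curve <- structure(
      data.frame(concentration_ng_per_ml = conc, mean_zncc = z,
                 sd_zncc = sigma, n = 1),
      class = c("correlation_curve", "data.frame"))
    fit_linear_sensitivity(curve)$sensitivity
  })
  se_slope <- sigma / sqrt(sum((conc - mean(conc))^2))
  mc_se <- se_slope / sqrt(300)
  expect_lt(abs(mean(est) - abs(true_slope)), 3 * mc_se)
})

test_that("inversion round-trips through both fits to 1e-9", {
  lfit <- fit_logistic(make_4pl_curve())
  for (c0 in c(2, 20, 80, 300, 900)) {
    inv <- invert_concentration(lfit, predict(lfit, c0))
    expect_false(inv$extrapolated)
    expect_equal(inv$estimate, c0, tolerance = 1e-9)
  }
  conc <- c(1, 5, 10, 20, 30, 50)
  curve <- structure(
    data.frame(concentration_ng_per_ml = conc,
               mean_zncc = 1 - 0.0012 * conc, sd_zncc = 0, n = 1),
    class = c("correlation_curve", "data.frame"))
  lin <- fit_linear_sensitivity(curve)
  inv <- invert_concentration(lin, predict(lin, 20))
  expect_false(inv$extrapolated)
  expect_equal(inv$estimate, 20, tolerance = 1e-9)
})

test_that("a ZNCC at the midpoint response inverts to the midpoint", {
  fit <- fit_logistic(make_4pl_curve(midpoint = 80))
  z_mid <- (fit$lower_asymptote + fit$upper_asymptote) / 2
  expect_equal(invert_concentration(fit, z_mid)$estimate, 80,
               tolerance = 1e-6)
})

test_that("values beyond the asymptotes clamp to the range with a flag", {
  fit <- fit_logistic(make_4pl_curve())
  hi <- invert_concentration(fit, 1.5)   # above upper asymptote
  lo <- invert_concentration(fit, 0.1)   # below lower asymptote
  expect_true(hi$extrapolated)
  expect_true(lo$extrapolated)
  expect_equal(hi$estimate, 1)      # high ZNCC = low concentration side
  expect_equal(lo$estimate, 1000)
})
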