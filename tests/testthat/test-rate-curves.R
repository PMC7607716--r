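test_that("noise-free logistic data are recovered to four significant digits", {
  t <- seq(2, 144, by = 6)
  y <- logistic4p(t, A1 = 60, A2 = 0, x0 = 40, p = 5)
  fit <- fitLogistic(t, y)
  expect_true(fit$converged)
  expect_equal(fit$A1, 60, tolerance = 1e-4)
  expect_equal(fit$A2, 0, tolerance = 1e-4 * 60) # absolute scale of the data
  expect_equal(fit$x0, 40, tolerance = 1e-4)
  expect_equal(fit$p, 5, tolerance = 1e-4)
})

test_that("constant series give a degenerate flagged fit", {
  fit <- fitLogistic(seq(1, 100, 10), rep(3.3, 10))
  expect_true(fit$degenerate)
  expect_equal(fit$A1, fit$A2)
  expect_equal(fit$rss, 0)
})

test_that("mid-range time is recovered within 5 % under 5 % noise", {
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    t <- seq(2, 144, by = 6)
    y0 <- logistic4p(t, 60, 0, 40, 5)
    y <- y0 * (1 + rnorm(length(t), 0, 0.05))
    fit <- fitLogistic(t, y)
    abs(fit$x0 - 40) / 40
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the analytic derivative matches its closed form and a numeric oracle", {
  fit <- fitLogistic(seq(2, 144, 6), logistic4p(seq(2, 144, 6), 60, 0, 40, 5))
  # at t = x0 the rate is |A1 - A2| p / (4 x0)
  expect_equal(derivativeRate(fit, fit$x0), 60 * 5 / (4 * 40),
               tolerance = 1e-4)
  expect_error(derivativeRate(fit, 0), "t > 0")
  # flat curve: zero rate everywhere
  flat <- fitLogistic(seq(1, 100, 10), rep(2, 10))
  expect_equal(derivativeRate(flat, c(1, 50, 99)), c(0, 0, 0))
  # central finite differences of the fitted curve
  set.seed(99)
  tt <- runif(100, 1, 140)
  h <- 1e-5
  fd <- abs(predict(fit, tt + h) - predict(fit, tt - h)) / (2 * h)
  expect_equal(derivativeRate(fit, tt), fd, tolerance = 1e-6)
})

test_that("the rate integrates back to the fitted cumulative change", {
  fit <- structure(list(A1 = 60, A2 = 0, x0 = 40, p = 5, rss = 0,
                        converged = TRUE, degenerate = FALSE, n_iter = 0L),
                   class = "logistic_fit")
  total <- integrate(function(t) derivativeRate(fit, t),
                     lower = 1e-6, upper = 144, rel.tol = 1e-9)$value
  expect_equal(total, abs(predict(fit, 144) - predict(fit, 1e-6)),
               tolerance = 1e-6)
})

test_that("fitting is scale-equivariant", {
  t <- seq(2, 144, by = 6)
  y <- logistic4p(t, 55, 3, 35, 4.2)
  f1 <- fitLogistic(t, y)
  f2 <- fitLogistic(t, 10 * y)
  expect_equal(f2$A1, 10 * f1$A1, tolerance = 1e-6)
  expect_equal(f2$A2, 10 * f1$A2, tolerance = 1e-4)
  expect_equal(f2$x0, f1$x0, tolerance = 1e-6)
  expect_equal(derivativeRate(f2, 40), 10 * derivativeRate(f1, 40),
               tolerance = 1e-6)
})

test_that("peak metrics are consistent and cross-checked by bisection", {
  fit <- structure(list(A1 = 60, A2 = 0, x0 = 40, p = 5, rss = 0,
                        converged = TRUE, degenerate = FALSE, n_iter = 0L),
                   class = "logistic_fit")
  curve <- rateCurve(fit, t_max = 144, step = 0.05, threshold = 0.1)
  # the derivative of a 4PL is unimodal for p > 1
  sign_changes <- sum(diff(sign(diff(curve$rates))) != 0)
  expect_lte(sign_changes, 1)
  # plateau contains the argmax and has at least one grid point
  expect_gte(curve$peak_time, curve$peak_interval[1])
  expect_lte(curve$peak_time, curve$peak_interval[2])
  # bisection on the closed form locates the same subthreshold crossing
  root <- uniroot(function(t) derivativeRate(fit, t) - 0.1,
                  lower = curve$peak_time, upper = 144, tol = 1e-8)$root
  expect_equal(curve$subthreshold_time, root, tolerance = 1e-3)
  expect_error(rateCurve(fit, t_max = 0.01), "t_max")
})

test_that("cumulative consumption linearizes pulsed records for fitting", {
  rec <- simulateCultivation(nfParams("glucose", S0 = 55.4),
                             restock_target = 90)
  cc <- cumulativeConsumption(rec)
  expect_true(all(diff(cc$consumed_gL) > 0)) # sawtooth removed
  expect_equal(cc$consumed_gL[1], 0)
})

test_that("daily sampling shifts the fitted peak only modestly", {
  # fit the daily-sampled record and a densely evaluated true course; within
  # the logistic model class, seven daily samples determine the peak of the
  # four-parameter curve to within ten percent of the dense-data fit. The
  # fitted peak also stays below the true instantaneous maximum: a smooth
  # sigmoid can only smear out the sharp consumption collapse at nitrogen
  # exhaustion, never exceed it.
  daily <- simulateCultivation(nfParams("glucose"), plan = gluContinuousPlan())
  dense <- simulateCultivation(
    nfParams("glucose", sampling_times = seq(0, 142, by = 0.5),
             sample_volume_L = 1e-9),
    plan = gluContinuousPlan())
  fit_daily <- fitLogistic(cumulativeConsumption(daily)$t_h,
                           cumulativeConsumption(daily)$consumed_gL)
  cc_dense <- cumulativeConsumption(dense)
  fit_dense <- fitLogistic(cc_dense$t_h, cc_dense$consumed_gL)
  pk_daily <- rateCurve(fit_daily, 142, step = 0.05)$peak_rate
  pk_dense <- rateCurve(fit_dense, 142, step = 0.05)$peak_rate
  expect_equal(pk_daily, pk_dense, tolerance = 0.10)
  expect_lt(pk_daily, attr(daily, "true_peak_sigma"))
})
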