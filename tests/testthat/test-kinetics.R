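test_that("windows without consumption are flagged, not dropped", {
  s <- data.frame(t_h = c(0, 24, 48, 72, 96), sugar_gL = rep(50, 5),
                  cdw_gL = rep(2, 5), fame_pct_cdw = rep(10, 5),
                  acid_gL = 0, co2_cum_g = 0)
  rec <- cultivationRecord("flat", s)
  y <- phaseYields(rec, phaseWindow(0, 96))
  expect_true(y$undefined_yield)
  expect_true(is.na(y$Y_xs))
  expect_equal(y$Q_s, 0)
})

test_that("phase yields recover simulator ground truth on clean data", {
  rec <- simulateCultivation(nfParams("glucose"), plan = gluContinuousPlan())
  tr <- attr(rec, "truth")
  windows <- list(phaseWindow(0, 70, "N-metabolization"),
                  phaseWindow(70, 142, "N-limitation"),
                  phaseWindow(0, 142, "Total"))
  y <- phaseYields(rec, windows, basis = "mass")
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    i0 <- which.min(abs(tr$t - w$t_start)); i1 <- which.min(abs(tr$t - w$t_end))
    # boundary masses use the post-event volume: windows are closed on the
    # left, so the sampling withdrawal at a boundary belongs to the window
    # that starts there
    v0 <- volumeAt(rec, tr$t[i0]); v1 <- volumeAt(rec, tr$t[i1])
    true_dS <- tr$consumed[i1] - tr$consumed[i0] +
      (tr$V[i1] - v1) * tr$S[i1]
    vbar <- (v0 + v1) / 2
    expect_equal(y$dS_gL[i] * vbar, true_dS, tolerance = 0.01)
    true_dX <- (tr$Xf[i1] + tr$L[i1]) * v1 - (tr$Xf[i0] + tr$L[i0]) * v0
    # mass-basis yield against the simulator's true mass changes
    expect_equal(y$Y_xs[i], true_dX / true_dS, tolerance = 0.01)
  }
})

test_that("daily windows telescope to the total window on any record", {
  rec <- simulateCultivation(simParams("glucose", seed = 3L),
                             plan = gluContinuousPlan())
  daily <- lapply(seq_len(6), function(i) {
    phaseWindow(c(0, 24, 46, 70, 94, 118)[i], c(24, 46, 70, 94, 118, 142)[i])
  })
  y <- phaseYields(rec, daily)
  tot <- phaseYields(rec, phaseWindow(0, 142, "Total"))
  expect_equal(sum(y$dS_gL), tot$dS_gL, tolerance = 1e-10)
  expect_equal(sum(y$dX_gL), tot$dX_gL, tolerance = 1e-10)
  expect_equal(sum(y$dP_gL), tot$dP_gL, tolerance = 1e-10)
})

test_that("whole-record consumption rate agrees with metabolized sugar", {
  rec <- simulateCultivation(nfParams("glucose"), plan = gluContinuousPlan())
  s <- rec$samples
  y <- phaseYields(rec, phaseWindow(0, 142, "Total"), basis = "mass")
  dt <- max(s$t_h) - min(s$t_h)
  vbar <- mean(volumeAt(rec, range(s$t_h)))
  expect_equal(y$Q_s * dt, metabolizedSugar(rec) / vbar, tolerance = 0.01)
})

test_that("utilization reproduces the published percentages and guards", {
  expect_equal(as.numeric(utilization(150.66, 269)), 56.01, tolerance = 0.01)
  expect_equal(as.numeric(utilization(138.46, 150)), 92.31, tolerance = 0.01)
  expect_equal(as.numeric(utilization(0, 100)), 0)
  over <- utilization(100.5, 100)
  expect_equal(as.numeric(over), 100)
  expect_true(attr(over, "capped"))
  expect_error(utilization(10, 0), "positive")
  expect_error(utilization(110, 100), "inconsistent")
})

test_that("percent change respects its base convention", {
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(5.98, 7.41, base = "new"), 19.30, tolerance = 0.01)
  expect_equal(percentChange(19.78, 10.38, base = "reference"), -47.52,
               tolerance = 0.01)
  expect_error(percentChange(0, 5, base = "reference"), "zero base")
})

test_that("strategy comparison summarizes outcomes and their deltas", {
  p <- nfParams("glucose")
  rec <- simulateCultivation(p, plan = gluContinuousPlan())
  same <- compareStrategies(list(rec, rec))
  expect_equal(same$changes$pct_change, rep(0, nrow(same$changes)))

  high <- simulateCultivation(nfParams("glucose", S0 = 55.4),
                              restock_target = 90, label = "high_excess")
  low <- simulateCultivation(p, plan = gluContinuousPlan(), label = "low_excess")
  cmp <- compareStrategies(list(high, low))
  expect_equal(nrow(cmp$summary), 2)
  # reduced excess: less acid, better utilization
  acid_delta <- cmp$changes$pct_change[cmp$changes$field == "final_acid_gL"]
  expect_lt(acid_delta, 0)
  expect_gt(cmp$summary$pct_used[2], cmp$summary$pct_used[1])
})

test_that("published totals imply the printed whole-process yields", {
  # continuous processes: total yield = final CDW / (metabolized / V0)
  tab <- read.csv(extdataPath("strategy_summary.csv"))
  cont <- tab[tab$process == "continuous", ]
  y <- cont$final_cdw_gL / (cont$metabolized_g / 1.2)
  expect_equal(y, c(0.21, 0.22), tolerance = 0.03)
})

test_that("normalizeToMax rescales to a unit maximum", {
  expect_equal(normalizeToMax(c(2, 5, 10)), c(0.2, 0.5, 1))
  expect_equal(max(normalizeToMax(c(1, NA, 3)), na.rm = TRUE), 1)
  expect_error(normalizeToMax(c(-1, 0)), "positive maximum")
})
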