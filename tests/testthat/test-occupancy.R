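test_that("sigmoid-Emax fit recovers noiseless parameters and halves at the IC50", {
  conc <- c(3, 10, 30, 86, 200, 600, 2000, 6000)
  inh <- 1 * conc / (86 + conc)            # IC50 86 nM, Hill 1, Emax 1
  fit <- fit_ic50(conc, inh)
  expect_equal(fit$ic50, 86, tolerance = 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_equal(fit$emax, 1, tolerance = 1e-4)
  expect_true(fit$reliable)
  # the fitted curve passes through Emax/2 at the fitted IC50 by definition
  pred_at_ic50 <- fit$emax * fit$ic50^fit$hill /
    (fit$ic50^fit$hill + fit$ic50^fit$hill)
  expect_equal(pred_at_ic50, fit$emax / 2, tolerance = 1e-12)

  expect_error(fit_ic50(c(10, 100, 1000), c(0.1, 0.5, 0.9)), "4 distinct")
})

test_that("noisy replicate fits concentrate around the true potency with sane interval coverage", {
  set.seed(33)
  conc <- c(3, 10, 30, 86, 200, 600, 2000, 6000)
  truth <- 1 * conc / (86 + conc)
  est <- numeric(60); covered <- logical(60)
  for (r in 1:60) {
    y <- truth + rnorm(8, 0, 0.05)          # ~10% noise near half-maximum
    f <- fit_ic50(conc, pmin(pmax(y, -0.2), 1.2))
    est[r] <- f$ic50
    covered[r] <- !any(is.na(f$ic50_ci)) &&
      f$ic50_ci[1] <= 86 && 86 <= f$ic50_ci[2]
  }
  expect_lt(abs(median(est) / 86 - 1), 0.05)
  expect_gte(mean(covered), 0.80)
})

test_that("kinetic occupancy: half-saturation, dissociation decay, and bounds", {
  occ <- occupancy_params()                 # Kd 86 nM, residence 5 min
  expect_equal(occ$kon_t * occ$kd_t, occ$koff_t, tolerance = 1e-14)
  expect_equal(occ$koff_t, 12)              # 1/h

  # constant exposure at Kd settles at 50% occupancy
  tt <- seq(0, 4, by = 0.01)
  ko <- occupancy_kinetics(tt, rep(86, length(tt)), occ, to0 = 0)
  expect_equal(ko$occupancy[length(tt)], 0.5, tolerance = 1e-4)
  expect_true(all(ko$occupancy >= 0 & ko$occupancy <= 1))

  # washout from full occupancy decays as exp(-koff t): half-time equals
  # the residence time times ln 2
  tt_d <- seq(0, 0.5, by = 0.001)
  ko2 <- occupancy_kinetics(tt_d, rep(0, length(tt_d)), occ, to0 = 1)
  expect_equal(ko2$occupancy, exp(-12 * tt_d), tolerance = 1e-5)
  expect_equal(stats::approx(ko2$occupancy, tt_d, xout = 0.5)$y,
               (5 / 60) * log(2), tolerance = 1e-3)
})

test_that("a 5-minute residence time tracks quasi-equilibrium against day-scale kinetics", {
  occ <- occupancy_params()
  tt <- seq(0, 48, by = 0.25)
  cu <- 500 * exp(-log(2) / 26 * tt)        # 26 h half-life exposure, nM
  ko <- occupancy_kinetics(tt, cu, occ,
                           to0 = equilibrium_occupancy(cu[1], occ))
  qe <- equilibrium_occupancy(cu, occ)
  expect_lt(max(abs(ko$occupancy - qe)), 0.01)
})

test_that("trough occupancy rises with dose, saturates, and favors divided dosing", {
  pop <- population_params()
  occ <- occupancy_params()
  tc <- trough_occupancy_curve(c(60, 120, 240, 480), c("QD", "BID"), pop,
                               occ, n_subjects = 4, seed = 5)
  bid <- tc[tc$regimen == "BID", ]
  qd <- tc[tc$regimen == "QD", ]
  # monotone nondecreasing in dose within each regimen
  expect_true(all(diff(bid$trough_occupancy) > -1e-9))
  expect_true(all(diff(qd$trough_occupancy) > -1e-9))
  # equal daily dose: twice-daily trough occupancy exceeds once-daily
  expect_gt(bid$trough_occupancy[bid$dose == 120],
            qd$trough_occupancy[qd$dose == 240])
  # saturable bioavailability flattens the top of the dose-response
  gain_low <- bid$trough_occupancy[bid$dose == 120] -
    bid$trough_occupancy[bid$dose == 60]
  gain_high <- bid$trough_occupancy[bid$dose == 480] -
    bid$trough_occupancy[bid$dose == 240]
  expect_lt(gain_high, gain_low)
  # the potency-uncertainty band brackets the point estimate
  expect_true(all(tc$occ_low <= tc$trough_occupancy + 1e-9))
  expect_true(all(tc$occ_high >= tc$trough_occupancy - 1e-9))

  # infinite-potency limit: occupancy approaches 1
  occ_hot <- occupancy_params(ic50 = 0.01, ic50_ci = c(0.005, 0.02))
  tc2 <- trough_occupancy_curve(120, "BID", pop, occ_hot,
                                n_subjects = 2, seed = 5)
  expect_gt(tc2$trough_occupancy, 0.999)

  # molar conversion must be configured
  pop_nomw <- pop
  pop_nomw$structural$binding$mw <- NA_real_
  expect_error(trough_occupancy_curve(120, "BID", pop_nomw, occ,
                                      n_subjects = 2, seed = 5),
               "mw")
})
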