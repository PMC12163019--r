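test_that("terminal slope is exact on mono-exponential data and guards degenerate input", {
  tt <- c(0.5, 1, 24, 36, 48)
  cc <- c(2, 9, 10 * exp(-0.1 * 24), 10 * exp(-0.1 * 36),
          10 * exp(-0.1 * 48))
  lz <- fit_lambda_z(tt, cc)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(lz$t_half, 6.93, tolerance = 1e-3)

  # constant profile: nonnegative slope -> not estimable
  flat <- fit_lambda_z(1:6, rep(2, 6))
  expect_false(flat$estimable)
  expect_true(is.na(flat$lambda_z))

  # fewer than 3 usable points -> not estimable
  expect_false(fit_lambda_z(c(1, 2), c(3, 1))$estimable)
})

test_that("terminal slope on noisy data equals an independent least-squares fit", {
  set.seed(71)
  tt <- c(1, 2, 24, 36, 48, 72, 96)
  cc <- 8 * exp(-0.08 * tt) * exp(rnorm(7, 0, 0.05))
  cc[1:2] <- c(3, 7)   # absorption phase, peak at t = 2
  lz <- fit_lambda_z(tt, cc)
  # oracle: closed-form OLS slope on the selected terminal window
  w <- seq(length(tt) - lz$n_points + 1, length(tt))
  x <- tt[w]; y <- log(cc[w])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(lz$lambda_z, -slope, tolerance = 1e-9)
})

test_that("AUC of a dense mono-exponential matches the analytic integral", {
  k <- 0.05; c0 <- 4
  tt <- seq(0, 240, by = 0.5)
  cc <- c0 * exp(-k * tt)
  r <- nca_single(tt, cc, dose = 10, route = "iv")
  expect_equal(r$auc_inf, c0 / k, tolerance = 1e-3)
  expect_equal(r$mrt, 1 / k, tolerance = 5e-3)         # MRT = 1/k for IV
  expect_equal(r$vss, (10 / c0), tolerance = 5e-3)     # Vss = V = D/C0
  # identities hold by construction
  expect_equal(r$cl_f * r$auc_inf, 10, tolerance = 1e-12)
  expect_equal(r$vz_f * r$lambda_z, r$cl_f, tolerance = 1e-12)
})

test_that("linear-up/log-down AUC lies at or below the linear trapezoid on declining data", {
  tt <- c(0, 1, 2, 4, 8, 12, 24)
  cc <- c(0, 3, 2.4, 1.7, 0.9, 0.5, 0.1)
  both <- auc_trapezoid(tt, cc, "lin-up-log-down")$auc
  lin <- auc_trapezoid(tt, cc, "linear")$auc
  expect_lt(both, lin)
  # on purely rising data the two rules coincide
  rise <- c(0, 1, 2, 3, 4, 5, 6)
  expect_equal(auc_trapezoid(tt, rise, "lin-up-log-down")$auc,
               auc_trapezoid(tt, rise, "linear")$auc)
})

test_that("single-dose NCA reproduces the 120 mg oral parameter set", {
  # profile constructed with AUC_inf = 119 mg·h/L and t1/2 = 24.4 h
  k <- log(2) / 24.4
  c0 <- 119 * k
  tt <- seq(0, 400, by = 0.25)
  r <- nca_single(tt, c0 * exp(-k * tt), dose = 120, route = "iv")
  expect_equal(r$cl_f, 1.01, tolerance = 0.01)   # apparent clearance
  expect_equal(r$vz_f, 35.6, tolerance = 0.01)   # terminal volume
})

test_that("multiple-dose NCA: interval metrics, identity case and superposition accumulation", {
  # identical steady-state and single-dose interval profiles
  tt <- c(0, 1, 2, 4, 8, 12)
  cc <- c(1.0, 2.2, 2.0, 1.6, 1.2, 1.0)
  sd_prof <- nca_single(c(tt, 24, 48), c(cc, 0.6, 0.2), dose = 60)
  r <- nca_multiple(tt, cc, dose = 60, tau = 12, sd_result = sd_prof,
                    time_sd = c(tt, 24, 48), conc_sd = c(cc, 0.6, 0.2))
  expect_equal(r$accumulation$ra_auc, 1, tolerance = 1e-12)
  expect_equal(r$accumulation$ra_cmax, 1, tolerance = 1e-12)
  expect_lte(r$accumulation$r_lin, 1)
  expect_equal(r$nca$c_av, r$nca$auc_tau / 12, tolerance = 1e-12)
  expect_equal(r$nca$ptf,
               100 * (max(cc) - min(cc)) / (r$nca$auc_tau / 12),
               tolerance = 1e-12)

  # superposition oracle: linear kinetics with known k, 100 doses
  k <- 0.06; tau <- 12
  tt2 <- seq(0, tau, by = 0.1)
  single <- exp(-k * tt2)                       # unit bolus, V = 1
  nsum <- vapply(tt2, function(t) {
    sum(exp(-k * (t + tau * (0:99))))
  }, numeric(1))
  rr <- nca_multiple(tt2, nsum, dose = 1, tau = tau,
                     time_sd = tt2, conc_sd = single)
  expect_equal(rr$accumulation$ra_auc, 1 / (1 - exp(-k * tau)),
               tolerance = 0.01)

  # mismatched sampling: single-dose profile not covering tau errors
  expect_error(nca_multiple(tt2, nsum, dose = 1, tau = tau,
                            time_sd = tt2[tt2 < 6],
                            conc_sd = single[tt2 < 6]),
               "does not cover")
})

test_that("average concentration over the interval matches the printed multiple-dose value", {
  # unbound AUC(0-24) of 1.65 mg·h/L at 45 mg once daily
  tt <- seq(0, 24, by = 0.5)
  cc <- rep(1.65 / 24, length(tt))
  cc[1] <- cc[1] * 1.000001   # break exact flatness, keep the AUC
  r <- nca_multiple(tt, cc, dose = 45, tau = 24)
  expect_equal(r$nca$c_av, 0.0689, tolerance = 0.005)
})

test_that("theoretical accumulation matches its closed form and a superposition oracle", {
  expect_equal(theoretical_accumulation(10, 10), 2, tolerance = 1e-12)
  # k*tau = 0.2: compare with explicitly summed superposed doses
  k <- 0.2 / 12
  t_half <- log(2) / k
  oracle <- sum(exp(-0.2 * (0:99))) / 1   # AUC ratio ss/first interval
  expect_equal(theoretical_accumulation(t_half, 12), oracle,
               tolerance = 1e-4)
  expect_equal(theoretical_accumulation(t_half, 12), 5.5167,
               tolerance = 1e-4)
  expect_error(theoretical_accumulation(-1, 12), "positive")
  expect_error(theoretical_accumulation(26, 0), "positive")
})
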