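test_that("dose-dependent bioavailability: anchor, monotonicity, linear limit, physical cap", {
  p <- structural_params()
  expect_equal(bioavailability_of_dose(120, p), p$f_ref, tolerance = 1e-12)
  expect_equal(bioavailability_of_dose(120, p), 0.739, tolerance = 1e-12)
  f <- bioavailability_of_dose(c(5, 15, 60, 120, 240, 480, 960), p)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f <= 1 & f > 0))
  p_inf <- structural_params(d50 = Inf)
  expect_equal(bioavailability_of_dose(c(10, 100, 1000), p_inf),
               rep(p_inf$f_ref, 3))
})

test_that("equilibrium unbound fraction follows its closed form", {
  b <- binding_params()          # Kd 0.4 µM, capacity 14.9 µM
  fu0 <- equilibrium_fu(0, b)
  expect_equal(fu0, 0.4 / 15.3, tolerance = 1e-12)
  expect_equal(100 * fu0, 2.61, tolerance = 0.002)
  # inside the measured pre-dose range of 1.44-4.00%
  expect_gt(100 * fu0, 1.44); expect_lt(100 * fu0, 4.00)
  # strictly increasing toward 1 at saturation
  grid <- c(0, 0.01, 0.1, 0.4, 1, 5, 20, 100, 1e4)
  expect_true(all(diff(equilibrium_fu(grid, b)) > 0))
  expect_equal(equilibrium_fu(1e7, b), 1, tolerance = 1e-5)
  # derived association rate is consistent to machine precision
  expect_equal(b$kon_bind * b$kd_bind, b$koff_bind, tolerance = 1e-14)
})

test_that("with binding removed the model collapses to the linear one-compartment closed form", {
  p <- linear_params(cl = 0.551, v = 20.1, ka = 0.4, t_lag = 0)
  tt <- seq(0.5, 120, by = 0.5)
  iv <- simulate_profile(p, data.frame(time = 0, amt = 0.1, route = "iv"),
                         tt)
  expect_equal(iv$c_total, conc_1cpt_iv(tt, 0.1, 0.551, 20.1),
               tolerance = 0.001)
  lz <- fit_lambda_z(iv$time, iv$c_total)
  expect_equal(lz$t_half, log(2) * 20.1 / 0.551, tolerance = 0.005)
  expect_equal(lz$t_half, 25.3, tolerance = 0.005)

  oral <- simulate_profile(p, data.frame(time = 0, amt = 120,
                                         route = "oral"), tt)
  expect_equal(oral$c_total,
               conc_1cpt_oral(tt, 120, p$f_ref, 0.4, 0.551, 20.1),
               tolerance = 0.001)
})

test_that("mass is conserved when clearance is removed", {
  b <- binding_params()
  p <- structural_params(cl_u = 1e-12, v = 12, ka = 0.3,
                         binding = b)
  tt <- seq(0, 96, by = 2)
  prof <- simulate_profile(p, data.frame(time = 0, amt = 120,
                                         route = "oral"), tt)
  umol <- 1000 * 120 * bioavailability_of_dose(120, p) / b$mw
  state <- attr(prof, "state_final")
  total_end <- state[["a_gut"]] + p$v * (state[["cu"]] + state[["cb"]])
  expect_equal(total_end, umol, tolerance = 1e-6)
})

test_that("fast binding kinetics reach the equilibrium unbound fraction everywhere", {
  b <- binding_params()
  b_fast <- binding_params(kd_bind = b$kd_bind, b_max = b$b_max,
                           koff_bind = b$koff_bind * 1000, mw = b$mw)
  p <- structural_params(v = 12, ka = 0.3, binding = b_fast)
  tt <- seq(2, 96, by = 1)   # past the absorption-onset transient
  prof <- simulate_profile(p, data.frame(time = 0, amt = 120,
                                         route = "oral"), tt)
  fu_sim <- prof$c_unbound / prof$c_total
  fu_eq <- equilibrium_fu(prof$cu_uM, b_fast)
  expect_lt(max(abs(fu_sim / fu_eq - 1)), 0.01)
})

test_that("states stay nonnegative and bound concentration never exceeds capacity", {
  p <- structural_params()
  tt <- seq(0, 240, by = 0.5)
  prof <- simulate_profile(
    p, data.frame(time = c(0, 12, 24, 36), amt = 480, route = "oral"), tt)
  expect_true(all(prof$cu_uM >= -1e-9))
  expect_true(all(prof$cb_uM >= -1e-9))
  expect_true(all(prof$cb_uM <= p$binding$b_max + 1e-6))
})

test_that("steady-state repetition matches linear accumulation theory and converges fast", {
  # linear model with near-instant absorption (the closed form assumes a
  # mono-exponential interval profile): achieved accumulation equals the
  # superposition prediction
  p_lin <- linear_params(cl = 1.2, v = 30, ka = 50, t_lag = 0)
  ss <- steady_state_profile(p_lin, dose = 100, tau = 12,
                             n_per_interval = 97)
  t_half <- log(2) * 30 / 1.2
  expect_equal(ss$auc_tau / ss$auc_tau_first,
               theoretical_accumulation(t_half, 12), tolerance = 0.01)

  # dosing much sparser than the half-life: no accumulation
  p_fast <- linear_params(cl = 20, v = 10, ka = 2, t_lag = 0)
  ss2 <- steady_state_profile(p_fast, dose = 100, tau = 24)
  expect_equal(ss2$auc_tau, ss2$auc_tau_first, tolerance = 0.01)
  expect_lte(ss2$n_intervals, 3)

  # default parameters at 120 mg twice daily reach steady state within six
  # intervals (~3 days), as observed
  ss3 <- steady_state_profile(structural_params(), 120, 12)
  expect_true(ss3$converged)
  expect_lte(ss3$n_intervals, 6)
  # by day 3 the interval exposure is within 3% of its final value
  expect_equal(ss3$auc_by_interval[5] / ss3$auc_tau, 1, tolerance = 0.03)
})

test_that("capacity-limited binding depresses accumulation below the linear prediction", {
  p <- structural_params()
  ss <- steady_state_profile(p, dose = 200, tau = 12)
  ra <- ss$auc_tau / ss$auc_tau_first
  # terminal half-life of the matching single-dose profile
  tt <- seq(0, 240, by = 0.5)
  sd_prof <- simulate_profile(p, data.frame(time = 0, amt = 200,
                                            route = "oral"), tt)
  t_half <- fit_lambda_z(sd_prof$time, sd_prof$c_total)$t_half
  expect_lt(ra, theoretical_accumulation(t_half, 12))
  expect_gt(ra, 1)
})
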