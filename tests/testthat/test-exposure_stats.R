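test_that("geometric mean ratio: identity, printed food-effect anchors, and arithmetic oracle", {
  x <- c(2.1, 3.7, 1.4, 5.2, 2.8)
  r <- gmr(x, x, paired = TRUE)
  expect_equal(r$point, 1, tolerance = 1e-12)
  expect_lte(r$ci90_low, 1); expect_gte(r$ci90_high, 1)

  # paired ratio of geometric means reproduces the printed Cmax ratios
  hf <- vector_with_geomean(4.63, 10); fasted <- vector_with_geomean(3.22, 10)
  expect_equal(gmr(hf, fasted)$point, 1.44, tolerance = 0.01)
  mf <- vector_with_geomean(4.59, 10)
  expect_equal(gmr(mf, fasted)$point, 1.43, tolerance = 0.01)
  auc_hf <- vector_with_geomean(158, 10); auc_f <- vector_with_geomean(161, 10)
  expect_equal(gmr(auc_hf, auc_f)$point, 0.980, tolerance = 0.01)

  # direct arithmetic oracle on random paired lognormal data
  set.seed(4)
  a <- rlnorm(12, 0, 0.4); b <- rlnorm(12, 0.2, 0.4)
  expect_equal(gmr(a, b)$point, exp(mean(log(a) - log(b))),
               tolerance = 1e-12)
  # multiplicativity: point estimate equals ratio of geometric means
  expect_equal(gmr(a, b)$point,
               exp(mean(log(a))) / exp(mean(log(b))), tolerance = 1e-12)

  expect_error(gmr(c(1, -2), c(1, 2)), "positive")
  expect_error(gmr(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("dose-normalized ratios reproduce the printed dose-proportionality table", {
  cav_120 <- vector_with_geomean(0.132, 8)
  cav_45 <- vector_with_geomean(0.0689, 8)
  r1 <- dose_normalized_ratio(cav_120, 120, cav_45, 45)
  expect_equal(r1$point, 0.718, tolerance = 0.01)

  cmax_200 <- vector_with_geomean(0.366, 8)
  cmax_120 <- vector_with_geomean(0.351, 8)
  r2 <- dose_normalized_ratio(cmax_200, 200, cmax_120, 120)
  expect_equal(r2$point, 0.627, tolerance = 0.01)

  # exactly proportional exposure gives a ratio of 1
  base <- vector_with_geomean(1, 6)
  r3 <- dose_normalized_ratio(4 * base, 200, base, 50)
  expect_equal(r3$point, 1, tolerance = 1e-12)
})

test_that("power model: proportional and flat limits, printed-table oracle, scale invariance", {
  doses <- c(15, 30, 60, 120, 240, 480)
  # exact data: confint warns about a perfect fit, which is the point here
  suppressWarnings({
    expect_equal(power_model(doses, 0.5 * doses)$slope, 1,
                 tolerance = 1e-12)
    expect_equal(power_model(doses, rep(7, 6))$slope, 0, tolerance = 1e-12)
  })

  # single-dose AUC geometric means: independent closed-form OLS oracle
  auc <- c(32.1, 69.5, 107, 119, 182, 188)
  x <- log(doses); y <- log(auc)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  pm <- power_model(doses, auc)
  expect_equal(pm$slope, slope_hand, tolerance = 1e-12)
  expect_lt(pm$slope, 1)                     # sub-proportional exposure
  expect_lt(pm$slope_ci90[2], 1)

  # invariance under positive rescaling of either axis
  pm2 <- power_model(doses * 3.7, auc)
  pm3 <- power_model(doses, auc * 0.021)
  expect_equal(pm2$slope, pm$slope, tolerance = 1e-10)
  expect_equal(pm3$slope, pm$slope, tolerance = 1e-10)

  expect_error(power_model(c(10, 10, 20), c(1, 1, 2)), "3 distinct")
})

test_that("absolute bioavailability: identity, printed anchor, and a known-truth simulation", {
  # identical dose-normalized exposure oral and IV
  r <- absolute_bioavailability(c(10, 12, 9), 120, c(10, 12, 9) / 1200, 0.1)
  expect_equal(r$point, 1, tolerance = 1e-12)

  # printed geometric means: 161 mg·h/L at 120 mg oral vs 181 µg·h/L at
  # 0.100 mg IV (tracer column µg-scaled)
  oral <- vector_with_geomean(161, 10)
  iv <- rev(vector_with_geomean(0.181, 10))   # uncorrelated within-subject spread
  r2 <- absolute_bioavailability(oral, 120, iv, 0.1)
  expect_equal(100 * r2$point, 73.9, tolerance = 0.01)
  expect_lt(r2$ci90_low, r2$point); expect_gt(r2$ci90_high, r2$point)

  # simulation with F fixed at 0.80 and no noise recovers 80% exactly
  tt <- seq(0.25, 400, by = 0.25)
  auc_o <- auc_iv <- numeric(5)
  for (s in 1:5) {
    scale <- 0.8 + 0.1 * s   # per-subject clearance differences
    p <- linear_params(cl = 0.551 * scale, v = 20, ka = 0.5, f_ref = 0.80)
    po <- simulate_profile(p, data.frame(time = 0, amt = 120,
                                         route = "oral"), tt)
    pi <- simulate_profile(p, data.frame(time = 0, amt = 0.1,
                                         route = "iv"), tt)
    auc_o[s] <- nca_single(po$time, po$c_total, 120)$auc_inf
    auc_iv[s] <- nca_single(pi$time, pi$c_total, 0.1, route = "iv")$auc_inf
  }
  rf <- absolute_bioavailability(auc_o, 120, auc_iv, 0.1)
  expect_equal(100 * rf$point, 80, tolerance = 0.005)
})

test_that("crossover ANOVA matches the paired analysis when balanced and absorbs period effects", {
  set.seed(8)
  n <- 10
  subj <- sprintf("S%02d", 1:n)
  bsl <- rlnorm(n, log(3), 0.3)
  trt_eff <- 1.4
  per_eff <- 1.1                      # +10% in period 2
  seq_ab <- rep(c(TRUE, FALSE), each = n / 2)
  d <- do.call(rbind, lapply(1:n, function(i) {
    trts <- if (seq_ab[i]) c("fed", "fasted") else c("fasted", "fed")
    data.frame(subject = subj[i], period = c("1", "2"), treatment = trts,
               value = bsl[i] * ifelse(trts == "fed", trt_eff, 1) *
                 c(1, per_eff) * rlnorm(2, 0, 0.08),
               stringsAsFactors = FALSE)
  }))
  ca <- crossover_anova(d, "fed", "fasted")

  # oracle: from-scratch normal-equations solve of the same fixed-effects
  # model
  X <- cbind(1,
             as.numeric(d$treatment == "fed"),
             as.numeric(d$period == "2"),
             outer(d$subject, subj[-1], "==") * 1)
  beta <- solve(t(X) %*% X, t(X) %*% log(d$value))
  expect_equal(ca$point, exp(beta[2]), tolerance = 1e-10)

  # the period effect is absorbed: treatment ratio unbiased near 1.4
  expect_equal(ca$point, trt_eff, tolerance = 0.06)

  # balanced complete case equals the paired geometric-mean ratio
  fed <- d$value[d$treatment == "fed"][order(d$subject[d$treatment == "fed"])]
  fst <- d$value[d$treatment == "fasted"][order(d$subject[d$treatment == "fasted"])]
  expect_equal(ca$point, gmr(fed, fst)$point, tolerance = 1e-10)

  # missing cells error names the subject
  expect_error(crossover_anova(d[-1, ], "fed", "fasted"), "S01")
})
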