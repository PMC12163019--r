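# Independent closed-form oracles and small fixture builders.

# linear one-compartment oral solution (no binding): first-order absorption
# after a lag, first-order elimination ke = cl/v
conc_1cpt_oral <- function(t, dose, f, ka, cl, v, t_lag = 0) {
  ke <- cl / v
  tt <- pmax(t - t_lag, 0)
  f * dose * ka / (v * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt))
}

# linear one-compartment IV bolus solution
conc_1cpt_iv <- function(t, dose, cl, v) {
  (dose / v) * exp(-(cl / v) * t)
}

# structural parameter set with binding switched off (linear limit)
linear_params <- function(cl = 0.551, v = 20.1, ka = 0.4, t_lag = 0,
                          f_ref = 0.739, mw = 390) {
  structural_params(cl_u = cl, v = v, ka = ka, t_lag = t_lag,
                    f_ref = f_ref, d50 = Inf,
                    binding = binding_params(b_max = 1e-12, mw = mw))
}

# a positive vector with an exactly prescribed geometric mean
vector_with_geomean <- function(gm, n = 8) {
  spread <- exp(seq(-0.3, 0.3, length.out = n))
  gm * spread / exp(mean(log(spread)))
}

# hand-built two-subject dataset exercising both routes, analytes, BLQ and
# crossover metadata
tiny_dataset <- function() {
  subjects <- data.frame(id = c("S1", "S2"), agp = c(0.55, 0.72),
                         arm = "120 mg", sequence = c("AB", "BA"),
                         stringsAsFactors = FALSE)
  doses <- data.frame(
    id = c("S1", "S1", "S2"), period = c("1", "2", "1"),
    time = c(0, 0, 0), amt = c(120, 0.1, 120),
    route = c("oral", "iv", "oral"),
    formulation = c("tablet", "iv-tracer", "tablet"),
    food = c("fasted", "fasted", "high-fat"),
    regimen = c("120 mg single", "tracer", "120 mg single"),
    stringsAsFactors = FALSE)
  obs <- data.frame(
    id = c(rep("S1", 4), rep("S1", 2), rep("S2", 3)),
    period = c(rep("1", 4), rep("2", 2), rep("1", 3)),
    time = c(-0.5, 1, 4, 24, 0.25, 2, 1, 4, 24),
    dv = c(NA, 1.2, 2.5, 0.9, 0.004, 0.003, 1.4, 2.9, NA),
    analyte = c(rep("total", 4), rep("tracer", 2), rep("total", 3)),
    lloq = c(rep(0.01, 4), rep(1e-5, 2), rep(0.01, 3)),
    blq = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  trial_dataset(subjects, doses, obs, design = list(study = "TINY"))
}
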