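#' Default rich sampling schedule (hours post dose)
#' @noRd
.default_sampling <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 12, 16, 24, 36,
                       48, 72, 96)

#' Phase-1 study designs
#'
#' Returns the design of one of the three emulated studies:
#' \describe{
#'   \item{SAD}{Single ascending oral doses 5-480 mg (5 mg as oral
#'     solution, the rest as tablets, fasted; 240 and 480 mg additionally as
#'     split doses, two halves 12 h apart, after a light meal), 6 active + 2
#'     placebo per group.}
#'   \item{MAD}{45 and 120 mg once daily and 60, 120 and 200 mg twice daily
#'     for 10 days (tablets after a light meal), 8 active + 2 placebo per
#'     group; rich sampling after the first and last dose.}
#'   \item{FE}{Three-period, two-sequence crossover of a single 120 mg
#'     tablet (fasted / high-fat meal in periods 1-2 by sequence;
#'     moderate-fat meal in period 3), n = 10, with a 0.100 mg intravenous
#'     microtracer co-administered in the fasted period.}
#' }
#' Washout between periods is 14 days.
#'
#' @param study_tag `"SAD"`, `"MAD"` or `"FE"`.
#' @return An object of class `trial_design` with elements `study`, `arms`
#'   (data frame), `sampling` (h), `washout_days`.
#' @export
make_design <- function(study_tag = c("SAD", "MAD", "FE")) {
  study_tag <- match.arg(study_tag)
  arms <- switch(
    study_tag,
    SAD = data.frame(
      arm = c("5 mg sol", "15 mg", "30 mg", "60 mg", "120 mg", "240 mg",
              "480 mg", "240 mg split", "480 mg split"),
      dose = c(5, 15, 30, 60, 120, 240, 480, 240, 480),
      regimen = c(rep("single", 7), "split", "split"),
      route = "oral",
      formulation = c("solution", rep("tablet", 8)),
      food = c(rep("fasted", 7), "light-meal", "light-meal"),
      n_active = 6L, n_placebo = 2L, treatment_days = 1L,
      tau = 24, stringsAsFactors = FALSE
    ),
    MAD = data.frame(
      arm = c("45 mg QD", "120 mg QD", "60 mg BID", "120 mg BID",
              "200 mg BID"),
      dose = c(45, 120, 60, 120, 200),
      regimen = c("QD", "QD", "BID", "BID", "BID"),
      route = "oral", formulation = "tablet", food = "light-meal",
      n_active = 8L, n_placebo = 2L, treatment_days = 10L,
      tau = c(24, 24, 12, 12, 12), stringsAsFactors = FALSE
    ),
    FE = data.frame(
      arm = "120 mg crossover",
      dose = 120, regimen = "single", route = "oral",
      formulation = "tablet", food = "crossover",
      n_active = 10L, n_placebo = 0L, treatment_days = 1L,
      tau = 24, stringsAsFactors = FALSE
    )
  )
  sampling <- .default_sampling
  if (study_tag == "FE") {
    # crossover periods have a 14-day washout; sample ~6 half-lives so the
    # AUC extrapolation stays small for both analytes
    sampling <- c(sampling, 120, 144, 168)
  }
  structure(list(study = study_tag, arms = arms,
                 sampling = sampling, washout_days = 14,
                 iv_tracer_mg = if (study_tag == "FE") 0.100 else NA_real_),
            class = "trial_design")
}

#' Population simulation parameters
#'
#' Typical structural parameters plus between-subject variability and
#' residual error for trial simulation. Inter-individual variability is
#' lognormal on `cl_u`, `v`, `ka` and the binding capacity, and
#' logit-normal on the reference bioavailability `f_ref`; residual error is
#' proportional (lognormal, homoscedastic on the log scale). The default
#' standard deviations of 0.25 reproduce the 20-30% geometric CVs typical
#' of the observed exposure parameters; the individual binding capacity
#' scales with the subject's simulated AGP concentration (plus lognormal
#' noise), mirroring the weak positive association between the fitted
#' binding capacity and measured AGP.
#'
#' @param structural Typical-value [structural_params()].
#' @param omega Named lognormal IIV SDs for `cl_u`, `v`, `ka`, `f`
#'   (logit scale) and `b_max`.
#' @param sigma_prop Proportional residual error SD (log scale).
#' @param agp_meanlog,agp_sdlog Lognormal AGP distribution (g/L); defaults
#'   give a 0.61 g/L geometric mean spanning roughly 0.4-0.9 g/L.
#' @param lloq,lloq_tracer Lower limits of quantification, mg/L, for the
#'   total and tracer analytes.
#' @param food_ka_mult Named multipliers on `ka` by food state (food
#'   accelerates dissolution, raising Cmax ~1.4-fold while leaving AUC
#'   unchanged).
#' @return An object of class `population_params`.
#' @export
population_params <- function(structural = structural_params(),
                              omega = c(cl_u = 0.25, v = 0.25, ka = 0.25,
                                        f = 0.25, b_max = 0.2),
                              sigma_prop = 0.10,
                              agp_meanlog = log(0.612), agp_sdlog = 0.18,
                              lloq = 0.01, lloq_tracer = 1e-5,
                              food_ka_mult = c("fasted" = 1,
                                               "light-meal" = 1.6,
                                               "moderate-fat" = 2.6,
                                               "high-fat" = 2.6)) {
  stopifnot(inherits(structural, "structural_params"), all(omega >= 0),
            sigma_prop >= 0, lloq > 0, lloq_tracer > 0)
  for (nm in c("cl_u", "v", "ka", "f", "b_max")) {
    if (!nm %in% names(omega)) omega[nm] <- 0
  }
  structure(list(structural = structural, omega = omega,
                 sigma_prop = sigma_prop, agp_meanlog = agp_meanlog,
                 agp_sdlog = agp_sdlog, lloq = lloq,
                 lloq_tracer = lloq_tracer, food_ka_mult = food_ka_mult),
            class = "population_params")
}

# deterministic per-subject substream seed below 2^31
.subject_seed <- function(root_seed, index) {
  (as.numeric(root_seed) * 48271 + index * 9973) %% 2147483647
}

#' Draw one individual's structural parameters
#'
#' Lognormal draws around the typical values (logit-normal for `f_ref`),
#' with the binding capacity scaled by the subject's AGP relative to the
#' population geometric mean. Used by [simulate_trial()] and by the
#' occupancy projector; a fixed seed makes the draw reproducible.
#'
#' @param pop A [population_params()] object.
#' @param seed Integer seed for this subject's substream.
#' @return List with `params` (a `structural_params`), `agp` (g/L) and the
#'   random effects `eta`.
#' @export
draw_individual <- function(pop, seed) {
  set.seed(seed)
  ty <- pop$structural
  om <- pop$omega
  eta <- c(cl_u = stats::rnorm(1, 0, om[["cl_u"]]),
           v = stats::rnorm(1, 0, om[["v"]]),
           ka = stats::rnorm(1, 0, om[["ka"]]),
           f = stats::rnorm(1, 0, om[["f"]]),
           b_max = stats::rnorm(1, 0, om[["b_max"]]))
  agp <- stats::rlnorm(1, pop$agp_meanlog, pop$agp_sdlog)
  agp <- min(max(agp, 0.2), 2.0)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  b <- ty$binding
  # weak AGP link: exponent 0.3 with omega_bmax 0.2 gives a Pearson
  # correlation near 0.3 between AGP and the individual binding capacity
  bi <- binding_params(
    kd_bind = b$kd_bind,
    b_max = b$b_max * (agp / exp(pop$agp_meanlog))^0.3 *
      exp(eta[["b_max"]]),
    koff_bind = b$koff_bind, mw = b$mw
  )
  pi <- structural_params(
    cl_u = ty$cl_u * exp(eta[["cl_u"]]),
    v = ty$v * exp(eta[["v"]]),
    ka = ty$ka * exp(eta[["ka"]]),
    t_lag = ty$t_lag,
    f_ref = inv_logit(logit(ty$f_ref) + eta[["f"]]),
    d50 = ty$d50, binding = bi
  )
  list(params = pi, agp = agp, eta = eta)
}

# dose events for one subject/period of an arm (times in h from first dose)
.arm_dose_times <- function(regimen, tau, treatment_days) {
  switch(regimen,
         single = 0,
         split = c(0, 12),
         QD = seq(0, by = 24, length.out = treatment_days),
         BID = seq(0, by = 12, length.out = 2 * treatment_days),
         stop("unknown regimen: ", regimen))
}

#' Simulate a phase-1 trial dataset
#'
#' Forward-simulates the structural model for every subject of a design:
#' draws individual parameters from the population distributions (one
#' deterministic substream per subject, so enlarging the trial does not
#' perturb existing subjects), integrates the model over the arm's dosing
#' schedule, samples at the design's schedule, applies lognormal
#' proportional residual error and censors below the LLOQ (censored records
#' keep `dv = NA` with `blq = TRUE`). Placebo subjects contribute all-BLQ
#' records. For the MAD design the schedule covers the first dose, daily
#' troughs, and the final dose with terminal follow-up; for the FE design
#' each subject is simulated in all three periods (identical individual
#' parameters, food-dependent absorption rate) and the intravenous
#' microtracer is co-simulated in the fasted period as analyte `"tracer"`.
#'
#' @param design A [make_design()] object.
#' @param pop A [population_params()] object.
#' @param seed Integer root seed (mandatory).
#' @return A validated [trial_dataset()].
#' @export
simulate_trial <- function(design, pop, seed) {
  stopifnot(inherits(design, "trial_design"),
            inherits(pop, "population_params"))
  if (missing(seed)) stop("seed is mandatory")
  subjects <- list(); doses <- list(); obs <- list()
  subj_idx <- 0
  add <- function(lst, x) c(lst, list(x))

  for (a in seq_len(nrow(design$arms))) {
    arm <- design$arms[a, ]
    for (k in seq_len(arm$n_active + arm$n_placebo)) {
      subj_idx <- subj_idx + 1
      active <- k <= arm$n_active
      id <- sprintf("%s-%02d", design$study, subj_idx)
      ind <- draw_individual(pop, .subject_seed(seed, subj_idx))
      sequence <- NA_character_

      if (design$study == "FE") {
        # two-sequence crossover; periods 1-2 fasted/HF by sequence, 3 MF
        sequence <- if (subj_idx %% 2 == 1) "fasted-HF-MF" else "HF-fasted-MF"
        foods <- if (sequence == "fasted-HF-MF") {
          c("fasted", "high-fat", "moderate-fat")
        } else {
          c("high-fat", "fasted", "moderate-fat")
        }
        for (per in 1:3) {
          food <- foods[per]
          dd <- data.frame(id = id, period = as.character(per), time = 0,
                           amt = arm$dose, route = "oral",
                           formulation = "tablet", food = food,
                           regimen = "120 mg single",
                           stringsAsFactors = FALSE)
          with_tracer <- food == "fasted" && !is.na(design$iv_tracer_mg)
          if (with_tracer) {
            # the microtracer rides on the oral dose and shares its
            # binding environment; simulate the two species jointly
            both <- .simulate_fe_fasted(
              ind, pop, oral_dose = arm$dose,
              tracer_dose = design$iv_tracer_mg,
              sampling_oral = design$sampling,
              sampling_tracer = sort(unique(c(0.083, 0.25,
                                              design$sampling[-1]))),
              active = active,
              seed_total = .subject_seed(seed, subj_idx * 10 + per),
              seed_tracer = .subject_seed(seed, subj_idx * 10 + 9))
            oo <- both$total
            ot <- both$tracer
          } else {
            oo <- .simulate_period(ind, pop, dose_times = 0,
                                   amt = arm$dose, route = "oral",
                                   food = food,
                                   sampling = design$sampling,
                                   active = active, analyte = "total",
                                   seed = .subject_seed(seed,
                                                        subj_idx * 10 + per))
          }
          oo$id <- id; oo$period <- as.character(per)
          doses <- add(doses, dd); obs <- add(obs, oo)
          if (with_tracer) {
            dd_iv <- data.frame(id = id, period = as.character(per),
                                time = 0, amt = design$iv_tracer_mg,
                                route = "iv", formulation = "iv-tracer",
                                food = food, regimen = "0.1 mg IV",
                                stringsAsFactors = FALSE)
            ot$id <- id; ot$period <- as.character(per)
            doses <- add(doses, dd_iv); obs <- add(obs, ot)
          }
        }
      } else {
        dose_times <- .arm_dose_times(arm$regimen, arm$tau,
                                      arm$treatment_days)
        samp <- .study_sampling(design, arm, dose_times)
        per_event_amt <- if (arm$regimen == "split") arm$dose / 2 else
          arm$dose
        dd <- data.frame(id = id, period = "1", time = dose_times,
                         amt = per_event_amt,
                         route = arm$route, formulation = arm$formulation,
                         food = arm$food, regimen = arm$arm,
                         stringsAsFactors = FALSE)
        oo <- .simulate_period(ind, pop, dose_times = dose_times,
                               amt = dd$amt[1], route = arm$route,
                               food = arm$food, sampling = samp,
                               active = active, analyte = "total",
                               seed = .subject_seed(seed, subj_idx * 10 + 1))
        oo$id <- id; oo$period <- "1"
        doses <- add(doses, dd); obs <- add(obs, oo)
      }
      subjects <- add(subjects, data.frame(
        id = id, agp = ind$agp, arm = arm$arm,
        sequence = sequence, active = active, stringsAsFactors = FALSE))
    }
  }
  trial_dataset(
    subjects = do.call(rbind, subjects),
    doses = do.call(rbind, doses),
    obs = do.call(rbind, obs),
    design = list(study = design$study,
                  washout_days = design$washout_days)
  )
}

# sampling times for a subject/period given the dosing schedule
.study_sampling <- function(design, arm, dose_times) {
  rich <- design$sampling
  if (length(dose_times) == 1) return(rich)
  tau <- arm$tau
  last <- max(dose_times)
  if (arm$regimen == "split") {
    return(sort(unique(c(rich[rich <= 12], 12 + rich[rich <= 12], 36, 48,
                         72, 96))))
  }
  first <- rich[rich <= tau]
  troughs <- dose_times[-1]
  final <- last + rich
  sort(unique(c(first, troughs, final)))
}

# fasted FE period: oral dose with co-administered IV microtracer, both
# analytes from one joint simulation
.simulate_fe_fasted <- function(ind, pop, oral_dose, tracer_dose,
                                sampling_oral, sampling_tracer, active,
                                seed_total, seed_tracer) {
  censor <- function(conc, sampling, lloq, analyte, sd_seed) {
    set.seed(sd_seed)
    dv <- conc * exp(stats::rnorm(length(conc), 0, pop$sigma_prop))
    blq <- dv < lloq
    dv[blq] <- NA_real_
    data.frame(time = sampling, dv = dv, analyte = analyte, lloq = lloq,
               blq = blq, stringsAsFactors = FALSE)
  }
  if (!active) {
    return(list(
      total = data.frame(time = sampling_oral, dv = NA_real_,
                         analyte = "total", lloq = pop$lloq, blq = TRUE,
                         stringsAsFactors = FALSE),
      tracer = data.frame(time = sampling_tracer, dv = NA_real_,
                          analyte = "tracer", lloq = pop$lloq_tracer,
                          blq = TRUE, stringsAsFactors = FALSE)))
  }
  grid <- sort(unique(c(0, sampling_oral, sampling_tracer)))
  prof <- simulate_tracer_profile(ind$params, oral_dose, tracer_dose,
                                  grid)
  list(
    total = censor(prof$c_total[match(sampling_oral, prof$time)],
                   sampling_oral, pop$lloq, "total", seed_total),
    tracer = censor(prof$c_total_tracer[match(sampling_tracer,
                                              prof$time)],
                    sampling_tracer, pop$lloq_tracer, "tracer",
                    seed_tracer))
}

# simulate one subject/period; returns obs data frame (id/period added by
# caller)
.simulate_period <- function(ind, pop, dose_times, amt, route, food,
                             sampling, active, analyte, seed) {
  lloq <- if (analyte == "tracer") pop$lloq_tracer else pop$lloq
  if (!active) {
    return(data.frame(time = sampling, dv = NA_real_, analyte = analyte,
                      lloq = lloq, blq = TRUE, stringsAsFactors = FALSE))
  }
  p <- ind$params
  if (route == "oral") {
    mult <- pop$food_ka_mult[[food]]
    if (is.null(mult) || is.na(mult)) mult <- 1
    p <- structural_params(cl_u = p$cl_u, v = p$v, ka = p$ka * mult,
                           t_lag = p$t_lag, f_ref = p$f_ref, d50 = p$d50,
                           binding = p$binding)
  }
  dosedf <- data.frame(time = dose_times, amt = amt, route = route)
  grid <- sort(unique(c(0, sampling)))
  prof <- tryCatch(
    simulate_profile(p, dosedf, grid),
    error = function(e) stop("simulation failed for a subject dosed '",
                             amt, " mg ", route, "': ",
                             conditionMessage(e))
  )
  conc <- prof$c_total[match(sampling, prof$time)]
  set.seed(seed)
  eps <- stats::rnorm(length(conc), 0, pop$sigma_prop)
  dv <- conc * exp(eps)
  blq <- dv < lloq
  dv[blq] <- NA_real_
  data.frame(time = sampling, dv = dv, analyte = analyte, lloq = lloq,
             blq = blq, stringsAsFactors = FALSE)
}
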