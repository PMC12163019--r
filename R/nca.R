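#' Terminal slope (lambda-z) estimation
#'
#' Log-linear regression on the terminal portion of a concentration-time
#' profile. Candidate windows are all contiguous terminal sets of at least
#' three positive, quantified concentrations strictly after tmax; the window
#' with the best adjusted R-squared is selected (ties within 1e-4 go to the
#' longer window, which also favours spans of at least two half-lives when
#' the data allow). Returns a "not estimable" result when fewer than three
#' usable points exist or the fitted slope is nonnegative.
#'
#' @param time Sample times, h.
#' @param conc Concentrations, mg/L (`NA` rows dropped).
#' @return List with `lambda_z` (1/h), `t_half` (h), `n_points`, `r2_adj`,
#'   `span` (h), `intercept` (log scale) and `estimable` (logical).
#' @export
fit_lambda_z <- function(time, conc) {
  keep <- !is.na(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  not_estimable <- list(lambda_z = NA_real_, t_half = NA_real_,
                        n_points = 0L, r2_adj = NA_real_, span = NA_real_,
                        intercept = NA_real_, estimable = FALSE)
  if (length(conc) < 3) return(not_estimable)
  i_max <- which.max(conc)
  idx <- seq_along(time)
  idx <- idx[idx > i_max]                  # strictly after tmax
  n <- length(idx)
  if (n < 3) return(not_estimable)
  best <- NULL
  for (k in 3:n) {
    w <- idx[(n - k + 1):n]
    lt <- time[w]; lc <- log(conc[w])
    fit <- stats::lm.fit(cbind(1, lt), lc)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum(fit$residuals^2)
    tss <- sum((lc - mean(lc))^2)
    if (tss <= 0) next
    r2a <- 1 - (rss / (k - 2)) / (tss / (k - 1))
    if (is.null(best) || r2a > best$r2_adj + 1e-4 ||
        (abs(r2a - best$r2_adj) <= 1e-4 && k > best$n_points)) {
      best <- list(lambda_z = unname(-slope),
                   t_half = unname(log(2) / -slope),
                   n_points = k, r2_adj = r2a,
                   span = max(lt) - min(lt),
                   intercept = unname(fit$coefficients[1]),
                   estimable = TRUE)
    }
  }
  if (is.null(best)) return(not_estimable)
  best
}

#' Trapezoidal AUC and AUMC over observed samples
#'
#' `"lin-up-log-down"` (the pharmacopeial default) uses the linear trapezoid
#' on rising or equal segments and the logarithmic trapezoid on declining
#' segments with both endpoints positive; `"linear"` uses the linear
#' trapezoid throughout. AUMC uses the matching exact log-segment moment
#' formula on log-down segments and the trapezoid on t*C otherwise.
#'
#' @param time Sample times, h (increasing).
#' @param conc Concentrations, mg/L (`NA` rows dropped).
#' @param method `"lin-up-log-down"` or `"linear"`.
#' @return List with `auc` and `aumc`.
#' @export
auc_trapezoid <- function(time, conc, method = c("lin-up-log-down",
                                                 "linear")) {
  method <- match.arg(method)
  keep <- !is.na(conc)
  time <- time[keep]; conc <- conc[keep]
  stopifnot(!is.unsorted(time, strictly = TRUE))
  auc <- 0; aumc <- 0
  for (i in seq_len(length(time) - 1)) {
    t1 <- time[i]; t2 <- time[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
    dt <- t2 - t1
    logdown <- method == "lin-up-log-down" && c1 > c2 && c2 > 0
    if (logdown) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Single-dose noncompartmental analysis
#'
#' Computes the standard single-dose parameter set: AUC(0-tlast) and
#' AUC(0-inf) (linear-up/log-down trapezoid plus `C_last/lambda_z`
#' extrapolation), Cmax/tmax, terminal slope and half-life, apparent
#' clearance `dose/AUC_inf` and terminal volume `CL/lambda_z`, mean
#' residence time `AUMC_inf/AUC_inf`, and, for intravenous bolus dosing,
#' `Vss = CL * MRT`. For IV profiles without a sample at t = 0 the
#' concentration at zero is back-extrapolated log-linearly from the first
#' two samples before integration. When the terminal slope is not estimable
#' the extrapolated quantities are returned as `NA`.
#'
#' @param time,conc Profile samples (h, mg/L); `NA` concentrations excluded.
#' @param dose Administered dose, mg.
#' @param route `"oral"` or `"iv"`.
#' @param method AUC interpolation rule, see [auc_trapezoid()].
#' @return One-row data frame of class `nca_result`.
#' @export
nca_single <- function(time, conc, dose, route = c("oral", "iv"),
                       method = "lin-up-log-down") {
  route <- match.arg(route)
  stopifnot(dose > 0)
  keep <- !is.na(conc)
  time <- time[keep]; conc <- conc[keep]
  if (route == "iv" && length(time) >= 2 && time[1] > 0 &&
      conc[1] > conc[2] && conc[2] > 0) {
    k01 <- log(conc[1] / conc[2]) / (time[2] - time[1])
    c0 <- conc[1] * exp(k01 * time[1])
    time <- c(0, time); conc <- c(c0, conc)
  }
  lz <- fit_lambda_z(time, conc)
  tr <- auc_trapezoid(time, conc, method = method)
  i_max <- which.max(conc)
  c_last <- conc[length(conc)]
  t_last <- time[length(time)]
  auc_inf <- aumc_inf <- extrap <- cl_f <- vz_f <- mrt <- vss <- NA_real_
  if (lz$estimable) {
    auc_inf <- tr$auc + c_last / lz$lambda_z
    aumc_inf <- tr$aumc + t_last * c_last / lz$lambda_z +
      c_last / lz$lambda_z^2
    extrap <- 100 * (auc_inf - tr$auc) / auc_inf
    cl_f <- dose / auc_inf
    vz_f <- cl_f / lz$lambda_z
    mrt <- aumc_inf / auc_inf
    if (route == "iv") vss <- cl_f * mrt
    if (extrap > 20) {
      warning(sprintf("extrapolated AUC fraction %.1f%% exceeds 20%%",
                      extrap))
    }
  }
  out <- data.frame(
    auc_0_t = tr$auc, auc_inf = auc_inf, extrapolated_fraction = extrap,
    cmax = conc[i_max], tmax = time[i_max], lambda_z = lz$lambda_z,
    t_half = lz$t_half, lambda_z_n = lz$n_points, lambda_z_r2 = lz$r2_adj,
    cl_f = cl_f, vz_f = vz_f, mrt = mrt, vss = vss, route = route,
    dose = dose
  )
  class(out) <- c("nca_result", "data.frame")
  out
}

#' Multiple-dose (steady-state) noncompartmental analysis
#'
#' Interval metrics over one steady-state dosing interval, with accumulation
#' ratios against the matching single-dose profile when supplied:
#' `AUC_tau` (interpolating the concentration at `tau` log-linearly when the
#' interval end is not sampled), `Cav = AUC_tau/tau`, `Cmax`/`Cmin` within
#' the interval (Cmin is the interval minimum, not only the trough sample),
#' peak-trough fluctuation `PTF = 100*(Cmax - Cmin)/Cav`, apparent clearance
#' `dose/AUC_tau`, `RA_AUC = AUC_tau,ss / AUC_tau,sd`,
#' `RA_Cmax = Cmax,ss / Cmax,sd`, and the linearity factor
#' `R_LIN = AUC_tau,ss / AUC_inf,sd`.
#'
#' @param time_ss,conc_ss Steady-state interval samples (time 0..tau since
#'   the last dose).
#' @param dose Dose per administration, mg.
#' @param tau Dosing interval, h.
#' @param sd_result Optional single-dose [nca_single()] result for `R_LIN`.
#' @param time_sd,conc_sd Optional single-dose profile (same dose and
#'   sampling convention) from which `AUC_tau,sd` and `Cmax,sd` are taken for
#'   the accumulation ratios.
#' @param method AUC interpolation rule.
#' @return List with `nca` (one-row data frame) and `accumulation` (one-row
#'   data frame with `ra_auc`, `ra_cmax`, `r_lin`, or `NULL` when no
#'   single-dose input was given).
#' @export
nca_multiple <- function(time_ss, conc_ss, dose, tau, sd_result = NULL,
                         time_sd = NULL, conc_sd = NULL,
                         method = "lin-up-log-down") {
  stopifnot(dose > 0, tau > 0)
  keep <- !is.na(conc_ss)
  tt <- time_ss[keep]; cc <- conc_ss[keep]
  if (max(tt) < tau) {
    stop("steady-state interval not fully sampled: last sample at ",
         max(tt), " h < tau = ", tau, " h")
  }
  clip <- .clip_interval(tt, cc, tau)
  tr <- auc_trapezoid(clip$time, clip$conc, method = method)
  auc_tau <- tr$auc
  cav <- auc_tau / tau
  cmax <- max(clip$conc); cmin <- min(clip$conc)
  ptf <- 100 * (cmax - cmin) / cav
  out <- data.frame(
    auc_tau = auc_tau, c_av = cav, cmax = cmax, cmin = cmin,
    tmax = clip$time[which.max(clip$conc)], ptf = ptf,
    cl_f = dose / auc_tau, dose = dose, tau = tau
  )
  acc <- NULL
  if (!is.null(time_sd)) {
    keep <- !is.na(conc_sd)
    ts <- time_sd[keep]; cs <- conc_sd[keep]
    if (max(ts) < tau) {
      stop("single-dose profile does not cover one dosing interval (tau = ",
           tau, " h)")
    }
    sd_clip <- .clip_interval(ts, cs, tau)
    auc_tau_sd <- auc_trapezoid(sd_clip$time, sd_clip$conc,
                                method = method)$auc
    cmax_sd <- max(sd_clip$conc)
    r_lin <- if (!is.null(sd_result)) auc_tau / sd_result$auc_inf
             else NA_real_
    acc <- data.frame(ra_auc = auc_tau / auc_tau_sd,
                      ra_cmax = cmax / cmax_sd, r_lin = r_lin)
  } else if (!is.null(sd_result)) {
    acc <- data.frame(ra_auc = NA_real_, ra_cmax = NA_real_,
                      r_lin = auc_tau / sd_result$auc_inf)
  }
  list(nca = out, accumulation = acc)
}

# restrict a profile to [0, tau], log-linearly interpolating at tau
.clip_interval <- function(time, conc, tau) {
  inside <- time <= tau
  tt <- time[inside]; cc <- conc[inside]
  if (max(tt) < tau) {
    i <- max(which(inside)); j <- i + 1
    c_tau <- if (conc[i] > 0 && conc[j] > 0 && conc[j] < conc[i]) {
      exp(log(conc[i]) + (log(conc[j]) - log(conc[i])) *
            (tau - time[i]) / (time[j] - time[i]))
    } else {
      conc[i] + (conc[j] - conc[i]) * (tau - time[i]) / (time[j] - time[i])
    }
    tt <- c(tt, tau); cc <- c(cc, c_tau)
  }
  list(time = tt, conc = cc)
}

#' Theoretical accumulation ratio under linear superposition
#'
#' Expected AUC accumulation ratio at steady state for a drug with
#' mono-exponential terminal decline, `1 / (1 - 2^(-tau/t_half))`. With a
#' 26 h half-life and 12 h (twice-daily) dosing this evaluates to 3.65; the
#' observed accumulation of a compound with capacity-limited plasma binding
#' falls short of this linear prediction.
#'
#' @param t_half Terminal half-life, h (> 0).
#' @param tau Dosing interval, h (> 0).
#' @return The accumulation ratio (> 1).
#' @export
theoretical_accumulation <- function(t_half, tau) {
  if (any(t_half <= 0) || any(tau <= 0)) {
    stop("t_half and tau must be positive")
  }
  1 / (1 - 2^(-tau / t_half))
}

#' Run single-dose NCA over every subject/period of a dataset
#'
#' Convenience wrapper applying [nca_single()] per subject, period and
#' analyte of a [trial_dataset()] (after any BLQ policy has been applied).
#' Periods with multiple dose events within 24 h (split dosing) are analysed
#' as one 24 h interval dosed with the total amount; multi-day regimens are
#' skipped (use [nca_multiple()] with explicit profiles).
#'
#' @param x A `trial_dataset`.
#' @param analyte Analyte to analyse (default `"total"`).
#' @param method AUC interpolation rule.
#' @return Data frame with one row per subject/period.
#' @export
nca_dataset <- function(x, analyte = "total", method = "lin-up-log-down") {
  o <- usable_records(x)
  o <- o[o$analyte == analyte, , drop = FALSE]
  res <- list()
  for (key in unique(paste(o$id, o$period, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    id <- parts[1]; per <- parts[2]
    oo <- o[o$id == id & o$period == per, , drop = FALSE]
    dd <- x$doses[x$doses$id == id & x$doses$period == per, , drop = FALSE]
    if (!nrow(dd) || nrow(oo) < 3) next
    if (max(dd$time) - min(dd$time) > 24) next   # multi-day regimen
    dose <- sum(dd$amt)
    route <- if (all(dd$route == "iv")) "iv" else "oral"
    post <- oo$time >= min(dd$time)
    r <- nca_single(oo$time[post], oo$dv[post], dose = dose, route = route,
                    method = method)
    r$id <- id; r$period <- per; r$analyte <- analyte
    res[[key]] <- r
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
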