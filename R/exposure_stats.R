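#' Build a ratio estimate
#' @noRd
.ratio_estimate <- function(label, point, lo, hi, cv, n) {
  out <- data.frame(label = label, point = point, ci90_low = lo,
                    ci90_high = hi, cv_geom = cv, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimate", "data.frame")
  out
}

#' Geometric mean ratio with 90% confidence interval
#'
#' Log-scale analysis of two positive exposure samples. Paired (within
#' subject): the point estimate is `exp(mean(log a - log b))` -- identically
#' the ratio of geometric means -- with a t-interval on the paired log
#' differences; the geometric CV is derived from the intra-subject residual
#' variance `var(d)/2` (the crossover-ANOVA residual in a balanced
#' two-treatment design). Unpaired: two-sample t-interval on log means with
#' pooled variance.
#'
#' @param values_a,values_b Positive exposure values (numerator /
#'   denominator arm). Paired analysis requires equal lengths with aligned
#'   subjects.
#' @param paired Within-subject contrast? Default TRUE.
#' @param conf Confidence level (default 0.90).
#' @param label Contrast label, e.g. `"HF/fasted"`.
#' @return A one-row `ratio_estimate` data frame with `point`, `ci90_low`,
#'   `ci90_high`, `cv_geom` (%) and `n`.
#' @export
gmr <- function(values_a, values_b, paired = TRUE, conf = 0.90,
                label = "a/b") {
  if (any(values_a <= 0) || any(values_b <= 0)) {
    stop("gmr requires strictly positive values")
  }
  if (paired) {
    if (length(values_a) != length(values_b)) {
      stop("paired gmr requires equal-length, subject-aligned vectors")
    }
    n <- length(values_a)
    if (n < 2) stop("need at least 2 pairs")
    d <- log(values_a) - log(values_b)
    m <- mean(d); se <- stats::sd(d) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    s2 <- stats::var(d) / 2
  } else {
    na <- length(values_a); nb <- length(values_b)
    if (na < 2 || nb < 2) stop("need at least 2 values per arm")
    la <- log(values_a); lb <- log(values_b)
    s2 <- ((na - 1) * stats::var(la) + (nb - 1) * stats::var(lb)) /
      (na + nb - 2)
    m <- mean(la) - mean(lb)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    tq <- stats::qt(1 - (1 - conf) / 2, df = na + nb - 2)
    n <- min(na, nb)
  }
  .ratio_estimate(label, exp(m), exp(m - tq * se), exp(m + tq * se),
                  100 * sqrt(exp(s2) - 1), n)
}

#' Dose-normalized exposure ratio between two dose groups
#'
#' Ratio of geometric means of dose-normalized parameters (high dose over
#' low dose) with a two-sample 90% t-interval on the log scale; equals the
#' one-way-ANOVA least-squares-mean ratio in the balanced case. A ratio of 1
#' indicates dose-proportional exposure.
#'
#' @param param_high,param_low Positive parameter values per group.
#' @param dose_high,dose_low Doses (mg) of each group (the normalizer; for
#'   twice-daily regimens pass the daily dose).
#' @param label Contrast label.
#' @param conf Confidence level.
#' @return A one-row `ratio_estimate` data frame.
#' @export
dose_normalized_ratio <- function(param_high, dose_high, param_low,
                                  dose_low, label = NULL, conf = 0.90) {
  stopifnot(dose_high > 0, dose_low > 0)
  if (is.null(label)) label <- paste0(dose_high, " mg/", dose_low, " mg")
  gmr(param_high / dose_high, param_low / dose_low, paired = FALSE,
      conf = conf, label = label)
}

#' Dose-proportionality power model
#'
#' Ordinary least squares of `log(param)` on `log(dose)`; the slope with its
#' 90% CI characterizes proportionality (slope 1 = proportional, < 1 =
#' sub-proportional). Invariant to rescaling doses or parameters by positive
#' constants (only the intercept shifts).
#'
#' @param doses Doses, mg (at least 3 distinct values).
#' @param params Positive parameter values, same length.
#' @param conf Confidence level for the slope interval.
#' @return List with `slope`, `slope_ci90` (length-2), `intercept` and the
#'   underlying `lm` fit.
#' @export
power_model <- function(doses, params, conf = 0.90) {
  stopifnot(length(doses) == length(params))
  if (length(unique(doses)) < 3) {
    stop("power model requires at least 3 distinct dose levels")
  }
  if (any(params <= 0) || any(doses <= 0)) {
    stop("power model requires positive doses and parameters")
  }
  fit <- stats::lm(log(params) ~ log(doses))
  ci <- if (stats::df.residual(fit) > 0) {
    stats::confint(fit, "log(doses)", level = conf)
  } else {
    matrix(c(NA_real_, NA_real_), nrow = 1)
  }
  list(slope = unname(stats::coef(fit)[2]),
       slope_ci90 = unname(ci[1, ]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}

#' Absolute bioavailability from paired oral and intravenous exposure
#'
#' Per-subject `F = (AUC/D)_oral / (AUC/D)_iv`, summarized as the geometric
#' mean with a 90% t-interval on the log scale (F assumed log-normal).
#' AUC units must agree between routes: an intravenous microtracer AUC
#' printed on a µg·h/L scale must be converted to mg·h/L (or, equivalently,
#' its dose given in µg) before calling.
#'
#' @param auc_oral,auc_iv Paired per-subject AUC(0-inf) values, mg·h/L.
#' @param dose_oral,dose_iv Doses, mg.
#' @param conf Confidence level.
#' @return A one-row `ratio_estimate` data frame; `point` is the
#'   bioavailable fraction (multiply by 100 for percent).
#' @export
absolute_bioavailability <- function(auc_oral, dose_oral, auc_iv, dose_iv,
                                     conf = 0.90) {
  stopifnot(dose_oral > 0, dose_iv > 0)
  if (length(auc_oral) != length(auc_iv)) {
    stop("absolute bioavailability requires paired within-subject AUCs")
  }
  f <- (auc_oral / dose_oral) / (auc_iv / dose_iv)
  if (length(f) == 1) {
    return(.ratio_estimate("F", f, NA_real_, NA_real_, NA_real_, 1L))
  }
  n <- length(f)
  lf <- log(f)
  se <- stats::sd(lf) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  .ratio_estimate("F", exp(mean(lf)), exp(mean(lf) - tq * se),
                  exp(mean(lf) + tq * se),
                  100 * sqrt(exp(stats::var(lf)) - 1), n)
}

#' Crossover ANOVA treatment ratio
#'
#' Fixed-effects linear model on log-transformed exposure from a crossover
#' design: `log(value) ~ treatment + period + subject`. With fixed subject
#' effects in a complete, balanced crossover the treatment contrast is
#' identical to the mixed-model (random-subject) least-squares-mean
#' contrast; period effects are absorbed by design. Incomplete cells raise
#' an error naming the affected subjects rather than silently approximating.
#'
#' @param data Data frame with columns `subject`, `period`, `treatment` and
#'   `value` (positive exposure parameter). A `sequence` column, if present,
#'   is ignored in the fixed-subject parameterization (it is aliased with
#'   subject).
#' @param test Treatment level of the numerator (e.g. `"HF"`).
#' @param ref Treatment level of the denominator (e.g. `"fasted"`).
#' @param conf Confidence level.
#' @return A one-row `ratio_estimate` data frame for `test/ref`; the
#'   geometric CV is the intra-subject CV from the residual variance.
#' @export
crossover_anova <- function(data, test, ref, conf = 0.90) {
  stopifnot(all(c("subject", "period", "treatment", "value") %in%
                  names(data)))
  if (any(data$value <= 0)) stop("exposure values must be positive")
  d <- data[data$treatment %in% c(test, ref), , drop = FALSE]
  tab <- table(d$subject, d$treatment)
  incomplete <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(incomplete)) {
    stop("incomplete crossover cells for subject(s): ",
         paste(incomplete, collapse = ", "))
  }
  d$treatment <- stats::relevel(factor(d$treatment), ref = ref)
  d$subject <- factor(d$subject)
  d$period <- factor(d$period)
  fit <- stats::lm(log(value) ~ treatment + period + subject, data = d)
  cf_name <- paste0("treatment", test)
  est <- stats::coef(fit)[cf_name]
  if (is.na(est)) stop("treatment contrast not estimable")
  ci <- suppressMessages(stats::confint(fit, cf_name, level = conf))
  s2 <- stats::sigma(fit)^2
  .ratio_estimate(paste0(test, "/", ref), exp(unname(est)),
                  exp(ci[1, 1]), exp(ci[1, 2]),
                  100 * sqrt(exp(s2) - 1), nlevels(d$subject))
}
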