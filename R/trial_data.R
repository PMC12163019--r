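#' Construct a phase-1 trial dataset
#'
#' Container for one study's subjects, dose events and concentration
#' observations, in the units used throughout the package (mg, hours, mg/L).
#' Times are hours since the first dose of the current period (pre-dose
#' samples may carry negative times).
#'
#' @param subjects Data frame with columns `id` (character), optionally
#'   `agp` (plasma alpha-1-acid glycoprotein, g/L), `arm`, `sequence`.
#' @param doses Data frame with columns `id`, `period`, `time` (h),
#'   `amt` (mg), `route` (`"oral"`/`"iv"`), `formulation`, `food`,
#'   `regimen`.
#' @param obs Data frame with columns `id`, `period`, `time` (h), `dv`
#'   (mg/L; `NA` when below the quantification limit), `analyte`
#'   (`"total"`, `"unbound"` or `"tracer"`), `lloq` (mg/L), `blq` (logical).
#' @param design Optional list of design metadata (study tag, washout days).
#' @param validate Validate invariants on construction (default TRUE).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(subjects, doses, obs, design = list(),
                          validate = TRUE) {
  x <- structure(
    list(subjects = as.data.frame(subjects),
         doses = as.data.frame(doses),
         obs = as.data.frame(obs),
         design = design),
    class = "trial_dataset"
  )
  if (validate) {
    problems <- validate_trial_dataset(x)
    if (length(problems)) {
      stop("invalid trial dataset:\n", paste0("  - ", problems,
                                              collapse = "\n"))
    }
  }
  x
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>",
      if (!is.null(x$design$study)) paste0(" study: ", x$design$study), "\n",
      sep = "")
  cat("  subjects: ", nrow(x$subjects),
      " | dose events: ", nrow(x$doses),
      " | observations: ", nrow(x$obs), "\n", sep = "")
  invisible(x)
}

#' Validate a trial dataset
#'
#' Checks every invariant of the data model and returns all violations
#' (rather than stopping at the first): positive dose amounts, nonnegative
#' dose times, positive LLOQ, quantified values at or above the LLOQ,
#' physiologic AGP range (0.2-2.0 g/L) when present, every observation
#' attached to a subject/period with at least one dose event, and strictly
#' increasing sample times per subject/period/analyte.
#'
#' @param x A `trial_dataset`.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_trial_dataset <- function(x) {
  p <- character(0)
  d <- x$doses
  o <- x$obs
  bad <- which(!(d$amt > 0))
  for (i in bad) {
    p <- c(p, sprintf("dose event %d (subject %s, period %s): AMT = %s must be > 0",
                      i, d$id[i], as.character(d$period[i]),
                      format(d$amt[i])))
  }
  bad <- which(d$time < 0)
  for (i in bad) {
    p <- c(p, sprintf("dose event %d (subject %s): TIME = %s must be >= 0",
                      i, d$id[i], format(d$time[i])))
  }
  bad <- which(!(o$lloq > 0))
  for (i in bad) {
    p <- c(p, sprintf("observation %d (subject %s): LLOQ must be > 0",
                      i, o$id[i]))
  }
  bad <- which(!o$blq & !is.na(o$dv) & o$dv < o$lloq & o$dv != 0)
  for (i in bad) {
    p <- c(p, sprintf(
      "observation %d (subject %s, t = %s h): quantified DV %s below LLOQ %s",
      i, o$id[i], format(o$time[i]), format(o$dv[i]), format(o$lloq[i])))
  }
  if ("agp" %in% names(x$subjects)) {
    a <- x$subjects$agp
    bad <- which(!is.na(a) & (a < 0.2 | a > 2.0))
    for (i in bad) {
      p <- c(p, sprintf("subject %s: AGP %s g/L outside physiologic range 0.2-2.0",
                        x$subjects$id[i], format(a[i])))
    }
  }
  dose_key <- unique(paste(d$id, d$period))
  obs_key <- paste(o$id, o$period)
  orphans <- unique(obs_key[!(obs_key %in% dose_key)])
  for (k in orphans) {
    p <- c(p, sprintf("observations for subject/period '%s' have no dose event", k))
  }
  sp <- split(seq_len(nrow(o)), paste(o$id, o$period, o$analyte))
  for (k in names(sp)) {
    tt <- o$time[sp[[k]]]
    if (is.unsorted(tt, strictly = TRUE)) {
      p <- c(p, sprintf("sample times not strictly increasing for subject/period/analyte '%s'", k))
    }
  }
  p
}

# NONMEM-style column order used on disk
.nm_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "CMT", "ANALYTE",
              "FOOD", "FORM", "PERIOD", "SEQ", "LLOQ", "DOSEGRP", "AGP",
              "BLQ")

#' Write a trial dataset as a NONMEM-style CSV
#'
#' Flat CSV with columns ID, TIME, AMT, DV, EVID, MDV, CMT, ANALYTE, FOOD,
#' FORM, PERIOD, SEQ, LLOQ, DOSEGRP, AGP, BLQ. Dose rows carry EVID = 1 and
#' MDV = 1; observation rows EVID = 0. Missing DV is encoded as "." per
#' NONMEM convention. CMT is 1 for oral doses (depot) and 2 otherwise.
#'
#' @param x A `trial_dataset`.
#' @param path Output file path.
#' @param tracer_dv_unit Unit in which tracer-analyte DV/LLOQ values are
#'   written: `"mg/L"` (default, internal unit) or `"ug/L"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, tracer_dv_unit = c("mg/L", "ug/L")) {
  tracer_dv_unit <- match.arg(tracer_dv_unit)
  s <- x$subjects
  agp_of <- function(id) {
    if ("agp" %in% names(s)) s$agp[match(id, s$id)] else rep(NA_real_,
                                                             length(id))
  }
  seq_of <- function(id) {
    if ("sequence" %in% names(s)) as.character(s$sequence[match(id, s$id)])
    else rep(NA_character_, length(id))
  }
  d <- x$doses
  dose_rows <- data.frame(
    ID = d$id, TIME = d$time, AMT = d$amt, DV = NA_real_, EVID = 1L,
    MDV = 1L, CMT = ifelse(d$route == "iv", 2L, 1L), ANALYTE = "dose",
    FOOD = d$food, FORM = d$formulation, PERIOD = d$period,
    SEQ = seq_of(d$id), LLOQ = NA_real_, DOSEGRP = d$regimen,
    AGP = agp_of(d$id), BLQ = 0L, stringsAsFactors = FALSE
  )
  o <- x$obs
  scale <- ifelse(o$analyte == "tracer" & tracer_dv_unit == "ug/L", 1000, 1)
  obs_rows <- data.frame(
    ID = o$id, TIME = o$time, AMT = NA_real_, DV = o$dv * scale, EVID = 0L,
    MDV = ifelse(is.na(o$dv), 1L, 0L), CMT = 2L, ANALYTE = o$analyte,
    FOOD = NA_character_, FORM = NA_character_, PERIOD = o$period,
    SEQ = seq_of(o$id), LLOQ = o$lloq * scale, DOSEGRP = NA_character_,
    AGP = agp_of(o$id), BLQ = as.integer(o$blq), stringsAsFactors = FALSE
  )
  all_rows <- rbind(dose_rows, obs_rows)
  # stable within-subject ordering: subject, period, time, doses before obs
  ord <- order(match(all_rows$ID, unique(all_rows$ID)), all_rows$PERIOD,
               all_rows$TIME, -all_rows$EVID)
  all_rows <- all_rows[ord, .nm_cols]
  num <- vapply(all_rows, is.numeric, logical(1))
  for (j in names(all_rows)[!num]) {
    all_rows[[j]][is.na(all_rows[[j]])] <- "."
  }
  for (j in names(all_rows)[num]) {
    all_rows[[j]] <- ifelse(is.na(all_rows[[j]]), ".",
                            format(all_rows[[j]], digits = 15,
                                   scientific = FALSE, trim = TRUE))
  }
  utils::write.csv(all_rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NONMEM-style CSV into a trial dataset
#'
#' Inverse of [write_dataset()]. Malformed rows raise a parse error naming
#' the offending line; invariant violations raise a single validation error
#' listing every problem found.
#'
#' @param path CSV file path (header line mandatory).
#' @param tracer_dv_unit Unit of tracer-analyte DV/LLOQ values in the file;
#'   `"ug/L"` values are converted to mg/L on read.
#' @param design Optional design metadata list to attach.
#' @return A validated `trial_dataset`.
#' @export
read_dataset <- function(path, tracer_dv_unit = c("mg/L", "ug/L"),
                         design = list()) {
  tracer_dv_unit <- match.arg(tracer_dv_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(setdiff(.nm_cols, c("AGP", "SEQ")), names(raw))
  if (length(missing_cols)) {
    stop("malformed dataset ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  num_field <- function(col, what) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
    bad <- which(!is.na(v) & v != "." & is.na(out))
    if (length(bad)) {
      stop(sprintf("parse error in %s, line %d: %s value '%s' is not numeric",
                   path, bad[1] + 1L, what, v[bad[1]]))
    }
    out
  }
  TIME <- num_field("TIME", "TIME")
  AMT <- num_field("AMT", "AMT")
  DV <- num_field("DV", "DV")
  EVID <- num_field("EVID", "EVID")
  LLOQ <- num_field("LLOQ", "LLOQ")
  BLQ <- num_field("BLQ", "BLQ")
  AGP <- if ("AGP" %in% names(raw)) num_field("AGP", "AGP") else NA_real_
  chr <- function(col) {
    if (col %in% names(raw)) ifelse(raw[[col]] == ".", NA_character_,
                                    raw[[col]])
    else rep(NA_character_, nrow(raw))
  }

  is_dose <- EVID == 1
  doses <- data.frame(
    id = raw$ID[is_dose], period = chr("PERIOD")[is_dose],
    time = TIME[is_dose], amt = AMT[is_dose],
    route = ifelse(raw$CMT[is_dose] == "2", "iv", "oral"),
    formulation = chr("FORM")[is_dose], food = chr("FOOD")[is_dose],
    regimen = chr("DOSEGRP")[is_dose], stringsAsFactors = FALSE
  )
  io <- !is_dose
  analyte <- chr("ANALYTE")[io]
  scale <- ifelse(analyte == "tracer" & tracer_dv_unit == "ug/L", 1000, 1)
  obs <- data.frame(
    id = raw$ID[io], period = chr("PERIOD")[io], time = TIME[io],
    dv = DV[io] / scale, analyte = analyte, lloq = LLOQ[io] / scale,
    blq = BLQ[io] == 1, stringsAsFactors = FALSE
  )
  ids <- unique(raw$ID)
  subjects <- data.frame(id = ids, stringsAsFactors = FALSE)
  if ("AGP" %in% names(raw)) subjects$agp <- AGP[match(ids, raw$ID)]
  if ("SEQ" %in% names(raw)) {
    sq <- chr("SEQ")[match(ids, raw$ID)]
    if (any(!is.na(sq))) subjects$sequence <- sq
  }
  trial_dataset(subjects, doses, obs, design = design)
}

#' Apply a below-quantification-limit policy
#'
#' `"m1-pre-zero"` (default): BLQ records taken before the first dose of
#' their subject/period are set to exactly 0 (the study drug is absent
#' pre-dose after an adequate washout); BLQ records after dosing keep a
#' missing value so that AUC/terminal-slope computation excludes them, and
#' retain their `blq` flag. `"exclude-all"`: every BLQ record keeps `NA`.
#' Both policies are idempotent.
#'
#' @param x A `trial_dataset`.
#' @param rule `"m1-pre-zero"` or `"exclude-all"`.
#' @return The modified `trial_dataset`.
#' @export
apply_blq_rule <- function(x, rule = c("m1-pre-zero", "exclude-all")) {
  rule <- match.arg(rule)
  o <- x$obs
  if (rule == "m1-pre-zero" && any(o$blq)) {
    d <- x$doses
    first_dose <- tapply(d$time, paste(d$id, d$period), min)
    fd <- first_dose[paste(o$id, o$period)]
    pre <- o$blq & !is.na(fd) & o$time < fd
    o$dv[pre] <- 0
    o$dv[o$blq & !pre] <- NA_real_
  } else if (rule == "exclude-all") {
    o$dv[o$blq] <- NA_real_
  }
  x$obs <- o
  x
}

#' Usable concentration records for NCA
#'
#' Observations with a non-missing value after BLQ policy application.
#'
#' @param x A `trial_dataset`.
#' @return The `obs` data frame restricted to usable rows.
#' @export
usable_records <- function(x) {
  x$obs[!is.na(x$obs$dv), , drop = FALSE]
}
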