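#' Pipeline configuration
#'
#' Validated configuration driving [run_pipeline()]. A seed is mandatory
#' (every stochastic stage is seeded from it), and the molar mass must be
#' set whenever the occupancy stage is enabled (fail-fast, before any
#' computation).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed, mandatory.
#' @param studies Studies to simulate, subset of `c("SAD","MAD","FE")`.
#' @param stages Stages to run, subset of
#'   `c("simulate", "nca", "stats", "occupancy")` in that order.
#' @param blq_rule BLQ policy, see [apply_blq_rule()].
#' @param mw Molar mass g/mol (default from [binding_params()]); `NULL`
#'   allowed only when the occupancy stage is disabled.
#' @param pop Optional [population_params()]; defaults to the calibrated
#'   package defaults (with `mw` injected).
#' @param occ Optional [occupancy_params()].
#' @param occupancy_doses,occupancy_n Dose grid (mg) and virtual-subject
#'   count for the trough-occupancy stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            studies = c("SAD", "MAD", "FE"),
                            stages = c("simulate", "nca", "stats",
                                       "occupancy"),
                            blq_rule = "m1-pre-zero",
                            mw = binding_params()$mw,
                            pop = NULL, occ = occupancy_params(),
                            occupancy_doses = c(15, 30, 60, 120, 240, 480),
                            occupancy_n = 8) {
  if (missing(seed) || is.null(seed)) {
    stop("configuration error: seed is mandatory")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  studies <- match.arg(studies, several.ok = TRUE)
  if ("occupancy" %in% stages && (is.null(mw) || !is.finite(mw) ||
                                  mw <= 0)) {
    stop("configuration error: molar mass (mw) must be set when the ",
         "occupancy stage is enabled")
  }
  if (is.null(pop)) {
    binding <- binding_params(mw = if (is.null(mw)) 480 else mw)
    pop <- population_params(structural = structural_params(
      binding = binding))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 studies = studies, stages = stages, blq_rule = blq_rule,
                 mw = mw, pop = pop, occ = occ,
                 occupancy_doses = occupancy_doses,
                 occupancy_n = occupancy_n),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar options (`out_dir`, `seed`, `studies`, `stages`,
#' `blq_rule`, `mw`, `occupancy_doses`, `occupancy_n`) from a YAML file and
#' builds a [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("out_dir", "seed", "studies", "stages",
                                  "blq_rule", "mw", "occupancy_doses",
                                  "occupancy_n"))]
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order -- simulate the configured studies,
#' noncompartmental analysis of single-dose profiles, exposure statistics
#' (dose-proportionality power model from the SAD arms; food-effect ratios
#' and absolute bioavailability from the FE study), and the dose versus
#' steady-state trough-occupancy table. Each stage writes its outputs to
#' distinct CSV files under `config$out_dir` and never mutates another
#' stage's inputs; progress is logged to stderr. Fully deterministic for a
#' fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data frame (`file`, `md5`) also written
#'   to `manifest.csv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log_ <- function(...) message("[run_pipeline] ", ...)
  datasets <- list()

  if ("simulate" %in% config$stages) {
    for (st in config$studies) {
      log_("simulating ", st, " study")
      ds <- simulate_trial(make_design(st), config$pop, seed = config$seed)
      ds <- apply_blq_rule(ds, config$blq_rule)
      f <- file.path(config$out_dir, paste0(tolower(st), ".csv"))
      write_dataset(ds, f)
      datasets[[st]] <- ds
      outputs <- c(outputs, f)
    }
  }

  nca_tabs <- list()
  if ("nca" %in% config$stages && length(datasets)) {
    for (st in names(datasets)) {
      log_("NCA on ", st)
      tab <- nca_dataset(datasets[[st]])
      if (is.null(tab)) next
      f <- file.path(config$out_dir, paste0("nca_", tolower(st), ".csv"))
      utils::write.csv(tab, f, row.names = FALSE)
      nca_tabs[[st]] <- tab
      outputs <- c(outputs, f)
    }
  }

  if ("stats" %in% config$stages && length(nca_tabs)) {
    log_("exposure statistics")
    stats_rows <- list()
    if (!is.null(nca_tabs$SAD)) {
      tab <- nca_tabs$SAD
      ok <- !is.na(tab$auc_inf)
      if (sum(ok) >= 3) {
        pm <- power_model(tab$dose[ok], tab$auc_inf[ok])
        stats_rows$power <- data.frame(
          label = "AUC power-model slope", point = pm$slope,
          ci90_low = pm$slope_ci90[1], ci90_high = pm$slope_ci90[2],
          cv_geom = NA_real_, n = sum(ok))
      }
    }
    if (!is.null(nca_tabs$FE) && !is.null(datasets$FE)) {
      fe <- .fe_exposure_table(datasets$FE, nca_tabs$FE)
      if (!is.null(fe$hf)) stats_rows$cmax_hf <- fe$hf
      if (!is.null(fe$mf)) stats_rows$cmax_mf <- fe$mf
      if (!is.null(fe$f_abs)) stats_rows$f_abs <- fe$f_abs
    }
    if (length(stats_rows)) {
      f <- file.path(config$out_dir, "stats.csv")
      utils::write.csv(do.call(rbind, stats_rows), f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }

  if ("occupancy" %in% config$stages) {
    log_("steady-state trough occupancy projection")
    occ_tab <- trough_occupancy_curve(
      config$occupancy_doses, c("QD", "BID"), config$pop, config$occ,
      n_subjects = config$occupancy_n, seed = config$seed)
    f <- file.path(config$out_dir, "occupancy.csv")
    utils::write.csv(occ_tab, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest,
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_("done in ", format(round(difftime(Sys.time(), t0, units = "secs"),
                                1)))
  invisible(manifest)
}

# food-effect / absolute-bioavailability statistics from an FE dataset
.fe_exposure_table <- function(ds, nca_tab) {
  s <- ds$subjects
  d <- ds$doses[ds$doses$route == "oral", ]
  key <- paste(nca_tab$id, nca_tab$period)
  food <- d$food[match(key, paste(d$id, d$period))]
  df <- data.frame(subject = nca_tab$id, period = nca_tab$period,
                   treatment = food, cmax = nca_tab$cmax,
                   auc = nca_tab$auc_inf, stringsAsFactors = FALSE)
  out <- list()
  cx <- df[!is.na(df$treatment), ]
  cx$value <- cx$cmax
  if (all(c("high-fat", "fasted") %in% cx$treatment)) {
    out$hf <- tryCatch(crossover_anova(cx, "high-fat", "fasted"),
                       error = function(e) NULL)
    out$mf <- tryCatch(crossover_anova(cx, "moderate-fat", "fasted"),
                       error = function(e) NULL)
  }
  # absolute F: oral fasted vs tracer in the same (fasted) period
  tr <- nca_dataset(ds, analyte = "tracer")
  if (!is.null(tr)) {
    fa <- df[df$treatment == "fasted", ]
    m <- match(fa$subject, tr$id)
    ok <- !is.na(m) & !is.na(fa$auc) & !is.na(tr$auc_inf[m])
    if (sum(ok) >= 2) {
      out$f_abs <- absolute_bioavailability(
        fa$auc[ok], 120, tr$auc_inf[m][ok], 0.100)
    }
  }
  for (nm in names(out)) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}
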