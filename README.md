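# zabedopk

Phase-1 pharmacokinetic (PK) and target-occupancy analysis for
zabedosertib, an oral IRAK4 (interleukin-1 receptor-associated kinase 4)
inhibitor in development for immune-mediated inflammatory disease.

Early-phase programs for this compound face three linked nonlinearities:
exposure rises **under-proportionally** with dose, multiple-dose
accumulation (observed 1.1–1.7) falls far short of the
`1/(1 − 2^(−τ/t½)) ≈ 3.65` predicted from the ~26 h terminal half-life
under twice-daily dosing, and the unbound fraction in plasma **increases**
with concentration. `zabedopk` packages the full analysis chain that
handles this behavior, for pharmacometricians and clinical pharmacologists
who want a tested, reproducible desk-scale implementation:

* **Trial data**: a NONMEM-style CSV interchange format (ID, TIME, AMT,
  DV, EVID, …) with validation that reports every violation, and
  below-limit-of-quantification policies (`m1-pre-zero`, `exclude-all`).
* **Synthetic trials**: a seeded generator for the three emulated designs
  — single ascending dose (5–480 mg), multiple ascending dose (45/120 mg
  QD, 60/120/200 mg BID × 10 days), and a three-period food-effect /
  absolute-bioavailability crossover (120 mg with a 0.100 mg IV
  microtracer co-administered on top of the fasted oral dose, sharing its
  plasma-binding environment).
* **NCA**: best-adjusted-R² terminal-slope selection, linear-up/log-down
  AUC/AUMC, multiple-dose metrics (`Cav`, PTF, `RA_AUC`, `R_LIN`) and the
  closed-form linear accumulation prediction.
* **Exposure statistics**: geometric mean ratios with 90% t-based CIs,
  dose-normalized ratios, the dose-proportionality power model, crossover
  food-effect ANOVA (fixed subject/period/treatment effects), absolute
  bioavailability `F = (AUC/D)_oral / (AUC/D)_IV`.
* **Structural model**: one-compartment disposition, first-order
  absorption, elimination acting on unbound drug, dose-dependent
  bioavailability `F(D) = f_ref(1 + 120/d50)/(1 + D/d50)`, and
  capacity-limited *kinetic* plasma binding
  (`Kd = 0.4 µM`, `Bmax = 14.9 µM`, 12 h dissociation half-life):

  `dCu/dt = ka·A/V − (CLu/V)·Cu − kon·Cu·(Bmax − CB) + koff·CB`,
  `dCB/dt = kon·Cu·(Bmax − CB) − koff·CB`, `C_total = Cu + CB`.
* **Population fitting**: per-subject log-scale least squares with
  multistart and a simulate-then-fit recovery qualification.
* **IRAK4 occupancy**: sigmoid-Emax IC50 estimation from whole-blood IL-6
  inhibition data (IC50 86 nM, 95% CI 60–122 nM), kinetic target binding
  `dTO/dt = kon_T·Cu(t)·(1 − TO) − koff_T·TO` with a ~5 min residence
  time, and dose → steady-state trough-occupancy curves with
  IC50-uncertainty bands.

The clinical datasets behind the program are confidential; the package's
generator reproduces their statistical structure, and the published
geometric-mean parameters serve as calibration anchors (see the methods
vignette, `vignettes/zabedopk-methods.Rmd`, including the documented
molar-mass assumption of 390 g/mol that all molar-scale results are
conditional on).

## Worked example

```r
library(zabedopk)

# simulate the food-effect / absolute-bioavailability study
ds  <- simulate_trial(make_design("FE"), population_params(), seed = 42)
ds  <- apply_blq_rule(ds, "m1-pre-zero")

# noncompartmental analysis of the oral and tracer profiles
nca    <- nca_dataset(ds, analyte = "total")
tracer <- nca_dataset(ds, analyte = "tracer")

# absolute bioavailability: oral fasted vs IV microtracer, same subjects
food   <- ds$doses$food[match(paste(nca$id, nca$period),
                              paste(ds$doses$id, ds$doses$period))]
fasted <- nca[food == "fasted", ]
f_abs  <- absolute_bioavailability(
  fasted$auc_inf, 120,
  tracer$auc_inf[match(fasted$id, tracer$id)], 0.100)
print(f_abs, digits = 3)
#>   label point ci90_low ci90_high cv_geom  n
#> 1     F 0.647    0.608     0.688    10.6 10
```

The simulated trial was generated with a true bioavailability of 0.739 at
120 mg, but the total-concentration microtracer ratio reads ~0.65: the IV
bolus spends part of its residence in the *unsaturated* binding regime
(before oral absorption and in the late tail), inflating its total AUC
relative to the gradually absorbed oral dose. The model thus quantifies a
methodological bias that time-varying plasma binding imposes on
total-concentration bioavailability estimates — unbound-concentration
ratios would not carry it.

```r
# accumulation: linear prediction vs the capacity-limited model
theoretical_accumulation(t_half = 26, tau = 12)
#> [1] 3.652453
ss <- steady_state_profile(structural_params(), dose = 120, tau = 12)
ss$auc_tau / ss$auc_tau_first
#> [1] 1.944478
```

A 26 h half-life dosed every 12 h predicts 3.65-fold accumulation under
linear superposition; the capacity-limited binding model accumulates only
~1.9-fold at 120 mg BID, reproducing the central observed nonlinearity
(higher doses accumulate even less).

```r
# projected steady-state IRAK4 trough occupancy
occ <- trough_occupancy_curve(c(120, 240), c("QD", "BID"),
                              population_params(), occupancy_params(),
                              n_subjects = 12, seed = 42)
print(occ, digits = 2)
#>   dose regimen trough_occupancy occ_low occ_high  n
#> 1  120      QD             0.52    0.44     0.61 12
#> 2  240      QD             0.57    0.49     0.65 12
#> 3  120     BID             0.74    0.67     0.80 12
#> 4  240     BID             0.78    0.72     0.83 12
```

Dividing the same daily dose sustains trough occupancy (120 mg BID ≈ 0.74
vs 240 mg QD ≈ 0.57 here), and the dose–response flattens above 120 mg
BID because bioavailability falls with dose — the model-based rationale
for selecting 120 mg twice daily. The `occ_low`/`occ_high` band
propagates the IC50 confidence interval (60–122 nM) only.

A one-call pipeline (`simulate → nca → stats → occupancy`) with a YAML
config and artifact manifest is available via `pipeline_config()` /
`run_pipeline()`.

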