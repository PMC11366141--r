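# icumotion

Movement biomarkers from thigh-fixed accelerometers and penalized
mixed-model prediction of muscle atrophy in neurocritical care.

Patients with acute brain injury barely move, and the resulting
mechanical unloading wastes the rectus femoris muscle (RFM) within
days — a core mechanism of ICU-acquired weakness. `icumotion` is for
researchers who instrument such patients with tri-axial accelerometers
(±16 g, ~12.5 Hz) on both thighs, log and exclude passive-movement
episodes (physiotherapy, transports, repositioning), track muscle
thickness by repeated ultrasound at days 0/3/7/10, and want to quantify
how much *active* movement protects against atrophy.

## What it computes

**Movement biomarkers** (per leg): the recording is down-sampled to
10 Hz, high-pass filtered (4th-order zero-phase Butterworth, 0.2 Hz) to
strip gravity and posture, and cut into non-overlapping 5 s windows.
Each window's signal magnitude area,

```
SMA = mean over window of ( |ax| + |ay| + |az| )        [g]
```

feeds an activity-bout detector: a bout is a maximal run of windows
with SMA ≥ 0.135 g. Seven features summarize a recording: `%active`
(share of non-excluded time in bouts), overall intensity, bouts/hour,
and log-normal ML estimates (log-mean, log-SD) of bout intensity and
duration.

**The prediction model**: one row per leg and follow-up day, outcome
the percent change of RFM thickness versus day 0. Because legs and days
repeat within patients, the model is a Gaussian linear mixed model with
patient random intercepts whose fixed effects are L1-penalized:

```
min  1/2 log|V| + 1/2 (y - Xb)' V^{-1} (y - Xb) + lambda * sum_j |b_j|,
V = sigma_e^2 I + sigma_b^2 Z Z'
```

solved by GLS-whitened coordinate descent with soft-thresholding
alternating with profile-ML variance updates (exact zeros, monotone
objective; written in C++). Candidate predictors pass a VIF > 5 screen
and are z-scored on the training patients. `lambda` is tuned by nested
cross-validation (4 outer / 2 inner patient-grouped folds, final
penalty = mean of the outer optima), performance is measured on a
held-out 20% of patients (grouped, outcome-stratified split), and
coefficient uncertainty comes from a patient-cluster BCa bootstrap.
Secondary analyses: Gaussian GEE limb-group contrasts with Bonferroni
correction, an OLS negative-control model for temporalis atrophy, and
Welch's t-test against healthy controls.

**Synthetic data**: `sim_config()` / `simulate_cohort()` /
`simulate_recording()` generate a cohort emulating the study conditions
(53 patients, ~91 legs, baseline RFM 10.3 ± 2.6 mm, %active
0.84 ± 1.08, day-10 atrophy −19.5 ± 12%, standardized effects −5.1 and
+1.6) with full ground truth, so the whole pipeline is testable.

## Worked example

```r
library(icumotion)
set.seed(5)
cohort <- simulate_cohort(sim_config())
tab <- build_analysis_table(cohort$ultrasound, cohort$clinical,
                            cohort$features, days = c(3, 7, 10))
model <- fit_atrophy_model(tab, seed = 5)
print(model)
```

```
<atrophy_model> with movement features; 12 predictors after VIF
VIF-removed: ab_per_hour, sofa
lambda (mean of outer optima): 0.5411
test: MSE 69.712 | RMSE 8.349 | MAE 6.635 | R2 0.380 (n = 57)
```

```r
round(model$coefficients[model$coefficients != 0], 2)
```

```
        (Intercept)                 age     baseline_rfm_mm     protein_deficit
             -13.07                0.27               -5.45                0.35
overall_intensity_g          pct_active ab_duration_logmean   ab_duration_logsd
              -1.29                1.42                0.04               -0.08
```

Reading the output: the VIF screen dropped the two redundant composites
(bouts/hour, full SOFA). On held-out patients the model explains 38% of
the variance in atrophy this run. The two planted effects dominate the
selected model: one SD more baseline RFM predicts ~5.5 percentage
points *more* atrophy by day 10, one SD more `%active` predicts ~1.4
points *less*; the remaining small coefficients are nuisance predictors
the MSE-optimal penalty did not quite zero (see the vignette on why an
MSE-optimal penalty is not a consistent selector). Intervals for any
coefficient come from `bootstrap_bca()`.

A thin CLI wrapping the same functions ships in `inst/cli/icumotion.R`
(subcommands `simulate`, `extract-features`, `build-table`, `fit`,
`run-all`); `run_pipeline()` drives the whole chain into a run
directory with a checksummed manifest.

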