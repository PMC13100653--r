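# rbvidh

Risk analysis of **intradialytic hypotension (IDH)** from continuous
**relative blood volume (RBV)** monitoring during hemodialysis.

During a dialysis session, ultrafiltration removes plasma water faster than
vascular refilling can replace it. A blood-volume monitor tracks the
resulting hemoconcentration through hematocrit, giving the relative blood
volume

```
RBV(t) = 100 × Ht(0) / Ht(t)   (%)
```

which starts at 100% and falls over the session. `rbvidh` implements, as a
tested R pipeline, the full analysis chain linking that signal to
hypotensive events (SBP < 90 mmHg with a ≥ 20 mmHg drop from the session's
first reading):

* **RBV and feature construction** — per-minute RBV from hematocrit, the
  trailing 10-minute slope dRBV/dt, ΔRBV = 100 − RBV, ΔSBP, and
  per-measurement model rows with concurrent or 10–60-minute-ahead labels
  (`compute_rbv`, `label_idh`, `build_rows`).
* **Trajectory clustering** — dynamic time warping distances (Rcpp) and
  k-medoids at k = 3 over whole-session RBV trajectories, with the
  lowest-incidence cluster as the low-risk reference
  (`cluster_trajectories`, `assign_risk_groups`).
* **A time-dependent RBV threshold** τ(t) — at each grid time, the cutoff
  maximizing the Youden index between high- and low-risk groups, LOESS
  smoothed, with session-level bootstrap bands
  (`derive_threshold_curve`, `below_threshold`).
* **Mixed-effects logistic risk models** — patient-random-intercept GLMMs
  (adaptive Gauss–Hermite via lme4) of IDH on the logit scale,
  `logit P(IDH) = β₀ + βᵀx + b_i`, `b_i ~ N(0, σ_b²)`, for concurrent
  association and near-future prediction (`fit_mixed_logistic`,
  `fit_association_suite`, `fit_predictive_model`).
* **Validation** — session-wise (future sessions of known patients, random
  effects usable) vs patient-wise (unseen patients, fixed effects only)
  splits, rank-based AUC, Youden operating points, Fisher/Wilcoxon
  descriptive comparisons (`evaluate_model`, `descriptive_suite`).
* **A synthetic cohort generator** — 56 patients × 9 sessions of 240
  minutes with 30-minute vitals, three RBV trajectory archetypes from a
  refilling recurrence, and a logistic event hazard whose injected odds
  ratios are the published estimates (`generate_cohort`,
  `calibrate_intercept`, packaged configs `paper_continuous`,
  `paper_threshold`, `paper_archetype`, `paper_multivariable`). Event
  labels and simulated blood pressures are consistent by construction, so
  the whole pipeline is testable by parameter recovery.

## Worked example

Simulate a cohort with the packaged concurrent effect (OR 1.053 per point
of ΔRBV, σ_b = 1.67), label it blind, and refit:

```r
library(rbvidh)

eff  <- load_effect_config("paper_continuous")
co   <- generate_cohort(cohort_config(), eff, seed = 1)
rows <- build_rows(co, mode = "concurrent")
fit  <- fit_mixed_logistic(rows, label ~ delta_rbv)
fit
#> Mixed-effects logistic fit: label ~ delta_rbv + (1 | patient_id)
#>   4032 obs, 56 patients; sigma_b = 1.654; logLik = -782.3
#>               coef    se    OR ci_low ci_high p
#> (Intercept) -4.432 0.304 0.012  0.007   0.022 0
#> delta_rbv    0.047 0.007 1.048  1.033   1.063 0
```

The fitted odds ratio per 1-point increase in ΔRBV (1.048, 95% CI
1.033–1.063) recovers the injected 1.053, and the random-intercept SD
(1.65) recovers the injected 1.67: each 1% of blood-volume decline raises
the odds of concurrent hypotension by ~5%, on top of ~5-fold
between-patient odds variation.

Downstream stages work the same way on any `rbv_cohort` (simulated or read
from `sessions.csv` / `machine.csv` / `vitals.csv` via `read_cohort()`):

```r
cl  <- cluster_trajectories(co, k = 3)           # DTW k-medoids
lab <- label_idh_cohort(co)
rg  <- assign_risk_groups(cl$labels,
                          setNames(lab$sessions$any_idh,
                                   lab$sessions$session_id))
thr <- derive_threshold_curve(co, rg, B = 200)   # Youden + LOESS + bootstrap
ev  <- evaluate_model(build_rows(co, lab, mode = "horizon"),
                      co$sessions, label ~ delta_rbv, mode = "session")
```

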