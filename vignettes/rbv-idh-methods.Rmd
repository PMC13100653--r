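---
title: "Modelling intradialytic hypotension risk from relative blood volume"
author: "rbvidh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intradialytic hypotension risk from relative blood volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbvidh)
```

## The problem

Intradialytic hypotension (IDH) — an abrupt fall of systolic blood pressure
during a hemodialysis session — is among the most common acute complications
of dialysis and is associated with organ hypoperfusion and mortality.
Ultrafiltration removes plasma water faster than the interstitium can refill
the vascular compartment, so intravascular volume falls over the session.
Blood-volume monitors track this continuously through hematocrit: as plasma
volume shrinks, red cells concentrate, and the *relative blood volume*

$$\mathrm{RBV}(t) = 100 \times \frac{\mathrm{Ht}(0)}{\mathrm{Ht}(t)} \;\; (\%)$$

falls from its 100% baseline. `rbvidh` implements an analysis pipeline that
asks, for per-minute RBV channels and 30-minute blood-pressure readings:

1. Is the concurrent RBV level associated with IDH (defined as SBP
   < 90 mmHg with a ≥ 20 mmHg drop from the session's first reading)?
2. Do whole-session RBV *trajectories* cluster into shapes with different
   risk, and can a time-dependent RBV threshold $\tau(t)$ separate them?
3. Can IDH in the next 10–60 minutes be predicted from the current
   measurement, and how does performance differ between holding out future
   sessions of known patients versus entirely unseen patients?

All associations are estimated with mixed-effects logistic regression,
$\operatorname{logit} P(\text{IDH}_{it}) = \beta_0 + \beta^\top x_{it} + b_i$,
with a per-patient random intercept $b_i \sim N(0, \sigma_b^2)$, because IDH
propensity varies enormously between patients (on the data this package
emulates, $\sigma_b \approx 1.67$ on the logit scale — an odds-ratio spread
of $e^{\pm 1.67} \approx$ 5-fold either way between typical patients).

Because the underlying patient data are not public, the package pairs every
analysis stage with a **synthetic cohort generator** whose injected effects
are the published point estimates; correctness is then demonstrated by
*parameter recovery*: run the blind pipeline on simulated data and check
that it returns what was injected.

## The event definition

A vitals entry is flagged as IDH when SBP < 90 mmHg *and* the drop from the
session's first recorded SBP is ≥ 20 mmHg. The nadir criterion follows the
outcome-validated definition of symptomatic-agnostic IDH; anchoring the drop
to the first reading avoids contamination by intra-session interventions.
The source material states the drop criterion inconsistently in one place
("< 20 mmHg"), which would make the compound definition weaker than the
nadir alone; this package adopts ≥ 20 mmHg throughout.

## The synthetic cohort

`cohort_config()` defaults encode the emulated study: 56 patients × 9
sessions of 240 minutes, vitals every 30 minutes, pre-dialysis SBP
128.8 ± 24.4 mmHg declining ~15 mmHg across the session, baseline
hematocrit ~34% (≈ 3 × hemoglobin 11.5 g/dl). RBV trajectories follow a
refilling recurrence

$$\mathrm{rbv}(t+1) = \mathrm{rbv}(t) - u + k_r\,(100 - \mathrm{rbv}(t)) + \varepsilon_t,$$

whose noise-free fixed point is $100 - u/k_r$: ultrafiltration drive $u$
pulls volume down, refilling $k_r$ pulls it back toward baseline. Three
archetypes differ only in $u$ (fixed points ≈ 65%, 92%, 80% for steep,
plateau and intermediate declines with $k_r = 0.01\,\mathrm{min}^{-1}$),
spanning the final-RBV spread observed between low- and high-risk
trajectory groups (medians ~92% vs ~72%). Refilling rates and noise
magnitudes are not published; they were chosen once to make trajectory
shapes and spreads plausible and are deliberately *not* tuned to reproduce
any reported statistic. Session-level variation enters through a lognormal
jitter on $u$ (SD 0.10) and per-minute innovation noise (SD 0.5%).

Events are generated at vitals times from the logistic hazard of an
`effect_spec()`; the packaged configurations inject the published odds
ratios (ΔRBV 1.053 per point; below-threshold 2.37; high-risk cluster 2.58;
the five-covariate 10–60-minute model 1.68 / 0.26 / 0.94 / 1.02 / 1.02)
with $\sigma_b = 1.67$. After the event flag is drawn, the SBP reading is
drawn from the region *consistent* with the flag under the labelling rule,
so relabelling simulated data reproduces the simulated events exactly —
this round trip is what makes the labeller testable. SBP deviations from
the within-session trend follow an AR(1) process (lag-30-min correlation
0.7, stationary SD 12 mmHg): intradialytic pressure follows a slow
hemodynamic trajectory rather than bouncing independently around a trend,
and this smoothness is what lets the predictive models' SBP terms be
identified.

Intercepts are calibrated by `calibrate_intercept()` (bisection on the
*expected* session-level incidence, each evaluation simulating ≥ 2000
sessions) to the 29.7% headline incidence; the packaged YAMLs ship
pre-calibrated values, and the acceptance script re-derives one from
scratch.

### What the generator does not emulate

No baroreflex or cardiac-output mechanism, no access recirculation
artifacts, no missing or irregular sampling, no symptom-triggered extra BP
measurements, no ultrafiltration-rate feedback by staff. Passing recovery
tests therefore demonstrates the *statistical machinery* is correct under
the assumed structure, not that the published real-data estimates are
reproducible from first principles.

### A known structural limit of horizon-mode recovery

The predictive label at measurement time $t$ is "any event in
$(t+10, t+60]$" — with 30-minute vitals, a union over events at $t+30$ and
$t+60$. The generator drives each event by the covariates one interval
before it (the lead time to the nearest in-window event), which makes the
horizon fit *approximately* well-specified: the union's log-odds is
$b_i + \log(e^{\eta(t)} + e^{\eta(t+30)})$, which preserves slopes exactly
only when covariates are constant across the window. No generator can do
better: label patterns such as (0, 1, 0) at successive measurements admit
*no* consistent event set, so the horizon model can never be made exactly
correctly specified. Consequently coefficients on fast-moving covariates
attenuate somewhat (the below-threshold indicator recovers ~1.4–1.5
against an injected 1.68, still inside the published interval 1.16–2.44;
ΔSBP, whose signal is smallest, attenuates most), while the
slowly-varying RBV features, SBP and HR recover well. The concurrent
models, where the hazard and the fit share the same timestamps, recover
their injected effects essentially unbiasedly.

## Trajectory clustering and risk groups

Sessions are compared by dynamic time warping on the raw per-minute RBV
series — absolute-difference local cost, unit steps, no global constraint
by default (a Sakoe–Chiba band is available for very long series). DTW
tolerates modest timing differences between sessions while the *level*
still carries the signal, which is why trajectories are deliberately not
z-normalized. Clustering is k-medoids (k = 3 by default) on the pairwise
DTW matrix: medoids require only a dissimilarity, whereas a DTW "mean"
is ill-defined. Small problems are solved by exhaustive medoid search,
larger ones by PAM; both are deterministic. Average-linkage hierarchical
clustering is available as an alternative. `assign_risk_groups()` then
declares the cluster with the lowest session-level IDH incidence the
low-risk reference and pools the rest as high risk — the generalization of
merging the two event-rich clusters observed at k = 3 (ties go to the
larger cluster).

## The time-dependent threshold

At each 5-minute grid time, the RBV values of all still-running sessions
are pooled by risk group and the cutoff maximizing the Youden index
J = sensitivity + specificity − 1 ("below the cutoff" classifying high
risk) is taken among midpoints of adjacent distinct pooled values; when a
run of candidates ties, the midpoint of the first maximizing interval is
returned, which for separable groups is the centre of the separating gap.
The raw curve is smoothed by LOESS (local linear, tricube weights,
span 0.3 by default) and a 95% pointwise band is attached by resampling
sessions with replacement *within* risk group (B = 200 in tests, 1000
recommended for reported curves). The percentile band is clipped to
contain the smoothed estimate so the stored curve always satisfies
`ci_low ≤ smooth ≤ ci_high`. Crossing is strict (`rbv < τ(t)`), with
linear interpolation between grid points and nearest-grid extrapolation
outside the curve's support. Grid step, span and B are not published
choices; they are exposed as arguments.

When the threshold feeds a *predictive* evaluation it should be derived on
training sessions only; `derive_threshold_curve()` operates on whatever
cohort subset it is given, so leakage control belongs to the caller (the
packaged evaluations use the generator-side curve, which involves no
estimation at all).

## Model fitting and validation

`fit_mixed_logistic()` wraps a single-random-intercept logistic GLMM
estimated by maximum likelihood with adaptive Gauss–Hermite quadrature
(21 nodes by default; 1 node gives the Laplace approximation; estimates at
21 vs 41 nodes agree to < 1e-4 on test fixtures). Wald 95% intervals
(exp(β ± 1.96 SE)) match the symmetric intervals conventionally reported.
Complete separation is detected and reported as an error suggesting
covariate removal; no penalized fallback is provided. Random slopes are
out of scope.

Two validation designs are built in: *session-wise* (each patient's
earliest ⌈0.7 n⌉ sessions train, the rest test — deployment on future
sessions of known patients, where the estimated $b_i$ may be used) and
*patient-wise* (random patient partition — unseen patients, fixed effects
only). The package's structural check mirrors the qualitative finding that
with strong heterogeneity the session-wise design outperforms the
patient-wise one, and that the gap collapses when $\sigma_b = 0$.

## Numerical and interface choices

* Time is integer minutes from session start; vitals times lie on the
  machine grid. The t = 0 entry defines baseline SBP and can never itself
  be an event (its drop is zero).
* `compute_rbv()` uses the first hematocrit reading as Ht(0) so that
  RBV(0) = 100 exactly (a 0–2-minute mean is available for noisy sensors).
* `drbv_dt` is the trailing 10-minute OLS slope in %/min; with fewer than
  two in-window points it is undefined and the row is dropped (counted).
* Horizon windows are half-open, `(t+10, t+60]`; windows extending past
  the session end are truncated, never errors. Rows where IDH is already
  ongoing are excluded from horizon fits by default.
* All simulation is driven by one seed through R's default RNG stream;
  identical (config, effect, seed) triples give identical cohorts.

## Problem sizes used by the packaged checks

Recovery checks run at the emulated study scale (56 × 9 sessions).
Replicate counts per quantity: 20 seeds for the concurrent ΔRBV odds ratio
and for the heterogeneity median; 10 for the threshold and multivariable
odds ratios in the acceptance script (3 in the test suite); 6 for the
clustering pipeline (2 in the test suite, where the DTW matrix dominates
runtime); bootstrap bands use B = 40–50 in tests. These counts were chosen
to keep Monte-Carlo error well below each quantity's acceptance band.

## Limitations

The generator targets statistical structure, not hemodynamic mechanism;
archetype parameters are plausible rather than estimated; the horizon-mode
attenuation described above is intrinsic to interval-censored event
labelling; and no real machine-log ingestion (proprietary formats,
bioimpedance channels, Kt/V) is provided.
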