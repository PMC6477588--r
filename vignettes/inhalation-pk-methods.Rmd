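---
title: "Methods: inhalation PK from exposure atmosphere to NCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inhalation PK from exposure atmosphere to NCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmopk)
```

`pulmopk` covers the analysis chain of a single-administration rodent
inhalation pharmacokinetic study: characterize the exposure atmosphere,
convert it to a deposited dose, build group concentration–time profiles
under assay censoring, and summarize them by noncompartmental analysis
(NCA). This vignette explains each model, the choices that were
genuinely open, and what the packaged synthetic data can and cannot
establish.

## Study design and data model

The design is destructive sampling: three arms (intravenous control and
two inhaled doses), ten necropsy times from 0.5 to 336 h, three animals
per arm and time, each animal contributing exactly one plasma (ng/mL)
and one lung (ng/g) observation. Concentrations below the assay's lower
limit of quantification (LLOQ) are recorded as BQL — an explicit
censoring state. The package never substitutes zero or LLOQ/2 for a BQL
value: the study's own group means demonstrably average the quantified
replicates only (a time point with replicates {BQL, 1.16, 1.36} prints
a mean of 1.26 over n = 2), and that convention is reproduced exactly.

Two standard-deviation conventions coexist in the source tables and are
preserved deliberately: the concentration tables print the population
(n-denominator) SD (replicates 153/205/261 print 44.1, not the sample
value 54.0), while the exposure-filter table prints the sample (n−1) SD
(8.76 for the low-dose filters). `group_mean_profile()` therefore uses
the population SD and `summarize_filters()` the sample SD.

Times are hours post-administration exactly as recorded; the 65-minute
exposure window is not added to the clock, which starts at the end of
administration.

## Exposure atmosphere

Filter statistics are plain mean/SD/%RSD. The cascade-impactor
reduction assumes the aerodynamic size distribution is lognormal: the
cumulative mass fraction finer than each stage cutoff is probit
transformed and regressed on the log cutoff diameter,
`z_i = a + b ln d_i`, giving MMAD = exp(−a/b) and GSD = exp(1/b). For a
truly lognormal aerosol the linearization is exact (r² = 1), which is
why the package prefers it over nonlinear CDF fitting: it is
deterministic, closed-form, and its residual r² is a meaningful
lognormality diagnostic. Fractions at (or within 1e−10 of) 0 or 1 have
unbounded probits carrying no usable information and are excluded; at
least three interior stages are required. Stage cutoffs are taken as
given — no flow-rate recalibration of effective cutoff diameters is
attempted.

Calibration-curve QC uses weighted least squares with 1/x² weights, the
bioanalytical standard when assay error scales with concentration, and
passes a run when the weighted correlation coefficient is ≥ 0.98 and
every standard and QC back-calculates to within ±15% of nominal.

## Deposited dose

The inhaled deposited dose is

DD (µg/kg) = AC (µg/L) × RMV (L/min) × DF × T (min) / BW (kg),

with the allometric rodent respiratory minute volume
RMV = 0.608 × BW^0.852 L/min. The deposition fraction DF is a modelling
assumption, not a measurement — 0.10 is the conventional value for
rodents inhaling 1–5 µm MMAD particles — so the API requires it
explicitly rather than defaulting silently. Body weights were not
published with the study; a weight of 0.44 kg makes the equation
consistent with both printed inhaled arm doses (0.382 and 1.170 mg/kg
against printed 0.38 and 1.18) to within rounding, and the tests use it
as a documented input, not an estimate. Whether the original analysis
averaged per-animal doses or used a group-mean weight cannot be
determined from the published tables; the function computes one dose per
parameter set and leaves averaging to the caller.

## Noncompartmental analysis

NCA runs on group mean profiles (the study's own convention for sparse
destructive sampling), not per-animal curves. The parameters:

* **Cmax/Tmax** — maximum quantified group mean; ties break to the
  earliest time.
* **AUC_last** — linear trapezoid over quantified means up to the last
  quantifiable time. A synthetic (0, 0) point is prepended by default:
  the published lung AUCs are matched only when the triangle from dosing
  to the first sample is included (for the intravenous arm,
  5800/2 × 0.5 = 1450 closes the gap exactly). The plain linear
  trapezoid was chosen over linear-up/log-down because it reproduces all
  three published lung AUC values to the integer; log-down yields ≈58,500
  for the intravenous arm against the published 62,870. Interior
  all-BQL time points are bridged by a single trapezoid between the
  neighbouring quantified means rather than dropped to zero; no
  published time point exercises this rule, so reports flag it as a
  convention rather than a validated behaviour.
* **λz and T1/2** — ordinary least squares of log mean concentration on
  time over an automatically selected terminal window: candidates are
  the last three quantified points, then each window extended one
  earlier point at a time, never including Tmax; the window maximizing
  the adjusted R² = 1 − (1 − R²)(n − 1)/(n − 2) wins, ties (within
  1e−12) going to the larger window. This is the de facto "best fit"
  rule of NCA software; the study names only its software, not a rule,
  so the rule is configurable via an explicit window override. On the
  intravenous-arm lung means the rule selects {12, 24, 48, 72} h
  (adjusted R² 0.961, beating the minimal window's 0.940), giving
  T1/2 = 19.86 ≈ 19.9 h.
* **AUC_D(last)** — AUC_last divided by the dose in mg/kg.

All computation is full precision; rounding to the published display
(3 significant figures for Cmax, one decimal for T1/2, integers for
AUC) happens only in the report layer.

### What is, and is not, reproduced

`reproduce_paper()` checks 12 quantities: the filter mean/SD statistics,
five Cmax values, the three lung AUC_last values, and the
intravenous-arm lung T1/2. Several published quantities are deliberately
not checked because the published tables do not determine them:

* Inhaled-arm plasma AUC_last (printed 101 and 228): the convention that
  reproduces all three lung AUCs exactly yields ≈89 and ≈202 here; the
  original handling of sparse terminal plasma points (n = 1 quantified)
  is unknown.
* AUC_D(last): the printed values are inconsistent with printed AUC ÷
  printed dose (e.g. 1,155,662 / 1.18 ≈ 979,400 vs printed 997,985),
  implying unrounded internal doses.
* Inhaled-arm lung T1/2 (56.3, 56.0 h): no candidate terminal window on
  the printed means gives these uniquely (candidates span 51–66 h).
* MMAD/GSD: no stage-level impactor data were published; the impactor
  code is validated against synthetic lognormal stage data instead.
* Deposited doses per animal: body weights are unpublished.

## The simulator

`simulate_study()` emulates the study's structure with known ground
truth. Lung kinetics are biexponential,
C(t) = A1·e^(−k1·t) + A2·e^(−k2·t) with k1 > k2 > 0: a fast-cleared
absorbed fraction plus a slowly dissolving particle depot. This is a
descriptive stand-in — no dissolution physics or mucociliary/macrophage
clearance is modelled — but two phases are exactly what is needed to
exercise terminal-window selection against contamination from the fast
phase. Plasma follows a one-compartment model with first-order input,
C(t) = coef·(e^(−ke·t) − e^(−ka·t)), `coef` lumping F·ka·D/(V(ka−ke)).
Inter-animal variability is a multiplicative lognormal deviate with
mean 1 and configurable CV (one deviate per animal and matrix, no
within-animal correlation — the destructive design has none), and each
matrix censors at its LLOQ (defaults: plasma 1 ng/mL, lung 50 ng/g; the
study reported a 10 ng/g linear-range floor for lung in one place and a
50 ng/g quantification limit in another, and its censoring pattern —
55.5 ng/g quantified, lower values BQL — matches 50).

Default arm parameters were calibrated once so that noise-free group
means lie within about a factor of two of the study's profiles and the
BQL pattern matches qualitatively (plasma BQL within days, inhaled lung
depot quantifiable at 336 h, intravenous lung BQL from 120 h); they are
study-shaped test conditions, not estimates of the drug's parameters.
The default CV of 0.3 is typical of the replicate scatter in the
concentration tables. The terminal depot half-life of the inhaled arms
(ln 2/0.009 ≈ 77 h) is deliberately in the slow range so that late
windows are informative.

`recover_parameters()` closes the loop: simulate, build profiles, run
NCA, compare with closed-form truth (Cmax against the model maximum on
the schedule, T1/2 against ln 2/k2 or ln 2/min(ka, ke), AUC against the
exact integral to t_last). With CV = 0 the pipeline recovers terminal
half-lives within 5% (the residual bias is biexponential contamination
of the selected window, not estimation error) and the AUC equals the
trapezoid of the true curve on the sampling grid — the difference from
the exact integral is pure discretization, quantified in the report.
Passing these tests shows the pipeline is internally consistent under
the model's assumptions; it does not validate the biexponential model
against real lung dissolution kinetics.

## Numerical conventions

* Trapezoid and λz computations are closed-form/OLS; no iterative
  optimization anywhere in the deterministic chain, so reproduction runs
  are bit-identical.
* Adjusted-R² ties break to the larger window at 1e−12; Cmax ties break
  to the earliest time.
* A single quantified point yields AUC equal to its anchor triangle
  (or 0 without the anchor) and no λz fit; fewer than three quantified
  points after Tmax, or a non-negative best slope, yield a missing λz
  with a stated reason.
* Degenerate impactor inputs (monodisperse mass in one band, all-zero
  stages) are rejected rather than fitted.
* Simulation problem sizes used by the test suite — single-replicate
  recovery runs at CV = 0 and a 500-replicate Monte-Carlo impactor
  experiment at 5% stage noise — were chosen as the smallest sizes at
  which the checked properties are stable.

## Limitations

Group-mean NCA estimates population-average parameters only; no
between-animal inference is attempted. The λz window rule is a
convention, and other software defaults (e.g. maximizing unadjusted R²,
or requiring a minimum span) can select different windows on shallow
curvature. The deposited-dose model uses a single whole-lung deposition
fraction with no regional deposition. The simulator's lognormal noise
and exact schedule adherence idealize real studies, which have sampling
jitter, assay error structure near the LLOQ, and occasional lost
samples.
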