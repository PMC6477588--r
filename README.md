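# pulmopk

Noncompartmental pharmacokinetics for rodent inhalation studies.

`pulmopk` implements the complete computational chain behind a rodent
inhaled-paclitaxel pharmacokinetic study comparing intravenous
nab-paclitaxel (IVnP, 2.9 mg/kg) with low- and high-dose inhaled
submicron-particle paclitaxel (IHNP-LD 0.38 mg/kg, IHNP-HD 1.18 mg/kg):

* **Exposure characterization** — mean/SD/%RSD of drug and total aerosol
  concentrations from nose-only exposure filter samples
  (`summarize_filters()`), and cascade-impactor reduction to MMAD and GSD
  by log-probit regression of cumulative-finer mass fractions on log
  cutoff diameter (`fit_impactor()`), which is exact for lognormal
  aerosols. Bioanalytical calibration curves are checked with the
  standard 1/x² weighted regression and ±15% recovery rules
  (`check_calibration()`).
* **Inhaled dosimetry** — deposited dose
  DD (µg/kg) = AC × RMV × DF × T / BW with the allometric respiratory
  minute volume RMV = 0.608 × BW^0.852 L/min (`rmv()`,
  `deposited_dose()`).
* **BQL-aware group profiles** — per-time group means over quantified
  replicates only; below-quantification-limit (BQL) values are a
  first-class censoring state, never zero or LLOQ/2
  (`group_mean_profile()`).
* **Noncompartmental analysis** — Cmax/Tmax, linear-trapezoidal
  AUC_last with a (0, 0) anchor at dosing, dose-normalized AUC, and the
  terminal slope λz chosen by the adjusted-R² best-fit window rule
  (last three quantified points, extended earlier one point at a time,
  never including Tmax), with T1/2 = ln 2 / λz (`auc_last()`,
  `lambda_z_best_fit()`, `nca_summary()`).
* **Synthetic studies** — a destructive-sampling simulator with
  biexponential lung depot kinetics, first-order-input plasma kinetics,
  lognormal inter-animal variability and LLOQ censoring, plus
  parameter-recovery experiments against closed-form ground truth
  (`simulate_study()`, `simulate_impactor()`, `recover_parameters()`).

The full study data (exposure filters, triplicate plasma and lung
concentrations at 10 necropsy times, printed group means, arm doses)
ship as plain-text fixtures; `paclitaxel_study()` loads them.

## Worked example

```r
library(pulmopk)
ds <- paclitaxel_study()

summarize_filters(subset(ds$filters, arm == "IHNP-LD"))
#> <aerosol_summary> n = 7 filters
#>   drug aerosol : 85.64 ug/L (SD 8.76, %RSD 10.23)
#>   total aerosol: 0.25 mg/L (SD 0.02, %RSD 7.43)

nca_summary(group_mean_profile(ds, "IVnP", "lung", use_printed_means = TRUE))
#> <nca_result> IVnP / lung
#>   Cmax 5800 ng/g at 0.5 h; t_last 72 h
#>   AUC_last 62869.5 hr*ng/g; AUC_D 21679.1 per mg/kg
#>   T1/2 19.9 h (lambda-z window {12, 24, 48, 72})

deposited_dose(ac_ug_per_L = 85.64, bw_kg = 0.44, df = 0.10, t_min = 65)
#> <dose_result> RMV 0.3021 L/min; deposited dose 382.2 ug/kg (0.3822 mg/kg)
```

The filter summary is the low-dose exposure atmosphere: 85.64 µg
paclitaxel per litre of inhaled air (10.2% relative SD across the seven
filters). The NCA line reads: peak lung concentration 5,800 ng/g at the
first necropsy (0.5 h), quantifiable to 72 h, total lung exposure
62,869.5 hr·ng/g (21,679 per unit dose), and an apparent residence
half-life of 19.9 h fitted on the 12–72 h window. The dose line converts
that exposure atmosphere into a deposited dose of 0.38 mg/kg for a
0.44 kg rat breathing it for 65 minutes with 10% lung deposition.

`reproduce_paper()` runs every deterministic check at once — filter
statistics, lung and plasma Cmax, lung AUC_last, and the intravenous-arm
lung half-life — and reports a pass/fail table against the published
values.

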