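#' Summarize exposure-atmosphere filter samples
#'
#' Arithmetic mean, sample (n-1) standard deviation and percent relative
#' standard deviation of the drug and total aerosol concentrations
#' collected on gravimetric filters during a nose-only exposure. The mean
#' drug aerosol concentration is the AC term of the deposited-dose
#' calculation ([deposited_dose()]).
#'
#' @param filters data.frame with columns `drug_ug_per_L` and
#'   `total_mg_per_L` (a `study_dataset$filters` slice works directly).
#' @return An object of class `aerosol_summary`: `n_filters`, and
#'   `mean`/`sd`/`pct_rsd` for both the drug (ug/L) and total (mg/L)
#'   aerosol concentrations. `sd` is `NA` for a single filter.
#' @examples
#' ds <- paclitaxel_study()
#' summarize_filters(subset(ds$filters, arm == "IHNP-LD"))
#' @export
summarize_filters <- function(filters) {
  if (is.null(filters) || nrow(filters) == 0) {
    stop("at least one filter sample is required")
  }
  if (!all(c("drug_ug_per_L", "total_mg_per_L") %in% names(filters))) {
    stop("filters must have columns drug_ug_per_L and total_mg_per_L")
  }
  one <- function(x) {
    m <- mean(x)
    s <- if (length(x) >= 2) stats::sd(x) else NA_real_
    list(mean = m, sd = s,
         pct_rsd = if (m > 0) 100 * s / m else NA_real_)
  }
  drug <- one(filters$drug_ug_per_L)
  total <- one(filters$total_mg_per_L)
  structure(list(n_filters = nrow(filters),
                 mean_drug_ug_per_L = drug$mean, sd_drug = drug$sd,
                 pct_rsd_drug = drug$pct_rsd,
                 mean_total_mg_per_L = total$mean, sd_total = total$sd,
                 pct_rsd_total = total$pct_rsd),
            class = "aerosol_summary")
}

#' @export
print.aerosol_summary <- function(x, ...) {
  cat("<aerosol_summary> n =", x$n_filters, "filters\n")
  cat(sprintf("  drug aerosol : %.2f ug/L (SD %.2f, %%RSD %.2f)\n",
              x$mean_drug_ug_per_L, x$sd_drug, x$pct_rsd_drug))
  cat(sprintf("  total aerosol: %.2f mg/L (SD %.2f, %%RSD %.2f)\n",
              x$mean_total_mg_per_L, x$sd_total, x$pct_rsd_total))
  invisible(x)
}

#' Construct a cascade-impactor run
#'
#' Stage data from a multi-stage cascade impactor: effective cutoff
#' diameters in decreasing order with the drug (or gravimetric) mass
#' collected on each stage, plus an optional backup-filter mass capturing
#' everything finer than the last cutoff.
#'
#' @param cutoff_um strictly decreasing stage cutoff diameters (um).
#' @param mass non-negative stage masses, same length as `cutoff_um`.
#' @param final_filter_mass mass on the backup filter (no cutoff).
#' @return An object of class `impactor_run`.
#' @export
impactor_run <- function(cutoff_um, mass, final_filter_mass = 0) {
  stopifnot(length(cutoff_um) == length(mass))
  if (any(diff(cutoff_um) >= 0)) stop("cutoff diameters must be strictly decreasing")
  if (any(cutoff_um <= 0)) stop("cutoff diameters must be positive")
  if (any(mass < 0) || final_filter_mass < 0) stop("stage masses must be non-negative")
  structure(list(cutoff_um = as.numeric(cutoff_um), mass = as.numeric(mass),
                 final_filter_mass = as.numeric(final_filter_mass)),
            class = "impactor_run")
}

#' Read impactor stage data from CSV
#'
#' Expects columns `stage`, `cutoff_um`, `mass`; an empty `cutoff_um`
#' denotes the backup filter.
#'
#' @param path CSV path.
#' @return An [impactor_run()].
#' @export
read_impactor_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cutoff_um", "mass") %in% names(raw))) {
    stop("impactor file must have columns cutoff_um and mass")
  }
  backup <- is.na(raw$cutoff_um)
  impactor_run(raw$cutoff_um[!backup], raw$mass[!backup],
               final_filter_mass = if (any(backup)) sum(raw$mass[backup]) else 0)
}

#' Fit MMAD and GSD to cascade-impactor stage masses
#'
#' Reduces stage masses to the mass median aerodynamic diameter (MMAD) and
#' geometric standard deviation (GSD) by log-probit linearization: the
#' cumulative mass fraction finer than each cutoff is transformed by the
#' standard-normal quantile function and regressed on the log cutoff
#' diameter. For a lognormal aerosol this linearization is exact, so the
#' fit recovers (MMAD, GSD) with r-squared 1 on noise-free stage data.
#'
#' Fractions of exactly 0 or 1 map to infinite probits and are excluded;
#' at least 3 interior points are required.
#'
#' @param run an [impactor_run()].
#' @return An object of class `impactor_fit` with `mmad_um`, `gsd`,
#'   `r_squared` and `n_points_used`.
#' @examples
#' run <- simulate_impactor(2.3, 1.9, c(10, 5, 2.5, 1.25, 0.63, 0.31, 0.16))
#' fit_impactor(run)
#' @export
fit_impactor <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  total <- sum(run$mass) + run$final_filter_mass
  if (total <= 0) stop("no mass collected")
  # mass finer than cutoff i: all stages below it plus the backup filter
  finer <- rev(cumsum(rev(c(run$mass[-1], run$final_filter_mass))))
  frac <- finer / total
  # cumulative-finer fractions must be non-increasing with decreasing cutoff
  if (is.unsorted(rev(frac), strictly = FALSE)) {
    stop("cumulative mass fractions are non-monotone")
  }
  # fractions at (or within numerical distance of) 0 or 1 carry unbounded
  # probit values with no usable precision; only interior points are fit
  eps <- 1e-10
  interior <- frac > eps & frac < 1 - eps
  if (sum(interior) < 3) {
    stop("fewer than 3 interior cumulative fractions; cannot fit size distribution")
  }
  d <- run$cutoff_um[interior]
  z <- stats::qnorm(frac[interior])
  fit <- stats::lm(z ~ log(d))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0) {
    stop("non-positive probit slope: mass increases with size; check stage order")
  }
  structure(list(mmad_um = exp(-a / b), gsd = exp(1 / b),
                 r_squared = r_squared_lm(fit),
                 n_points_used = sum(interior)),
            class = "impactor_fit")
}

#' @export
print.impactor_fit <- function(x, ...) {
  cat(sprintf("<impactor_fit> MMAD %.3g um, GSD %.3g (r2 %.4f, %d stages)\n",
              x$mmad_um, x$gsd, x$r_squared, x$n_points_used))
  invisible(x)
}

#' Check a bioanalytical calibration curve
#'
#' Weighted linear regression of measured response on nominal
#' concentration with 1/x^2 weighting, the standard bioanalytical
#' calibration model for assays whose error scales with concentration.
#' The run passes when the weighted correlation coefficient is at least
#' 0.98 and every standard and quality-control sample back-calculates to
#' within +/-15% of nominal.
#'
#' @param standards data.frame with columns `nominal` and `measured`.
#' @param qcs optional data.frame with the same columns.
#' @param r_min minimum correlation coefficient (default 0.98).
#' @param recovery_tol_pct allowed deviation of recovery from 100%.
#' @return An object of class `calibration_qc`: `slope`, `intercept`,
#'   `correlation`, per-sample `standard_recovery_pct` and
#'   `qc_recovery_pct`, and the overall `pass` flag.
#' @export
check_calibration <- function(standards, qcs = NULL, r_min = 0.98,
                              recovery_tol_pct = 15) {
  stopifnot(is.data.frame(standards),
            all(c("nominal", "measured") %in% names(standards)))
  if (any(standards$nominal <= 0)) stop("nominal concentrations must be positive")
  if (length(unique(standards$nominal)) < 3) {
    stop("at least 3 distinct nominal levels are required")
  }
  x <- standards$nominal
  y <- standards$measured
  w <- 1 / x^2
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # weighted Pearson correlation
  wm <- function(v) sum(w * v) / sum(w)
  sxy <- sum(w * (x - wm(x)) * (y - wm(y)))
  r <- sxy / sqrt(sum(w * (x - wm(x))^2) * sum(w * (y - wm(y))^2))
  back <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(numeric(0))
    if (any(df$nominal <= 0)) stop("nominal concentrations must be positive")
    100 * ((df$measured - intercept) / slope) / df$nominal
  }
  std_rec <- back(standards)
  qc_rec <- back(qcs)
  ok <- function(rec) all(abs(rec - 100) <= recovery_tol_pct)
  structure(list(slope = slope, intercept = intercept, correlation = r,
                 standard_recovery_pct = std_rec, qc_recovery_pct = qc_rec,
                 pass = r >= r_min && ok(std_rec) && ok(qc_rec)),
            class = "calibration_qc")
}

#' @export
print.calibration_qc <- function(x, ...) {
  cat(sprintf("<calibration_qc> slope %.4g, intercept %.4g, r %.4f -> %s\n",
              x$slope, x$intercept, x$correlation,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
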