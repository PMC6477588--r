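#' Group mean concentration-time profile
#'
#' Collapses individual-animal measurements for one arm and matrix to a
#' group profile: per necropsy time, the arithmetic mean and standard
#' deviation over the quantified replicates only. BQL replicates are
#' excluded from the mean, never substituted by zero or half the
#' quantification limit; a time point where every replicate is BQL
#' carries a missing mean and is skipped by downstream AUC and lambda-z
#' computations.
#'
#' The per-time SD is the population (n-denominator) standard deviation,
#' the convention of the study's concentration tables (replicates
#' 153/205/261 print SD 44.1); note this differs from the sample (n-1)
#' SD used for exposure-filter statistics ([summarize_filters()]).
#'
#' With `use_printed_means = TRUE` the profile is taken verbatim from the
#' dataset's `printed_means` table (the group means exactly as published,
#' including their original rounding) rather than recomputed from the
#' replicates.
#'
#' @param ds a [study_dataset()].
#' @param arm,matrix arm label and matrix (`"plasma"` or `"lung"`).
#' @param use_printed_means take means from `ds$printed_means` verbatim.
#' @return A data.frame of class `group_profile` with columns `time_hr`,
#'   `mean`, `sd`, `n_quantified`, `n_total`, and attributes `arm`,
#'   `matrix`, `dose_mg_per_kg` and `unit`.
#' @examples
#' ds <- paclitaxel_study()
#' group_mean_profile(ds, "IVnP", "plasma")
#' @export
group_mean_profile <- function(ds, arm, matrix, use_printed_means = FALSE) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!arm %in% ds$arms) stop("unknown arm: ", arm)
  if (!matrix %in% STUDY_MATRICES) stop("unknown matrix: ", matrix)
  if (use_printed_means) {
    pm <- ds$printed_means
    if (is.null(pm)) stop("dataset has no printed means")
    pm <- pm[pm$arm == arm & pm$matrix == matrix, , drop = FALSE]
    if (!nrow(pm)) stop("no printed means for ", arm, " ", matrix)
    pm <- pm[order(pm$time_hr), ]
    prof <- data.frame(time_hr = pm$time_hr, mean = pm$mean, sd = pm$sd,
                       n_quantified = pm$n_quantified, n_total = pm$n_total)
  } else {
    m <- ds$measurements
    m <- m[m$arm == arm & m$matrix == matrix, , drop = FALSE]
    if (!nrow(m)) stop("no measurements for ", arm, " ", matrix)
    times <- sort(unique(m$time_hr))
    prof <- do.call(rbind, lapply(times, function(t) {
      v <- m$conc[m$time_hr == t]
      q <- v[!is.na(v)]
      data.frame(time_hr = t,
                 mean = if (length(q)) mean(q) else NA_real_,
                 sd = if (length(q) >= 2) sqrt(mean((q - mean(q))^2)) else NA_real_,
                 n_quantified = length(q), n_total = length(v))
    }))
  }
  dose <- if (!is.null(ds$doses) && arm %in% names(ds$doses))
    unname(ds$doses[arm]) else NA_real_
  structure(prof, class = c("group_profile", "data.frame"),
            arm = arm, matrix = matrix, dose_mg_per_kg = dose,
            unit = unname(MATRIX_UNITS[matrix]))
}

#' Construct a group profile directly from times and means
#'
#' Convenience constructor for ad hoc profiles (e.g. printed group means
#' typed in by hand, or model curves in simulations).
#'
#' @param time_hr strictly increasing times.
#' @param mean group mean concentrations (`NA` where all replicates BQL).
#' @param sd,n_quantified,n_total optional per-time metadata.
#' @param arm,matrix,dose_mg_per_kg profile attributes.
#' @return A `group_profile`.
#' @export
group_profile <- function(time_hr, mean, sd = NA_real_,
                          n_quantified = ifelse(is.na(mean), 0L, 1L),
                          n_total = NA_integer_, arm = NA_character_,
                          matrix = "plasma", dose_mg_per_kg = NA_real_) {
  if (any(diff(time_hr) <= 0)) stop("times must be strictly increasing")
  if (any(time_hr < 0)) stop("times must be non-negative")
  prof <- data.frame(time_hr = time_hr, mean = mean, sd = sd,
                     n_quantified = n_quantified, n_total = n_total)
  structure(prof, class = c("group_profile", "data.frame"),
            arm = arm, matrix = matrix, dose_mg_per_kg = dose_mg_per_kg,
            unit = unname(MATRIX_UNITS[matrix]))
}

# R^2 without summary.lm (which warns on numerically perfect fits,
# a case the exactness properties hit on purpose)
r_squared_lm <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / sst
}

quantified_points <- function(profile) {
  ok <- !is.na(profile$mean)
  data.frame(time_hr = profile$time_hr[ok], mean = profile$mean[ok])
}

#' Area under the curve to the last quantifiable time
#'
#' Linear trapezoidal AUC over the quantified group means, up to the last
#' time with a quantified mean (t_last). By default a synthetic (0, 0)
#' anchor precedes the first observation, adding the triangle from dosing
#' to the first sample; interior times where every replicate was BQL are
#' bridged by a single trapezoid between the neighbouring quantified
#' means.
#'
#' @param profile a `group_profile`.
#' @param anchor_zero_at_t0 prepend a (0, 0) point (default `TRUE`).
#' @return AUC in hr*concentration-units, or `NA` if nothing quantified.
#' @examples
#' p <- group_profile(c(1, 3), c(10, 10))
#' auc_last(p)  # 5 (triangle) + 20 (rectangle) = 25
#' @export
auc_last <- function(profile, anchor_zero_at_t0 = TRUE) {
  q <- quantified_points(profile)
  if (!nrow(q)) return(NA_real_)
  if (anyDuplicated(q$time_hr)) stop("duplicate time points")
  t <- q$time_hr
  y <- q$mean
  if (anchor_zero_at_t0 && t[1] > 0) {
    t <- c(0, t)
    y <- c(0, y)
  }
  if (length(t) < 2) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Best-fit terminal slope (lambda-z)
#'
#' Log-linear regression of the quantified group means against time over
#' an automatically selected terminal window. Candidate windows are the
#' last three quantified points, then each window extended one earlier
#' point at a time, never including the time of the maximum mean (Tmax);
#' the window maximizing the adjusted R-squared
#' 1 - (1 - R^2)(n - 1)/(n - 2) is selected, ties (within 1e-12) going to
#' the larger window. This is the conventional automatic "best fit" rule
#' of noncompartmental PK software. The terminal rate constant is
#' lambda-z = -slope and the apparent half-life ln(2)/lambda-z.
#'
#' @param profile a `group_profile`.
#' @param window optional explicit time window (vector of times to use),
#'   overriding the automatic rule (at least 2 points).
#' @return An object of class `lambdaz_fit` with `window`, `lambda_z`
#'   (/hr), `intercept` (log scale), `r_squared`, `adj_r_squared` and
#'   `half_life_hr`; or `NULL` (with a message explaining why) when no
#'   valid fit exists.
#' @examples
#' p <- group_profile(c(2, 4, 8, 16, 32), 100 * exp(-0.1 * c(2, 4, 8, 16, 32)))
#' lambda_z_best_fit(p)
#' @export
lambda_z_best_fit <- function(profile, window = NULL) {
  q <- quantified_points(profile)
  fit_window <- function(t, y) {
    n <- length(t)
    fit <- stats::lm(log(y) ~ t)
    slope <- unname(stats::coef(fit)[2])
    r2 <- r_squared_lm(fit)
    adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
    list(window = t, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, adj_r_squared = adj)
  }
  if (!is.null(window)) {
    keep <- q$time_hr %in% window
    if (sum(keep) < 2) stop("explicit window must cover at least 2 quantified points")
    best <- fit_window(q$time_hr[keep], q$mean[keep])
  } else {
    if (nrow(q) < 3) return(lambdaz_missing("fewer than 3 quantified points"))
    tmax <- q$time_hr[which.max(q$mean)]
    eligible <- q[q$time_hr > tmax, , drop = FALSE]
    n <- nrow(eligible)
    if (n < 3) return(lambdaz_missing("fewer than 3 quantified points after Tmax"))
    best <- NULL
    for (k in 3:n) {
      idx <- (n - k + 1):n
      cand <- fit_window(eligible$time_hr[idx], eligible$mean[idx])
      if (is.null(best) || cand$adj_r_squared > best$adj_r_squared + 1e-12 ||
          abs(cand$adj_r_squared - best$adj_r_squared) <= 1e-12) {
        best <- cand  # ties go to the larger (later-iterated) window
      }
    }
  }
  if (!is.finite(best$slope) || best$slope >= 0) {
    return(lambdaz_missing("no terminal decline (non-negative slope)"))
  }
  lz <- -best$slope
  structure(list(window = best$window, lambda_z = lz,
                 intercept = best$intercept, r_squared = best$r_squared,
                 adj_r_squared = best$adj_r_squared,
                 half_life_hr = log(2) / lz),
            class = "lambdaz_fit")
}

lambdaz_missing <- function(reason) {
  message("lambda-z fit unavailable: ", reason)
  NULL
}

#' @export
print.lambdaz_fit <- function(x, ...) {
  cat(sprintf("<lambdaz_fit> window {%s} h: lambda-z %.4g /hr, T1/2 %.3g h (adj R2 %.4f)\n",
              paste(x$window, collapse = ", "), x$lambda_z, x$half_life_hr,
              x$adj_r_squared))
  invisible(x)
}

#' Noncompartmental summary of a group profile
#'
#' Computes the standard sparse-design NCA parameters from a group mean
#' profile: Cmax (maximum quantified mean, with the replicate SD at that
#' time), Tmax (earliest time achieving the maximum), t_last, AUC to
#' t_last by linear trapezoid ([auc_last()]), the best-fit terminal slope
#' ([lambda_z_best_fit()]) with its half-life, and the dose-normalized
#' AUC when the profile carries a dose.
#'
#' @param profile a `group_profile`.
#' @param anchor_zero_at_t0 passed to [auc_last()].
#' @param lambda_window optional explicit lambda-z window, passed to
#'   [lambda_z_best_fit()].
#' @return An object of class `nca_result`.
#' @examples
#' ds <- paclitaxel_study()
#' nca_summary(group_mean_profile(ds, "IHNP-HD", "lung", use_printed_means = TRUE))
#' @export
nca_summary <- function(profile, anchor_zero_at_t0 = TRUE,
                        lambda_window = NULL) {
  q <- quantified_points(profile)
  if (!nrow(q)) stop("profile has no quantified means")
  imax <- which.max(q$mean)  # which.max returns the earliest maximum
  tmax <- q$time_hr[imax]
  cmax <- q$mean[imax]
  row <- which(profile$time_hr == tmax)
  cmax_sd <- if (length(row)) profile$sd[row] else NA_real_
  auc <- auc_last(profile, anchor_zero_at_t0 = anchor_zero_at_t0)
  dose <- attr(profile, "dose_mg_per_kg")
  structure(list(arm = attr(profile, "arm"), matrix = attr(profile, "matrix"),
                 cmax = cmax, cmax_sd = cmax_sd, tmax_hr = tmax,
                 t_last_hr = q$time_hr[nrow(q)], auc_last = auc,
                 auc_d_last = if (is.null(dose) || is.na(dose)) NA_real_ else auc / dose,
                 dose_mg_per_kg = if (is.null(dose)) NA_real_ else dose,
                 lambda_fit = lambda_z_best_fit(profile, window = lambda_window),
                 unit = attr(profile, "unit")),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s / %s\n", x$arm, x$matrix))
  cat(sprintf("  Cmax %.4g %s at %g h; t_last %g h\n",
              x$cmax, x$unit, x$tmax_hr, x$t_last_hr))
  cat(sprintf("  AUC_last %.6g hr*%s", x$auc_last, x$unit))
  if (!is.na(x$auc_d_last)) {
    cat(sprintf("; AUC_D %.6g per mg/kg", x$auc_d_last))
  }
  cat("\n")
  if (!is.null(x$lambda_fit)) {
    cat(sprintf("  T1/2 %.3g h (lambda-z window {%s})\n",
                x$lambda_fit$half_life_hr,
                paste(x$lambda_fit$window, collapse = ", ")))
  } else cat("  terminal fit: unavailable\n")
  invisible(x)
}
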