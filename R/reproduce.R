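#' Reproduce the published pharmacokinetic summary from the packaged tables
#'
#' Runs the complete deterministic analysis chain on the packaged study
#' transcription and compares each result against the corresponding
#' printed value:
#'
#' * exposure-filter statistics (mean and SD of the drug aerosol
#'   concentration per inhaled arm) from the filter table;
#' * lung and plasma Cmax from the raw triplicate concentrations,
#'   rounded to 3 significant figures as in the published summary;
#' * lung AUC to the last quantifiable time by linear trapezoid with the
#'   (0, 0) anchor, on the printed group means;
#' * the intravenous-arm lung terminal half-life via the adjusted-R-squared
#'   best-fit lambda-z window, on the printed group means.
#'
#' Quantities the printed tables do not determine (inhaled-arm plasma AUC,
#' dose-normalized AUC, inhaled-arm lung half-lives, impactor stage data,
#' per-animal deposited doses) are deliberately not checked; see the
#' methods vignette.
#'
#' @param verbose print a per-check table and the lambda-z candidate
#'   windows.
#' @return A data.frame of class `reproduction_checks` with columns
#'   `check`, `expected`, `computed`, `rel_tol` and `pass`. The overall
#'   result is `all(x$pass)`.
#' @examples
#' checks <- reproduce_paper(verbose = FALSE)
#' all(checks$pass)
#' @export
reproduce_paper <- function(verbose = TRUE) {
  ds <- paclitaxel_study()
  checks <- list()
  add <- function(check, expected, computed, rel_tol) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      rel_tol = rel_tol,
      pass = is.finite(computed) &&
        abs(computed - expected) <= rel_tol * abs(expected),
      stringsAsFactors = FALSE)
  }

  ## exposure-atmosphere statistics (exact at 2-decimal display rounding)
  ld <- summarize_filters(ds$filters[ds$filters$arm == "IHNP-LD", ])
  hd <- summarize_filters(ds$filters[ds$filters$arm == "IHNP-HD", ])
  add("filter mean drug aerosol, IHNP-LD (ug/L)", 85.64,
      round(ld$mean_drug_ug_per_L, 2), 0)
  add("filter SD drug aerosol, IHNP-LD (ug/L)", 8.76, round(ld$sd_drug, 2), 0)
  add("filter mean drug aerosol, IHNP-HD (ug/L)", 262.27,
      round(hd$mean_drug_ug_per_L, 2), 0)

  ## Cmax from raw replicates, displayed at 3 significant figures
  cmax_expected <- list(
    c("IVnP", "lung", 5800), c("IHNP-LD", "lung", 21000),
    c("IHNP-HD", "lung", 41600), c("IVnP", "plasma", 206),
    c("IHNP-HD", "plasma", 15.9))
  for (ce in cmax_expected) {
    prof <- group_mean_profile(ds, ce[[1]], ce[[2]])
    res <- suppressMessages(nca_summary(prof))
    add(sprintf("Cmax, %s %s (%s)", ce[[1]], ce[[2]], MATRIX_UNITS[[ce[[2]]]]),
        as.numeric(ce[[3]]), signif(res$cmax, 3), 0)
  }

  ## lung AUC_last on the printed group means (0.1% relative)
  auc_expected <- list(c("IVnP", 62870), c("IHNP-LD", 342877),
                       c("IHNP-HD", 1155662))
  for (ae in auc_expected) {
    prof <- group_mean_profile(ds, ae[[1]], "lung", use_printed_means = TRUE)
    add(sprintf("AUC_last, %s lung (hr*ng/g)", ae[[1]]),
        as.numeric(ae[[2]]), auc_last(prof), 0.001)
  }

  ## intravenous-arm lung terminal half-life (0.5% before rounding)
  prof <- group_mean_profile(ds, "IVnP", "lung", use_printed_means = TRUE)
  lam <- lambda_z_best_fit(prof)
  if (verbose && !is.null(lam)) {
    cat(sprintf("lambda-z window for IVnP lung: {%s} h (adj R2 %.4f)\n",
                paste(lam$window, collapse = ", "), lam$adj_r_squared))
  }
  add("T1/2, IVnP lung (h)", 19.9,
      if (is.null(lam)) NA_real_ else lam$half_life_hr, 0.005)

  out <- do.call(rbind, checks)
  class(out) <- c("reproduction_checks", "data.frame")
  if (verbose) {
    print(out)
    cat(sprintf("%d/%d checks pass\n", sum(out$pass), nrow(out)))
  }
  invisible(out)
}

#' @export
print.reproduction_checks <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Concentration-time plot of group profiles
#'
#' Semilog overlay of one or more group mean profiles, the standard
#' visual check of multi-phase decay and BQL truncation.
#'
#' @param profiles list of `group_profile` objects.
#' @param main plot title.
#' @return `NULL`, invisibly (draws on the current device).
#' @export
plot_profiles <- function(profiles, main = "Group mean concentration-time") {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  xs <- unlist(lapply(profiles, function(p) p$time_hr))
  ys <- unlist(lapply(profiles, function(p) p$mean))
  ys <- ys[!is.na(ys)]
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), log = "y",
                 xlab = "time (h)", ylab = "concentration", main = main)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ok <- !is.na(p$mean)
    graphics::lines(p$time_hr[ok], p$mean[ok], type = "b", pch = 19, col = i)
  }
  graphics::legend("topright", bty = "n", col = seq_along(profiles), pch = 19,
                   legend = vapply(profiles, function(p)
                     paste(attr(p, "arm"), attr(p, "matrix")), character(1)))
  invisible(NULL)
}
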