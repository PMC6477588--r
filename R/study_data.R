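#' @keywords internal
"_PACKAGE"

# Arms of the study design: intravenous nab-paclitaxel control and the two
# inhaled submicron-particle arms (low / high dose).
STUDY_ARMS <- c("IVnP", "IHNP-LD", "IHNP-HD")
STUDY_MATRICES <- c("plasma", "lung")
MATRIX_UNITS <- c(plasma = "ng/mL", lung = "ng/g")

#' Construct a study dataset
#'
#' A `study_dataset` bundles everything one concentration-time study
#' produces: individual-animal concentration measurements (possibly
#' censored below the assay quantification limit, "BQL"), exposure-filter
#' samples for inhaled arms, optionally the group means as printed in a
#' source report, and the administered dose per arm.
#'
#' @param measurements data.frame with columns `animal`, `arm`, `matrix`,
#'   `time_hr`, `conc` (numeric, `NA` when censored), `bql` (logical) and
#'   `unit`.
#' @param filters data.frame with columns `arm`, `filter_id`,
#'   `total_mg_per_L`, `drug_ug_per_L`, or `NULL`.
#' @param printed_means data.frame of per-arm, per-matrix group means as
#'   printed (columns `arm`, `matrix`, `time_hr`, `mean`, `sd`,
#'   `n_quantified`, `n_total`), or `NULL`.
#' @param doses named numeric vector of administered dose in mg/kg per arm,
#'   or `NULL`.
#' @param arms character vector of valid arm labels.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(measurements, filters = NULL, printed_means = NULL,
                          doses = NULL, arms = STUDY_ARMS) {
  stopifnot(is.data.frame(measurements))
  req <- c("animal", "arm", "matrix", "time_hr", "conc", "bql", "unit")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    stop("measurements is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(measurements)) {
    bad_arm <- setdiff(unique(measurements$arm), arms)
    if (length(bad_arm)) {
      stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "))
    }
    if (any(measurements$time_hr < 0)) stop("time_hr must be non-negative")
    quant <- !measurements$bql
    if (any(is.na(measurements$conc[quant]))) {
      stop("quantified measurements must carry a numeric concentration")
    }
    if (any(measurements$conc[quant] <= 0)) {
      stop("quantified concentrations must be positive")
    }
    if (any(!is.na(measurements$conc) & measurements$bql)) {
      stop("a measurement cannot be both BQL and quantified")
    }
  }
  if (!is.null(filters) && nrow(filters)) {
    if (any(filters$total_mg_per_L <= 0) || any(filters$drug_ug_per_L <= 0)) {
      stop("filter concentrations must be positive")
    }
    # drug mass on the filter cannot exceed total collected aerosol mass
    if (any(filters$drug_ug_per_L > filters$total_mg_per_L * 1000)) {
      stop("drug aerosol concentration exceeds total aerosol concentration")
    }
  }
  structure(list(measurements = measurements, filters = filters,
                 printed_means = printed_means, doses = doses, arms = arms),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  m <- x$measurements
  cat("<study_dataset>\n")
  cat(sprintf("  %d measurements (%d BQL) across %d arm(s), matrices: %s\n",
              nrow(m), sum(m$bql), length(unique(m$arm)),
              paste(unique(m$matrix), collapse = ", ")))
  if (!is.null(x$filters)) cat(sprintf("  %d exposure filter sample(s)\n", nrow(x$filters)))
  if (!is.null(x$doses)) {
    cat("  doses (mg/kg): ",
        paste(sprintf("%s=%g", names(x$doses), x$doses), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a concentration-time table from delimited text
#'
#' Parses a CSV of individual-animal concentration measurements. Censored
#' observations are encoded by a token (default `"BQL"`) in the
#' concentration column and are kept as an explicit censoring state --
#' never as zero or as a fraction of the quantification limit.
#'
#' @param path path to a CSV file with a header row.
#' @param bql_token string marking a below-quantification-limit value.
#' @param col_map optional named character vector mapping the required
#'   names (`animal`, `arm`, `matrix`, `time_hr`, `concentration`, and
#'   optionally `unit`) to the headers actually present in the file.
#' @param arms valid arm labels; any other label is a validation error.
#' @param filters,printed_means,doses passed through to [study_dataset()].
#' @return A [study_dataset()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("animal,arm,matrix,time_hr,concentration,unit",
#'              "A1,IVnP,plasma,0.5,153,ng/mL",
#'              "A7,IHNP-LD,plasma,24,BQL,ng/mL"), f)
#' ds <- read_concentration_table(f)
#' ds$measurements$bql
#' @export
read_concentration_table <- function(path, bql_token = "BQL", col_map = NULL,
                                     arms = STUDY_ARMS, filters = NULL,
                                     printed_means = NULL, doses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("animal", "arm", "matrix", "time_hr", "concentration")
  map <- stats::setNames(required, required)
  map["unit"] <- "unit"
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  missing_cols <- setdiff(unname(map[required]), names(raw))
  if (length(missing_cols)) {
    stop("input file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  conc_chr <- trimws(raw[[map["concentration"]]])
  bql <- conc_chr == bql_token
  conc <- rep(NA_real_, n)
  if (any(!bql)) {
    conc[!bql] <- suppressWarnings(as.numeric(conc_chr[!bql]))
    bad <- which(!bql & is.na(conc))
    if (length(bad)) {
      stop("row ", bad[1], ": concentration '", conc_chr[bad[1]],
           "' is neither numeric nor the BQL token '", bql_token, "'")
    }
  }
  time_hr <- suppressWarnings(as.numeric(raw[[map["time_hr"]]]))
  if (anyNA(time_hr)) stop("row ", which(is.na(time_hr))[1], ": non-numeric time")
  bad_t <- which(time_hr < 0)
  if (length(bad_t)) stop("row ", bad_t[1], ": negative time")
  bad_c <- which(!bql & conc <= 0)
  if (length(bad_c)) stop("row ", bad_c[1], ": non-positive concentration")

  matrix <- raw[[map["matrix"]]]
  bad_m <- which(!matrix %in% STUDY_MATRICES)
  if (length(bad_m)) stop("row ", bad_m[1], ": unknown matrix '", matrix[bad_m[1]], "'")
  arm <- raw[[map["arm"]]]
  bad_a <- which(!arm %in% arms)
  if (length(bad_a)) stop("row ", bad_a[1], ": unknown arm label '", arm[bad_a[1]], "'")

  unit <- if (map["unit"] %in% names(raw)) raw[[map["unit"]]] else
    unname(MATRIX_UNITS[matrix])
  expected <- unname(MATRIX_UNITS[matrix])
  bad_u <- which(n > 0 & unit != expected)
  if (length(bad_u)) {
    stop("row ", bad_u[1], ": unit '", unit[bad_u[1]], "' does not match matrix '",
         matrix[bad_u[1]], "' (expected ", expected[bad_u[1]], ")")
  }
  measurements <- data.frame(animal = raw[[map["animal"]]], arm = arm,
                             matrix = matrix, time_hr = time_hr, conc = conc,
                             bql = bql, unit = unit, stringsAsFactors = FALSE)
  study_dataset(measurements, filters = filters, printed_means = printed_means,
                doses = doses, arms = arms)
}

#' Write a concentration-time table as delimited text
#'
#' Inverse of [read_concentration_table()]: censored rows are written with
#' the BQL token, quantified rows at full (17 significant digit) precision
#' so a write/read round trip is exact.
#'
#' @param ds a [study_dataset()].
#' @param path output CSV path.
#' @param bql_token token to write for censored rows.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(ds, path, bql_token = "BQL") {
  stopifnot(inherits(ds, "study_dataset"))
  m <- ds$measurements
  out <- data.frame(animal = m$animal, arm = m$arm, matrix = m$matrix,
                    time_hr = sprintf("%.17g", m$time_hr),
                    concentration = ifelse(m$bql, bql_token,
                                           sprintf("%.17g", m$conc)),
                    unit = m$unit)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged inhaled-paclitaxel study
#'
#' Returns the full transcription of the published rodent study: 7
#' exposure-filter samples per inhaled arm, triplicate plasma and lung
#' concentrations for 3 arms at 10 necropsy times (0.5 to 336 h), the
#' group means and standard deviations exactly as printed, and the
#' administered doses (2.9, 0.38, 1.18 mg/kg).
#'
#' Group means in the source report show nonuniform rounding (e.g. a mean
#' of 244 printed for replicates 307/190/237), so the printed means are
#' carried verbatim alongside the raw replicates; see
#' [group_mean_profile()]'s `use_printed_means`.
#'
#' @return A [study_dataset()].
#' @examples
#' ds <- paclitaxel_study()
#' subset(ds$measurements, arm == "IHNP-HD" & matrix == "lung" & time_hr == 0.5)
#' @export
paclitaxel_study <- function() {
  ext <- function(f) system.file("extdata", f, package = "pulmopk", mustWork = TRUE)
  filters <- utils::read.csv(ext("filter_samples.csv"), stringsAsFactors = FALSE)
  pm <- utils::read.csv(ext("printed_means.csv"), stringsAsFactors = FALSE)
  read_concentration_table(ext("concentrations.csv"),
                           filters = filters, printed_means = pm,
                           doses = c(`IVnP` = 2.9, `IHNP-LD` = 0.38,
                                     `IHNP-HD` = 1.18))
}

#' Write a pharmacokinetic summary report
#'
#' Emits one row per arm-by-matrix noncompartmental result with the
#' parameters at full precision, plus display columns that mimic the usual
#' published rounding (3 significant figures for Cmax and half-life,
#' integer AUC).
#'
#' @param results a list of [nca_summary()] results.
#' @param path output CSV path.
#' @return The report data.frame, invisibly.
#' @export
write_pk_report <- function(results, path) {
  if (!length(results)) stop("at least one NCA result is required")
  if (inherits(results, "nca_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "nca_result"))
    lam <- r$lambda_fit
    data.frame(
      arm = r$arm %||% NA_character_, matrix = r$matrix %||% NA_character_,
      cmax = r$cmax, cmax_sd = r$cmax_sd %||% NA_real_, tmax_hr = r$tmax_hr,
      t_last_hr = r$t_last_hr, auc_last = r$auc_last,
      auc_d_last = r$auc_d_last %||% NA_real_,
      lambda_z_per_hr = if (is.null(lam)) NA_real_ else lam$lambda_z,
      t_half_hr = if (is.null(lam)) NA_real_ else lam$half_life_hr,
      lambda_window = if (is.null(lam)) "" else paste(lam$window, collapse = ";"),
      cmax_printed = formatC(signif(r$cmax, 3), format = "fg", big.mark = ","),
      t_half_printed = if (is.null(lam)) "" else sprintf("%.1f", lam$half_life_hr),
      auc_last_printed = formatC(round(r$auc_last), format = "d", big.mark = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  disp <- out
  disp[num] <- lapply(out[num], function(v) ifelse(is.na(v), "", sprintf("%.17g", v)))
  tryCatch(utils::write.csv(disp, path, row.names = FALSE, quote = TRUE),
           error = function(e) stop("cannot write report to '", path, "': ",
                                    conditionMessage(e)))
  invisible(out)
}

#' Read back a pharmacokinetic summary report
#'
#' @param path CSV written by [write_pk_report()].
#' @return data.frame with numeric columns restored at full precision.
#' @export
read_pk_report <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  num_cols <- c("cmax", "cmax_sd", "tmax_hr", "t_last_hr", "auc_last",
                "auc_d_last", "lambda_z_per_hr", "t_half_hr")
  for (nc in intersect(num_cols, names(out))) {
    out[[nc]] <- suppressWarnings(as.numeric(out[[nc]]))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
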