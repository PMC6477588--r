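test_that("filter summaries reproduce the published exposure statistics", {
  ds <- paclitaxel_study()
  ld <- summarize_filters(ds$filters[ds$filters$arm == "IHNP-LD", ])
  expect_equal(round(ld$mean_drug_ug_per_L, 2), 85.64)
  expect_equal(round(ld$sd_drug, 2), 8.76)
  expect_equal(round(ld$pct_rsd_drug, 2), 10.23)
  expect_equal(round(ld$mean_total_mg_per_L, 2), 0.25)
  expect_equal(round(ld$pct_rsd_total, 2), 7.43)

  hd <- summarize_filters(ds$filters[ds$filters$arm == "IHNP-HD", ])
  expect_equal(round(hd$mean_drug_ug_per_L, 2), 262.27)
  expect_equal(round(hd$sd_drug, 2), 31.45)
  expect_equal(round(hd$pct_rsd_drug, 2), 11.99)
})

test_that("filter summary matches a two-pass oracle and handles edge cases", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(2:12, 1), 10, 300)
    s <- summarize_filters(data.frame(drug_ug_per_L = x, total_mg_per_L = x / 300))
    o <- naive_mean_sd(x)
    expect_equal(s$mean_drug_ug_per_L, o$mean, tolerance = 1e-12)
    expect_equal(s$sd_drug, o$sd, tolerance = 1e-12)
    expect_equal(s$pct_rsd_drug, 100 * o$sd / o$mean, tolerance = 1e-12)
  }
  ident <- summarize_filters(data.frame(drug_ug_per_L = c(5, 5, 5),
                                        total_mg_per_L = c(1, 1, 1)))
  expect_equal(ident$mean_drug_ug_per_L, 5)
  expect_equal(ident$sd_drug, 0)
  expect_equal(ident$pct_rsd_drug, 0)

  single <- summarize_filters(data.frame(drug_ug_per_L = 80, total_mg_per_L = 0.2))
  expect_equal(single$mean_drug_ug_per_L, 80)
  expect_true(is.na(single$sd_drug))
  expect_error(summarize_filters(data.frame()), "at least one")
})

test_that("impactor fit recovers MMAD and GSD exactly from lognormal stages", {
  for (mmad in c(0.5, 1.2, 1.8, 2.3, 3.7, 5)) {
    for (gsd in c(1.2, 1.9, 2.0, 2.5, 3)) {
      st <- lognormal_stage_masses(mmad, gsd, default_cutoffs)
      fit <- fit_impactor(impactor_run(default_cutoffs, st$mass,
                                       final_filter_mass = st$filter))
      expect_equal(fit$mmad_um, mmad, tolerance = 1e-9)
      expect_equal(fit$gsd, gsd, tolerance = 1e-9)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
      expect_gte(fit$gsd, 1)
    }
  }
})

test_that("degenerate impactor inputs are rejected", {
  # monodisperse: all mass between two adjacent cutoffs -> < 3 interior points
  mass <- c(0, 0, 1, 0, 0, 0, 0)
  expect_error(fit_impactor(impactor_run(default_cutoffs, mass)),
               "fewer than 3 interior")
  expect_error(fit_impactor(impactor_run(default_cutoffs, rep(0, 7))),
               "no mass")
  expect_error(impactor_run(c(5, 10, 2.5), c(1, 1, 1)), "decreasing")
  expect_error(impactor_run(c(10, 5, 2.5), c(1, -1, 1)), "non-negative")
})

test_that("impactor stage CSV reader handles the backup filter row", {
  st <- lognormal_stage_masses(2.3, 1.9, default_cutoffs)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(stage = c(1:7, "F"),
                       cutoff_um = c(default_cutoffs, NA),
                       mass = c(st$mass, st$filter)),
            f, row.names = FALSE)
  fit <- fit_impactor(read_impactor_table(f))
  expect_equal(fit$mmad_um, 2.3, tolerance = 1e-9)
  expect_equal(fit$gsd, 1.9, tolerance = 1e-9)
})

test_that("calibration QC applies the correlation and recovery rules", {
  std <- data.frame(nominal = c(1, 10, 100, 1000),
                    measured = 2 * c(1, 10, 100, 1000))
  qc <- check_calibration(std)
  expect_equal(qc$correlation, 1, tolerance = 1e-12)
  expect_equal(qc$standard_recovery_pct, rep(100, 4), tolerance = 1e-9)
  expect_true(qc$pass)

  bad_qc <- data.frame(nominal = 80, measured = 2 * 80 * 1.20)
  qc2 <- check_calibration(std, qcs = bad_qc)
  expect_equal(qc2$qc_recovery_pct, 120, tolerance = 1e-9)
  expect_false(qc2$pass)

  expect_error(check_calibration(data.frame(nominal = c(-1, 2, 3),
                                            measured = c(1, 2, 3))),
               "positive")
  expect_error(check_calibration(data.frame(nominal = c(1, 1, 1),
                                            measured = c(1, 2, 3))),
               "distinct")
})

test_that("1/x^2 weighting matches a grid oracle and beats unweighted fits", {
  set.seed(7)
  x <- c(1, 5, 10, 50, 100, 500, 1000)
  true_slope <- 2
  # proportional (heteroscedastic) noise, large at the top of the range
  y <- true_slope * x * (1 + c(0.01, -0.02, 0.015, -0.01, 0.05, -0.20, 0.25))
  qc <- check_calibration(data.frame(nominal = x, measured = y))

  o <- grid_wls(x, y, slope_grid = seq(1.9, 2.1, by = 1e-4),
                intercept_grid = seq(-0.05, 0.05, by = 1e-3))
  expect_equal(qc$slope, o$slope, tolerance = 1e-3)
  expect_lt(abs(qc$intercept - o$intercept), 1e-3)  # grid step on intercept

  unweighted <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(qc$slope - true_slope), abs(unweighted - true_slope))
})

test_that("worsening a recovery never flips a failing run to pass", {
  std <- data.frame(nominal = c(1, 10, 100), measured = c(1, 10, 100))
  qcs <- data.frame(nominal = c(5, 50), measured = c(5 * 1.2, 50))
  base <- check_calibration(std, qcs = qcs)
  expect_false(base$pass)
  for (worse in c(1.25, 1.5, 2, 5)) {
    qcs2 <- qcs
    qcs2$measured[1] <- 5 * worse
    expect_false(check_calibration(std, qcs = qcs2)$pass)
  }
})
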