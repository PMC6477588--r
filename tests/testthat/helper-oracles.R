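# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# adaptive quadrature of the piecewise-linear interpolant through (t, y),
# optionally with a (0, 0) anchor — an AUC oracle independent of the
# closed-form trapezoid
quadrature_auc <- function(t, y, anchor_zero = TRUE) {
  if (anchor_zero && t[1] > 0) {
    t <- c(0, t)
    y <- c(0, y)
  }
  f <- stats::approxfun(t, y)
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    total <- total + stats::integrate(f, t[i], t[i + 1],
                                      rel.tol = 1e-12)$value
  }
  total
}

# two-pass mean / sample SD oracle
naive_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# exhaustive enumeration of contiguous terminal log-linear windows
# (ending at the last quantified point, >= 3 points, excluding Tmax),
# returning the window with maximal adjusted R^2; ties to larger window
brute_force_lambda_window <- function(t, y) {
  tmax <- t[which.max(y)]
  keep <- t > tmax
  t <- t[keep]
  y <- y[keep]
  n <- length(t)
  best <- NULL
  for (start in seq_len(n - 2)) {
    idx <- start:n
    ly <- log(y[idx])
    tt <- t[idx]
    fit <- lm(ly ~ tt)
    r2 <- cor(tt, ly)^2
    k <- length(idx)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-12 ||
        abs(adj - best$adj) <= 1e-12 && k > length(best$window)) {
      best <- list(window = tt, adj = adj, slope = unname(coef(fit)[2]))
    }
  }
  best
}

# grid minimizer of the 1/x^2-weighted squared loss for a straight line
grid_wls <- function(x, y, slope_grid, intercept_grid) {
  best <- NULL
  for (b in slope_grid) {
    for (a in intercept_grid) {
      loss <- sum((y - a - b * x)^2 / x^2)
      if (is.null(best) || loss < best$loss) {
        best <- list(slope = b, intercept = a, loss = loss)
      }
    }
  }
  best
}

# lognormal stage masses evaluated directly from the CDF (no package code)
lognormal_stage_masses <- function(mmad, gsd, cutoffs, total = 1) {
  finer <- plnorm(cutoffs, log(mmad), log(gsd))
  list(mass = (c(1, finer[-length(finer)]) - finer) * total,
       filter = finer[length(finer)] * total)
}

default_cutoffs <- c(10, 5, 2.5, 1.25, 0.63, 0.31, 0.16)
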