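# Independent oracles used to cross-check the closed forms. These stay
# deliberately separate from the implementation: numerical integration and
# direct density evaluation instead of the analytic shortcuts.

# ROC integral by the trapezoid rule on a fine FPR grid.
oracle_auc_by_integration <- function(delta, n_grid = 20000L) {
  f <- seq(1e-7, 1 - 1e-7, length.out = n_grid)
  dr <- pnorm(delta - qnorm(1 - f))
  sum(diff(f) * (head(dr, -1) + tail(dr, -1)) / 2) +
    # close the [0, f_min] and [f_max, 1] end caps linearly
    f[1] * dr[1] / 2 + (1 - f[n_grid]) * (dr[n_grid] + 1) / 2
}

# Likelihood ratio as a direct ratio of normal densities.
oracle_lr_density_ratio <- function(delta, z) {
  dnorm(z, mean = delta, sd = 1) / dnorm(z, mean = 0, sd = 1)
}

# Stratum case share by trapezoid integration of the affected density
# between the unaffected-distribution centile cut-offs.
oracle_case_share_integration <- function(delta, lower, upper,
                                          n_grid = 200000L) {
  zlo <- if (lower == 0) -10 + min(0, delta) else qnorm(lower)
  zhi <- if (upper == 1) 10 + max(0, delta) else qnorm(upper)
  x <- seq(zlo, zhi, length.out = n_grid)
  y <- dnorm(x, mean = delta)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Independent inversion of the extreme-quantile OR via stats::uniroot.
oracle_delta_from_eq_or <- function(or_value, fraction) {
  zs <- qnorm(1 - fraction)
  f <- function(d) pnorm(d - zs) / pnorm(-zs - d) - or_value
  uniroot(f, lower = -15, upper = 15, tol = 1e-12)$root
}

# Paper-anchored separations, recomputed here from their defining
# operating points rather than imported from the implementation.
delta_dr5_80 <- qnorm(0.80) + qnorm(0.95)   # good screening benchmark
delta_dr5_11 <- qnorm(0.11) + qnorm(0.95)   # typical polygenic score
delta_dr5_15 <- qnorm(0.15) + qnorm(0.95)   # breast-cancer score
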