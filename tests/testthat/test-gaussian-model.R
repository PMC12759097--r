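# Closed-form calculus under the equal-variance Gaussian model.

test_that("dr_at_fpr reproduces the defining cases", {
  # no separation: DR equals FPR for any cut-off
  for (f in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
    expect_equal(dr_at_fpr(0, f), f, tolerance = 1e-12)
  }
  # reported OR/SD 1.49 -> DR5 11%; 1.73 -> 14%
  expect_equal(round(100 * dr_at_fpr(log(1.49), 0.05)), 11)
  expect_equal(round(100 * dr_at_fpr(log(1.73), 0.05)), 14)
  # round trip of the good-test benchmark
  expect_equal(dr_at_fpr(delta_dr5_80, 0.05), 0.80, tolerance = 1e-9)
})

test_that("dr_at_fpr is strictly increasing in delta and fpr and rejects bad fpr", {
  deltas <- seq(0, 3, by = 0.25)
  expect_true(all(diff(dr_at_fpr(separation_model(0.7),
                                 seq(0.01, 0.99, by = 0.01))) > 0))
  drs <- vapply(deltas, function(d) dr_at_fpr(d, 0.05), numeric(1))
  expect_true(all(diff(drs) > 0))
  expect_error(dr_at_fpr(0.5, 0), "fpr")
  expect_error(dr_at_fpr(0.5, 1), "fpr")
})

test_that("delta round-trips with every metric to 1e-9", {
  for (delta in c(-0.8, 0, 0.4183, 0.6084, 1.2, 2.4865)) {
    m <- separation_model(delta)
    # operating point
    dr <- dr_at_fpr(m, 0.05)
    expect_equal(delta_from_operating_point(dr = dr, fpr = 0.05)$delta,
                 delta, tolerance = 1e-9)
    # OR/SD
    expect_equal(delta_from_or_per_sd(or_per_sd_from_delta(m))$delta,
                 delta, tolerance = 1e-9)
    # AUC
    expect_equal(delta_from_auc(auc_from_delta(m))$delta,
                 delta, tolerance = 1e-9)
    # extreme-quantile OR at several fractions
    for (f in c(0.03, 0.20, 0.45)) {
      orv <- extreme_quantile_or(m, f)
      expect_equal(delta_from_extreme_quantile_or(orv, f)$delta,
                   delta, tolerance = 1e-8)
    }
  }
})

test_that("AUC closed form matches the ROC-integral oracle", {
  for (delta in c(0, 0.4183, 0.6084, 1.5, 2.4865)) {
    expect_equal(auc_from_delta(delta), oracle_auc_by_integration(delta),
                 tolerance = 1e-6)
  }
  expect_equal(auc_from_delta(0), 0.5, tolerance = 1e-12)
  expect_equal(round(auc_from_delta(delta_dr5_80), 2), 0.96)
  expect_equal(round(auc_from_delta(delta_dr5_11), 2), 0.62)
})

test_that("extreme-quantile OR matches its examples and monotonicity", {
  expect_equal(extreme_quantile_or(0, 0.20), 1, tolerance = 1e-12)
  expect_equal(round(extreme_quantile_or(delta_dr5_11, 0.20)), 3)
  expect_equal(extreme_quantile_or(delta_dr5_11, 0.20), 3.236,
               tolerance = 1e-3)
  # the often-quoted 2284 quintile OR corresponds to delta = 2.5 exactly
  expect_equal(round(extreme_quantile_or(2.5, 0.20)), 2284)
  # increasing in delta; for delta > 0, increasing as the tail narrows
  ors <- vapply(seq(0, 3, 0.5), function(d) extreme_quantile_or(d, 0.2),
                numeric(1))
  expect_true(all(diff(ors) > 0))
  by_frac <- vapply(c(0.45, 0.30, 0.20, 0.10, 0.03),
                    function(f) extreme_quantile_or(1.2, f), numeric(1))
  expect_true(all(diff(by_frac) > 0))
  expect_error(extreme_quantile_or(1, 0.6), "fraction")
})

test_that("bisection inversion agrees with an independent root-finder", {
  cases <- expand.grid(or = c(1.5, 3, 10, 100, 1000, 10000),
                       frac = c(0.03, 0.20, 0.40))
  for (i in seq_len(nrow(cases))) {
    got <- delta_from_extreme_quantile_or(cases$or[i], cases$frac[i])$delta
    expect_equal(got, oracle_delta_from_eq_or(cases$or[i], cases$frac[i]),
                 tolerance = 1e-7)
  }
  # quintile-OR ladder: 10 -> DR5 about 20%
  lad <- vapply(c(10, 100, 1000, 10000), function(orv) {
    dr_at_fpr(delta_from_extreme_quantile_or(orv, 0.20), 0.05)
  }, numeric(1))
  expect_equal(round(100 * lad[1]), 20)
  expect_true(all(diff(lad) > 0))
  # protective direction reflects through symmetry
  expect_equal(delta_from_extreme_quantile_or(0.1, 0.2)$delta,
               -delta_from_extreme_quantile_or(10, 0.2)$delta,
               tolerance = 1e-9)
})

test_that("delta_from_metric dispatches consistently over all kinds", {
  expect_equal(delta_from_metric(kind = "or_per_sd", value = 1.73)$delta,
               log(1.73), tolerance = 1e-12)
  expect_equal(delta_from_metric(kind = "auc", value = 0.5)$delta, 0,
               tolerance = 1e-12)
  expect_equal(
    delta_from_metric(kind = "extreme_quantile_or", value = 3.236,
                      extreme_fraction = 0.20)$delta,
    delta_dr5_11, tolerance = 1e-3)
  expect_equal(delta_from_metric(kind = "dr5", value = 0.15)$delta,
               delta_dr5_15, tolerance = 1e-12)
  # hazard ratios ride the OR conversion but record the approximation
  hr <- delta_from_metric(kind = "hr_per_sd", value = 1.49)
  expect_equal(hr$delta, log(1.49), tolerance = 1e-12)
  expect_match(attr(hr, "conversion"), "rare-disease")
  expect_error(delta_from_metric(kind = "extreme_quantile_or", value = 3),
               "extreme_fraction")
  expect_error(reported_metric("auc", 1.2), "0, 1")
})

test_that("likelihood ratio equals the density ratio and is log-linear", {
  zs <- seq(-3, 3, by = 0.5)
  for (delta in c(0.4183, 0.5481, 2.4865)) {
    expect_equal(likelihood_ratio(delta, zs),
                 oracle_lr_density_ratio(delta, zs), tolerance = 1e-12)
    # LR = 1 exactly midway between the two means
    expect_equal(likelihood_ratio(delta, delta / 2), 1, tolerance = 1e-12)
    # log LR linear in z with slope delta
    slopes <- diff(log(likelihood_ratio(delta, zs))) / diff(zs)
    expect_equal(slopes, rep(delta, length(slopes)), tolerance = 1e-9)
  }
  expect_equal(likelihood_ratio(0.5481, 1.645), 2.12, tolerance = 1e-2)
  expect_equal(likelihood_ratio(0.7, 0), exp(-0.7^2 / 2), tolerance = 1e-12)
})

test_that("risk_profile applies Bayes across centiles", {
  # null score: posterior risk equals the prior everywhere
  rp0 <- risk_profile(0, c(0.05, 0.5, 0.95), prior_odds = "1:9")
  expect_equal(rp0$posterior_risk, rep(0.10, 3), tolerance = 1e-12)
  # typical score at the 95th centile with 10% background risk
  rp <- risk_profile(delta_dr5_11, 0.95, prior_odds = "1:9")
  expect_equal(rp$likelihood_ratio, 1.82, tolerance = 1e-2)
  expect_equal(rp$posterior_risk, 0.1685, tolerance = 1e-3)
  # log-LR column is a straight line in z
  rp2 <- risk_profile(0.5481, seq(0.01, 0.99, by = 0.01))
  fit <- lm(log(likelihood_ratio) ~ z, data = rp2)
  expect_equal(unname(coef(fit)[2]), 0.5481, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_error(risk_profile(0.5, 0.95, prior_odds = "-1:9"), "odds")
  expect_error(risk_profile(0.5, c(0, 0.5)), "centiles")
})

test_that("ppv_from_operating_point reproduces the odds arithmetic", {
  expect_equal(round(100 * ppv_from_operating_point(
    dr = 0.11, fpr = 0.05, prior_odds = "1:9")), 20)
  expect_equal(ppv_from_operating_point(dr = 0.80, fpr = 0.05,
                                        prior_odds = "1:9"),
               0.80 / (0.80 + 0.45), tolerance = 1e-12)
  # an uninformative test leaves the prior risk unchanged
  for (f in c(0.05, 0.3)) {
    expect_equal(ppv_from_operating_point(dr = f, fpr = f, prior_odds = 0.25),
                 0.2, tolerance = 1e-12)
  }
  # prior odds parsing equivalences
  expect_equal(parse_prior_odds("1:9"), 1 / 9, tolerance = 1e-12)
  expect_equal(parse_prior_odds(risk = 0.10), 1 / 9, tolerance = 1e-12)
  expect_equal(parse_prior_odds(0.25), 0.25)
  expect_error(parse_prior_odds("1:0"), "odds")
})

test_that("monotone ladder: larger OR/SD means larger DR5", {
  # reproduces the 'negligible improvement' orderings: 1.49 < 1.73,
  # 8% -> 10% and 13% -> 15% style upgrades keep their order
  ors <- c(1.2, 1.49, 1.6, 1.73, 2.5, 12)
  dr5s <- vapply(ors, function(o) dr_at_fpr(delta_from_or_per_sd(o), 0.05),
                 numeric(1))
  expect_true(all(diff(dr5s) > 0))
})

test_that("constructors validate their domains", {
  expect_error(separation_model(Inf), "finite")
  expect_error(separation_model("a"), "finite")
  expect_error(operating_point(0, 0.5), "fpr")
  expect_error(operating_point(0.5, 1), "dr")
  expect_error(delta_from_or_per_sd(0), "positive")
  expect_error(delta_from_or_per_sd(-1), "positive")
  # protective metrics reflect rather than fail
  expect_lt(delta_from_or_per_sd(0.8)$delta, 0)
  expect_lt(delta_from_auc(0.4)$delta, 0)
})
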