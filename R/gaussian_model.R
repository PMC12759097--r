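# Closed-form screening-performance calculus under the equal-variance
# Gaussian (binormal) model. The unaffected score distribution is standard
# normal; the affected distribution is normal(delta, 1). A single parameter,
# delta (the mean separation in unaffected-SD units), determines every
# screening property of the score.

#' Construct a separation model
#'
#' The equal-variance Gaussian model for a continuous screening marker:
#' unaffected individuals have standard-normal marker values, affected
#' individuals are shifted by `delta` standard deviations. All screening
#' performance (detection rate, false positive rate, AUC, odds ratios,
#' likelihood ratios) is a function of `delta` alone.
#'
#' @param delta Mean difference between affected and unaffected groups, in
#'   unaffected-SD units (a z-score). Negative values describe a protective
#'   marker and are permitted.
#' @return An object of class `separation_model`.
#' @examples
#' separation_model(0.4)
#' @export
separation_model <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("`delta` must be a single finite number (SD units)", call. = FALSE)
  }
  structure(list(delta = as.numeric(delta)), class = "separation_model")
}

#' @export
print.separation_model <- function(x, ...) {
  cat(sprintf("Equal-SD Gaussian separation model: delta = %.4f SD\n", x$delta))
  cat(sprintf("  DR_5 = %s   AUC = %.4f   OR/SD = %.3f\n",
              format_percent(dr_at_fpr(x, 0.05)),
              auc_from_delta(x), or_per_sd_from_delta(x)))
  invisible(x)
}

# Accept either a separation_model or a bare numeric delta.
as_delta <- function(model) {
  if (inherits(model, "separation_model")) return(model$delta)
  if (is.numeric(model) && length(model) == 1L && is.finite(model)) {
    return(as.numeric(model))
  }
  stop("expected a `separation_model` or a single finite numeric delta",
       call. = FALSE)
}

#' Construct an operating point
#'
#' A (false positive rate, detection rate) pair on a ROC curve.
#'
#' @param fpr False positive rate, strictly between 0 and 1.
#' @param dr Detection rate (sensitivity), strictly between 0 and 1.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(fpr, dr) {
  check_proportion(fpr, "fpr", open = TRUE)
  check_proportion(dr, "dr", open = TRUE)
  structure(list(fpr = as.numeric(fpr), dr = as.numeric(dr)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point: DR = %s at FPR = %s\n",
              format_percent(x$dr), format_percent(x$fpr)))
  invisible(x)
}

check_proportion <- function(x, name, open = FALSE, upper = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < upper else x >= 0 && x <= upper)
  if (!ok) {
    bound <- if (open) sprintf("in (0, %g)", upper) else sprintf("in [0, %g]", upper)
    stop(sprintf("`%s` must be a single proportion %s", name, bound),
         call. = FALSE)
  }
  invisible(x)
}

#' Detection rate at a given false positive rate
#'
#' The cut-off is placed at the (1 - fpr) quantile of the unaffected
#' (standard normal) distribution; the detection rate is the share of the
#' affected distribution above it: `DR = pnorm(delta - qnorm(1 - fpr))`.
#' `dr_at_fpr(model, 0.05)` is the DR5 summary: the detection rate for a
#' 5% false positive rate, i.e. a cut-off at the 95th centile of the
#' unaffected distribution.
#'
#' @param model A `separation_model` (or a bare numeric delta).
#' @param fpr False positive rate(s), strictly inside (0, 1). Vectorised.
#' @return Detection rate(s) in (0, 1).
#' @examples
#' dr_at_fpr(separation_model(log(1.49)), 0.05)  # ~0.11
#' @export
dr_at_fpr <- function(model, fpr) {
  delta <- as_delta(model)
  if (!is.numeric(fpr) || any(!is.finite(fpr)) || any(fpr <= 0 | fpr >= 1)) {
    stop("`fpr` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::pnorm(delta - stats::qnorm(1 - fpr))
}

#' Separation implied by an operating point
#'
#' Inverts [dr_at_fpr()]: `delta = qnorm(dr) + qnorm(1 - fpr)`.
#'
#' @param point An `operating_point`, or `dr` and `fpr` given directly.
#' @param dr,fpr Alternative scalar interface.
#' @return A `separation_model`.
#' @examples
#' delta_from_operating_point(dr = 0.80, fpr = 0.05)  # delta ~ 2.5
#' @export
delta_from_operating_point <- function(point = NULL, dr = NULL, fpr = NULL) {
  if (!is.null(point)) {
    if (!inherits(point, "operating_point")) {
      stop("`point` must be an `operating_point`", call. = FALSE)
    }
    dr <- point$dr
    fpr <- point$fpr
  }
  check_proportion(dr, "dr", open = TRUE)
  check_proportion(fpr, "fpr", open = TRUE)
  separation_model(stats::qnorm(dr) + stats::qnorm(1 - fpr))
}

#' Separation from the odds ratio per SD
#'
#' Under the equal-variance Gaussian model the log odds of disease is linear
#' in the score with slope delta, so the odds ratio for a 1-SD increment is
#' `exp(delta)` (exact in the rare-disease limit): `delta = log(or_per_sd)`.
#' Values below 1 (protective direction) give negative delta.
#'
#' @param or_per_sd Odds ratio per 1-SD increment of the score; positive.
#' @return A `separation_model`.
#' @examples
#' dr_at_fpr(delta_from_or_per_sd(1.73), 0.05)  # ~0.14
#' @export
delta_from_or_per_sd <- function(or_per_sd) {
  if (!is.numeric(or_per_sd) || length(or_per_sd) != 1L ||
      !is.finite(or_per_sd) || or_per_sd <= 0) {
    stop("`or_per_sd` must be a single positive number", call. = FALSE)
  }
  separation_model(log(or_per_sd))
}

#' @rdname delta_from_or_per_sd
#' @param model A `separation_model` (or bare delta).
#' @export
or_per_sd_from_delta <- function(model) exp(as_delta(model))

#' Area under the ROC curve
#'
#' Binormal equal-variance closed form: `AUC = pnorm(delta / sqrt(2))`.
#'
#' @param model A `separation_model` (or bare delta).
#' @return AUC in (0, 1); 0.5 when delta = 0.
#' @export
auc_from_delta <- function(model) stats::pnorm(as_delta(model) / sqrt(2))

#' @rdname auc_from_delta
#' @param auc AUC in (0, 1); values below 0.5 reflect to negative delta.
#' @export
delta_from_auc <- function(auc) {
  check_proportion(auc, "auc", open = TRUE)
  separation_model(sqrt(2) * stats::qnorm(auc))
}

#' Odds ratio comparing extreme quantile groups
#'
#' The odds ratio for disease comparing membership of the top versus the
#' bottom `fraction` of the score distribution (quantile cut-offs taken on
#' the unaffected, standard-normal distribution). With
#' `z* = qnorm(1 - fraction)`, the affected shares of the two tails are
#' `pnorm(delta - z*)` and `pnorm(-z* - delta)` while the unaffected shares
#' are equal, so `OR = pnorm(delta - z*) / pnorm(-z* - delta)`.
#'
#' @param model A `separation_model` (or bare delta).
#' @param fraction Tail fraction in (0, 0.5); 0.20 compares quintiles.
#' @return A positive odds ratio; 1 when delta = 0.
#' @examples
#' extreme_quantile_or(separation_model(0.4183), 0.20)  # ~3.2
#' @export
extreme_quantile_or <- function(model, fraction) {
  delta <- as_delta(model)
  check_proportion(fraction, "fraction", open = TRUE, upper = 0.5)
  zs <- stats::qnorm(1 - fraction)
  stats::pnorm(delta - zs) / stats::pnorm(-zs - delta)
}

#' Separation from an extreme-quantile odds ratio
#'
#' Inverts [extreme_quantile_or()] by bisection on delta in \[0, 15\]
#' (the odds ratio is strictly increasing in delta), to relative tolerance
#' 1e-10. Odds ratios below 1 are handled by symmetry (negative delta).
#'
#' @param or_value Observed odds ratio comparing top vs bottom tail groups.
#' @param fraction Tail fraction in (0, 0.5).
#' @return A `separation_model`.
#' @examples
#' delta_from_extreme_quantile_or(10, 0.20)  # delta ~ 0.81, DR5 ~ 20%
#' @export
delta_from_extreme_quantile_or <- function(or_value, fraction) {
  if (!is.numeric(or_value) || length(or_value) != 1L ||
      !is.finite(or_value) || or_value <= 0) {
    stop("`or_value` must be a single positive number", call. = FALSE)
  }
  check_proportion(fraction, "fraction", open = TRUE, upper = 0.5)
  if (or_value < 1) {
    # protective direction: OR(delta) * OR(-delta) = 1
    refl <- delta_from_extreme_quantile_or(1 / or_value, fraction)
    return(separation_model(-refl$delta))
  }
  if (or_value == 1) return(separation_model(0))
  lo <- 0
  hi <- 15
  if (extreme_quantile_or(hi, fraction) < or_value) {
    stop("`or_value` exceeds the invertible range (delta > 15 SD)",
         call. = FALSE)
  }
  repeat {
    mid <- (lo + hi) / 2
    f <- extreme_quantile_or(mid, fraction)
    if (abs(f - or_value) / or_value < 1e-10 || (hi - lo) < 1e-14) break
    if (f < or_value) lo <- mid else hi <- mid
  }
  separation_model(mid)
}

#' Describe a published performance metric
#'
#' One reported performance figure for a score, convertible to the model's
#' separation parameter. Recognised kinds:
#'
#' * `or_per_sd` — odds ratio per 1-SD increment
#' * `hr_per_sd` — hazard ratio per 1-SD increment, treated as an OR per
#'   SD under the rare-disease approximation
#' * `auc` — area under the ROC curve, in (0, 1)
#' * `extreme_quantile_or` — odds ratio comparing top vs bottom tail
#'   groups; requires `extreme_fraction`
#' * `dr5` — detection rate at 5% false positive rate, in (0, 1)
#'
#' @param kind One of the metric kinds above.
#' @param value The reported value; positive (and in (0,1) for `auc`/`dr5`).
#' @param extreme_fraction Tail fraction for `extreme_quantile_or`
#'   (e.g. 0.20 for quintiles, 0.03 for top/bottom 3\%).
#' @return An object of class `reported_metric`.
#' @export
reported_metric <- function(kind, value, extreme_fraction = NULL) {
  kind <- match.arg(kind, metric_kinds())
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop("`value` must be a single positive number", call. = FALSE)
  }
  if (kind %in% c("auc", "dr5") && value >= 1) {
    stop(sprintf("`value` for kind '%s' must lie in (0, 1)", kind),
         call. = FALSE)
  }
  if (kind == "extreme_quantile_or") {
    if (is.null(extreme_fraction)) {
      stop("`extreme_fraction` is required for kind 'extreme_quantile_or'",
           call. = FALSE)
    }
    check_proportion(extreme_fraction, "extreme_fraction",
                     open = TRUE, upper = 0.5)
  } else {
    extreme_fraction <- NA_real_
  }
  structure(list(kind = kind, value = as.numeric(value),
                 extreme_fraction = as.numeric(extreme_fraction)),
            class = "reported_metric")
}

metric_kinds <- function() {
  c("or_per_sd", "hr_per_sd", "auc", "extreme_quantile_or", "dr5")
}

#' Separation from any reported metric
#'
#' Dispatches to the appropriate conversion. The returned model carries a
#' `"conversion"` attribute naming the conversion applied, including the
#' rare-disease approximation flag when a hazard ratio is treated as an OR.
#'
#' @param metric A `reported_metric`, or `kind`/`value`/`extreme_fraction`
#'   given directly.
#' @param kind,value,extreme_fraction Alternative direct interface; see
#'   [reported_metric()].
#' @return A `separation_model` with attribute `"conversion"`.
#' @examples
#' delta_from_metric(kind = "or_per_sd", value = 1.73)
#' @export
delta_from_metric <- function(metric = NULL, kind = NULL, value = NULL,
                              extreme_fraction = NULL) {
  if (is.null(metric)) {
    metric <- reported_metric(kind, value, extreme_fraction)
  }
  if (!inherits(metric, "reported_metric")) {
    stop("`metric` must be a `reported_metric`", call. = FALSE)
  }
  model <- switch(metric$kind,
    or_per_sd = delta_from_or_per_sd(metric$value),
    hr_per_sd = delta_from_or_per_sd(metric$value),
    auc = delta_from_auc(metric$value),
    extreme_quantile_or = delta_from_extreme_quantile_or(
      metric$value, metric$extreme_fraction),
    dr5 = delta_from_operating_point(dr = metric$value, fpr = 0.05)
  )
  attr(model, "conversion") <- switch(metric$kind,
    or_per_sd = "log odds ratio per SD",
    hr_per_sd = "log hazard ratio per SD (rare-disease approximation)",
    auc = "binormal AUC inversion",
    extreme_quantile_or = "extreme-quantile OR bisection",
    dr5 = "operating-point inversion at FPR 5%"
  )
  model
}

#' Likelihood ratio at a score value
#'
#' The ratio of the affected to unaffected score densities at z:
#' `LR(z) = dnorm(z - delta) / dnorm(z) = exp(delta * z - delta^2 / 2)`.
#' log LR is linear in z with slope delta, so on a logarithmic risk scale a
#' Gaussian equal-SD score shows a straight-line risk gradient with no
#' threshold; LR = 1 exactly at z = delta / 2.
#'
#' @param model A `separation_model` (or bare delta).
#' @param z Score value(s) in unaffected-SD units. Vectorised.
#' @return Positive likelihood ratio(s).
#' @export
likelihood_ratio <- function(model, z) {
  delta <- as_delta(model)
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("`z` must be finite numeric", call. = FALSE)
  }
  exp(delta * z - delta^2 / 2)
}

#' Risk profile across score centiles
#'
#' For each population centile of the score, gives the z value, the
#' likelihood ratio, and (when prior odds are supplied) the posterior odds
#' and absolute risk from Bayes' theorem: posterior odds = LR x prior odds,
#' risk = odds / (1 + odds). Emits both the log-LR representation (log2_lr
#' column, a straight line in z) and the arithmetic-risk representation
#' (posterior_risk column, which shows the familiar artefactual "uptick"
#' when plotted against centile on an arithmetic scale).
#'
#' @param model A `separation_model` (or bare delta).
#' @param centiles Population centiles, strictly inside (0, 1).
#' @param prior_odds Background odds of disease: an `"a:b"` string, a
#'   single odds value, or `NULL` to omit the risk columns. A proportion
#'   can be supplied via `parse_prior_odds(risk = ...)`.
#' @return A data.frame with columns `centile`, `z`, `likelihood_ratio`,
#'   `log2_lr`, and when prior odds are given `posterior_odds`,
#'   `posterior_risk`.
#' @examples
#' risk_profile(delta_from_or_per_sd(1.73), c(0.05, 0.5, 0.95), "1:9")
#' @export
risk_profile <- function(model, centiles, prior_odds = NULL) {
  delta <- as_delta(model)
  if (!is.numeric(centiles) || any(!is.finite(centiles)) ||
      any(centiles <= 0 | centiles >= 1)) {
    stop("`centiles` must lie strictly inside (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(centiles)
  lr <- likelihood_ratio(delta, z)
  out <- data.frame(centile = centiles, z = z, likelihood_ratio = lr,
                    log2_lr = log2(lr))
  if (!is.null(prior_odds)) {
    odds0 <- parse_prior_odds(prior_odds)
    post <- lr * odds0
    out$posterior_odds <- post
    out$posterior_risk <- post / (1 + post)
  }
  out
}

#' Parse prior odds
#'
#' Accepts odds written as an `"a:b"` string (e.g. `"1:9"`), a single
#' positive odds value, or a risk proportion via the `risk` argument
#' (odds = risk / (1 - risk)).
#'
#' @param x An `"a:b"` string or a single positive numeric odds.
#' @param risk Alternatively, a risk proportion in (0, 1).
#' @return A single positive numeric odds (a/b).
#' @export
parse_prior_odds <- function(x = NULL, risk = NULL) {
  if (!is.null(risk)) {
    check_proportion(risk, "risk", open = TRUE)
    return(risk / (1 - risk))
  }
  if (is.character(x) && length(x) == 1L && grepl(":", x, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(x, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || any(!is.finite(parts)) || any(parts <= 0)) {
      stop("odds string must look like 'a:b' with positive a, b",
           call. = FALSE)
    }
    return(parts[1] / parts[2])
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0) {
    return(as.numeric(x))
  }
  stop("`prior_odds` must be an 'a:b' string or a single positive number",
       call. = FALSE)
}

#' Positive predictive value at an operating point
#'
#' Bayes in odds form: posterior odds = (DR x a) : (FPR x b) for prior odds
#' a:b; PPV is the posterior odds expressed as a probability. For the
#' typical score with DR 11% at FPR 5% applied at background odds 1:9
#' (10% risk) this gives odds 0.11:0.45, a PPV of 20%.
#'
#' @param point An `operating_point`, or `dr` and `fpr` given directly.
#' @param prior_odds Background odds (see [parse_prior_odds()]).
#' @param dr,fpr Alternative scalar interface.
#' @return PPV as a proportion.
#' @examples
#' ppv_from_operating_point(dr = 0.11, fpr = 0.05, prior_odds = "1:9")
#' @export
ppv_from_operating_point <- function(point = NULL, prior_odds, dr = NULL,
                                     fpr = NULL) {
  if (!is.null(point)) {
    if (!inherits(point, "operating_point")) {
      stop("`point` must be an `operating_point`", call. = FALSE)
    }
    dr <- point$dr
    fpr <- point$fpr
  }
  check_proportion(dr, "dr", open = TRUE)
  check_proportion(fpr, "fpr", open = TRUE)
  odds0 <- parse_prior_odds(prior_odds)
  post <- (dr / fpr) * odds0
  post / (1 + post)
}
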