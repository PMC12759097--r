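# Risk stratification: partition the population by score centiles and
# compute each stratum's share of the population, of cases and of non-cases,
# plus relative and absolute risks. Centile cut-offs are taken on the
# unaffected (standard normal) distribution by default, which approximates
# population centiles for uncommon disease; a prevalence-aware mixture mode
# computes exact population-centile cut-offs numerically.

#' Share of cases between two score centiles
#'
#' The proportion of affected individuals whose score falls between the
#' `lower` and `upper` centiles of the unaffected distribution:
#' `pnorm(qnorm(upper) - delta) - pnorm(qnorm(lower) - delta)`.
#' Centiles 0 and 1 map to -Inf and +Inf.
#'
#' @param model A `separation_model` (or bare delta).
#' @param lower,upper Centile bounds, 0 <= lower < upper <= 1.
#' @return A proportion in \[0, 1\]; equals `upper - lower` when delta = 0.
#' @examples
#' # top 3% of a DR5 = 15% score holds ~10% of cases
#' m <- delta_from_operating_point(dr = 0.15, fpr = 0.05)
#' case_share_between_centiles(m, 0.97, 1)
#' @export
case_share_between_centiles <- function(model, lower, upper) {
  delta <- as_delta(model)
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L ||
      lower < 0 || upper > 1 || lower >= upper) {
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  }
  zlo <- if (lower == 0) -Inf else stats::qnorm(lower)
  zhi <- if (upper == 1) Inf else stats::qnorm(upper)
  stats::pnorm(zhi - delta) - stats::pnorm(zlo - delta)
}

# Cut-offs (z-scale) for a centile vector: on the unaffected distribution,
# or on the prevalence-weighted mixture solved numerically.
centile_cutoffs <- function(centiles, delta, prevalence = NULL,
                            quantiles = c("unaffected", "population")) {
  quantiles <- match.arg(quantiles)
  if (quantiles == "unaffected") return(stats::qnorm(centiles))
  if (is.null(prevalence)) {
    stop("`prevalence` is required for population-mixture quantiles",
         call. = FALSE)
  }
  check_proportion(prevalence, "prevalence", open = TRUE)
  mix_cdf <- function(x) {
    (1 - prevalence) * stats::pnorm(x) + prevalence * stats::pnorm(x - delta)
  }
  vapply(centiles, function(p) {
    stats::uniroot(function(x) mix_cdf(x) - p, lower = -20, upper = 20 + abs(delta),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Full risk-stratification table over a centile partition
#'
#' Partitions the population at the given centile cut-points and reports,
#' for every stratum (including the ones a selective display would omit),
#' its share of the population, of cases and of non-cases, the relative
#' risk versus the remainder of the population and versus the population
#' average, and (when a prevalence is supplied) the absolute risk obtained
#' by applying the stratum likelihood ratio to the prior odds.
#'
#' @param model A `separation_model` (or bare delta).
#' @param cutpoints Strictly increasing centiles inside (0, 1); k cut-points
#'   define k + 1 strata.
#' @param prevalence Optional average disease risk in (0, 1); enables the
#'   `absolute_risk` column (and the population-mixture quantile mode).
#' @param quantiles `"unaffected"` (default) takes centile cut-offs on the
#'   unaffected standard-normal distribution; `"population"` solves for
#'   exact mixture quantiles (requires `prevalence`). The two differ only
#'   in the third decimal for prevalence up to ~10%.
#' @return A data.frame of class `stratification_table` with columns
#'   `stratum_label`, `lower_centile`, `upper_centile`, `population_share`,
#'   `case_share`, `noncase_share`, `rr_vs_remainder`, `rr_vs_average`,
#'   `absolute_risk`. Shares each sum to 1 over the partition.
#' @examples
#' m <- delta_from_operating_point(dr = 0.15, fpr = 0.05)
#' stratification_table(m, c(0.03, 0.40, 0.60, 0.97))
#' @export
stratification_table <- function(model, cutpoints, prevalence = NULL,
                                 quantiles = c("unaffected", "population")) {
  delta <- as_delta(model)
  quantiles <- match.arg(quantiles)
  if (!is.numeric(cutpoints) || length(cutpoints) < 1L ||
      any(!is.finite(cutpoints)) || any(cutpoints <= 0 | cutpoints >= 1)) {
    stop("`cutpoints` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("`cutpoints` must be strictly increasing", call. = FALSE)
  }
  lower <- c(0, cutpoints)
  upper <- c(cutpoints, 1)
  z <- c(-Inf, centile_cutoffs(cutpoints, delta, prevalence, quantiles), Inf)
  noncase <- diff(stats::pnorm(z))
  cases <- diff(stats::pnorm(z - delta))
  pop <- if (quantiles == "population") {
    upper - lower
  } else if (!is.null(prevalence)) {
    (1 - prevalence) * noncase + prevalence * cases
  } else {
    noncase
  }
  rr_rem <- (cases / pop) / ((1 - cases) / (1 - pop))
  rr_avg <- cases / pop
  abs_risk <- if (!is.null(prevalence)) {
    odds <- (prevalence / (1 - prevalence)) * (cases / noncase)
    odds / (1 + odds)
  } else {
    rep(NA_real_, length(cases))
  }
  labels <- sprintf("%g-%g%%", 100 * lower, 100 * upper)
  out <- data.frame(
    stratum_label = labels,
    lower_centile = lower,
    upper_centile = upper,
    population_share = pop,
    case_share = cases,
    noncase_share = noncase,
    rr_vs_remainder = rr_rem,
    rr_vs_average = rr_avg,
    absolute_risk = abs_risk,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stratification_table", "data.frame")
  attr(out, "delta") <- delta
  attr(out, "prevalence") <- prevalence
  out
}

#' Write a stratification table to CSV or JSON
#'
#' @param table A `stratification_table`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_stratification_table <- function(table, path,
                                       format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Relative risk of the top score fraction versus the remainder
#'
#' For a cut-off flagging the top `fraction` of the distribution, the risk
#' ratio comparing those flagged with everyone else:
#' `(DR / fraction) / ((1 - DR) / (1 - fraction))` with
#' `DR = dr_at_fpr(delta, fraction)` (rare-disease form).
#'
#' @param model A `separation_model` (or bare delta).
#' @param fraction Top fraction flagged, in (0, 1).
#' @return A positive risk ratio; 1 when delta = 0.
#' @examples
#' relative_risk_top_fraction(delta_from_or_per_sd(1.73), 0.05)  # ~3
#' @export
relative_risk_top_fraction <- function(model, fraction) {
  delta <- as_delta(model)
  check_proportion(fraction, "fraction", open = TRUE)
  dr <- dr_at_fpr(delta, fraction)
  (dr / fraction) / ((1 - dr) / (1 - fraction))
}

#' Prevention-paradox summary for a high-risk designation
#'
#' When risk is Gaussian with a log-linear gradient, most cases arise among
#' the many at near-average risk rather than the few flagged as high risk.
#' Returns the share of cases falling outside the top `high_risk_fraction`
#' (the cases a high-risk-only strategy misses) and the ratio of the case
#' share captured to the population share flagged
#' (`dr_at_fpr(delta, f) / f`).
#'
#' @param model A `separation_model` (or bare delta).
#' @param high_risk_fraction Fraction of the population designated high
#'   risk, in (0, 0.5).
#' @return A list with `case_share_outside` and `cases_to_flags_ratio`.
#' @examples
#' # a DR5 = 11% score misses 89% of affected individuals
#' prevention_paradox_summary(separation_model(0.4183), 0.05)
#' @export
prevention_paradox_summary <- function(model, high_risk_fraction) {
  delta <- as_delta(model)
  check_proportion(high_risk_fraction, "high_risk_fraction",
                   open = TRUE, upper = 0.5)
  dr <- dr_at_fpr(delta, high_risk_fraction)
  list(case_share_outside = 1 - dr,
       cases_to_flags_ratio = dr / high_risk_fraction)
}
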