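# Individual-level simulation under the Gaussian equal-SD model, used to
# validate every closed form by Monte Carlo: case-control and population
# cohorts, empirical operating points, rank-based AUC, separation recovery,
# and the between-score instability experiment.

new_cohort <- function(score, status, config) {
  structure(list(score = as.numeric(score), status = as.integer(status),
                 config = config),
            class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d affected, %d unaffected (delta = %.3f, seed = %s)\n",
              sum(x$status == 1L), sum(x$status == 0L),
              x$config$delta, x$config$seed))
  invisible(x)
}

#' Simulate a case-control cohort
#'
#' Draws `n_unaffected` scores from the standard normal and `n_affected`
#' from normal(delta, 1): the equal-SD Gaussian structure polygenic risk
#' scores display in affected and unaffected groups. Reproducible given
#' `seed`; the RNG algorithm is recorded in the cohort's config.
#'
#' @param n_affected,n_unaffected Group sizes (positive integers).
#' @param delta Mean separation in SD units (or a `separation_model`).
#' @param seed Integer seed; recorded in all outputs.
#' @return A `prs_cohort`: list with `score`, `status` (1 = affected) and
#'   `config`.
#' @examples
#' co <- simulate_case_control(1000, 1000, 0.4183, seed = 1)
#' empirical_operating_point(co, 0.05)
#' @export
simulate_case_control <- function(n_affected, n_unaffected, delta, seed) {
  delta <- as_delta(delta)
  stopifnot(n_affected >= 1, n_unaffected >= 1)
  score <- withr::with_seed(seed, {
    c(stats::rnorm(n_unaffected), stats::rnorm(n_affected, mean = delta))
  })
  status <- c(rep(0L, n_unaffected), rep(1L, n_affected))
  new_cohort(score, status, list(
    mode = "case_control", n_affected = as.integer(n_affected),
    n_unaffected = as.integer(n_unaffected), delta = delta,
    seed = as.integer(seed), rng = "Mersenne-Twister"))
}

#' Simulate a population cohort
#'
#' Affected status is Bernoulli(`prevalence`); scores are drawn
#' conditionally on status as in [simulate_case_control()].
#'
#' @param n Population size.
#' @param prevalence Disease risk in (0, 1).
#' @param delta Mean separation in SD units (or a `separation_model`).
#' @param seed Integer seed.
#' @return A `prs_cohort`.
#' @export
simulate_population <- function(n, prevalence, delta, seed) {
  delta <- as_delta(delta)
  stopifnot(n >= 1)
  check_proportion(prevalence, "prevalence", open = TRUE)
  out <- withr::with_seed(seed, {
    status <- stats::rbinom(n, 1L, prevalence)
    score <- stats::rnorm(n, mean = delta * status)
    list(score = score, status = status)
  })
  new_cohort(out$score, out$status, list(
    mode = "population", n = as.integer(n), prevalence = prevalence,
    delta = delta, seed = as.integer(seed), rng = "Mersenne-Twister"))
}

check_two_classes <- function(cohort) {
  if (!inherits(cohort, "prs_cohort")) {
    stop("expected a `prs_cohort`", call. = FALSE)
  }
  if (!any(cohort$status == 1L) || !any(cohort$status == 0L)) {
    stop("cohort must contain both affected and unaffected individuals",
         call. = FALSE)
  }
  invisible(cohort)
}

#' Empirical operating point of a cohort
#'
#' The threshold is the nearest-rank empirical (1 - fpr) quantile of the
#' unaffected scores (the finite-sample analogue of a cut-off at, say, the
#' 95th percentile of the unaffected distribution); the detection rate is
#' the fraction of affected scores above it.
#'
#' @param cohort A `prs_cohort` containing both classes.
#' @param fpr Target false positive rate in (0, 1).
#' @return An `operating_point` with an attached `"threshold"` attribute.
#' @export
empirical_operating_point <- function(cohort, fpr) {
  check_two_classes(cohort)
  check_proportion(fpr, "fpr", open = TRUE)
  unaff <- sort(cohort$score[cohort$status == 0L])
  k <- ceiling((1 - fpr) * length(unaff))
  threshold <- unaff[max(1L, min(k, length(unaff)))]
  aff <- cohort$score[cohort$status == 1L]
  dr <- mean(aff > threshold)
  # clamp away from {0,1} so tiny cohorts still yield a valid point
  eps <- 1 / (2 * length(aff))
  point <- operating_point(fpr, min(max(dr, eps), 1 - eps))
  attr(point, "threshold") <- threshold
  attr(point, "dr_raw") <- dr
  point
}

#' Empirical AUC by the rank statistic
#'
#' The Mann-Whitney estimator: the proportion of (affected, unaffected)
#' pairs in which the affected score is higher, ties counted half.
#' Computed from midranks in O(n log n).
#'
#' @param cohort A `prs_cohort` containing both classes.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(cohort) {
  check_two_classes(cohort)
  r <- rank(cohort$score)  # midranks handle ties
  na <- as.numeric(sum(cohort$status == 1L))
  nu <- as.numeric(sum(cohort$status == 0L))
  (sum(r[cohort$status == 1L]) - na * (na + 1) / 2) / (na * nu)
}

#' Empirical separation of a cohort
#'
#' Recovers delta as the difference in group means divided by the pooled
#' within-group standard deviation.
#'
#' @param cohort A `prs_cohort` with at least two members per class.
#' @return A `separation_model` holding the estimate.
#' @export
empirical_delta <- function(cohort) {
  check_two_classes(cohort)
  a <- cohort$score[cohort$status == 1L]
  u <- cohort$score[cohort$status == 0L]
  if (length(a) < 2L || length(u) < 2L) {
    stop("need at least two members per class", call. = FALSE)
  }
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                   (length(u) - 1) * stats::var(u)) /
    (length(a) + length(u) - 2)
  if (pooled_var <= 0) stop("degenerate (zero) pooled variance", call. = FALSE)
  separation_model((mean(a) - mean(u)) / sqrt(pooled_var))
}

#' Between-score instability experiment
#'
#' Different polygenic scores for the same disease can place the same
#' individual at wildly different centiles. This experiment draws, for each
#' individual, a pair of scores with identical marginal separation `delta`
#' and cross-correlation `score_correlation`, via a shared-component
#' construction: each score is `sqrt(r) * common + sqrt(1 - r) * own` noise
#' (plus `delta` when affected), which preserves each score's marginal
#' distribution. It then reports the distribution of per-individual centile
#' discordance. At correlation 1 the discordance is zero; it grows as the
#' correlation falls.
#'
#' @param delta Marginal separation of both scores, SD units.
#' @param score_correlation Correlation between the two scores, in \[0, 1\].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param prevalence Disease risk used for affected status (default 0.10).
#' @return A list with `centile_pairs` (data.frame: `centile_1`,
#'   `centile_2`, `discordance` in centile points, `status`),
#'   `fraction_discordant_gt` (named vector over thresholds 10..90 centile
#'   points) and `config`.
#' @examples
#' res <- score_instability_experiment(0.4, 0.2, 2000, seed = 7)
#' res$fraction_discordant_gt
#' @export
score_instability_experiment <- function(delta, score_correlation, n, seed,
                                         prevalence = 0.10) {
  delta <- as_delta(delta)
  if (!is.numeric(score_correlation) || length(score_correlation) != 1L ||
      score_correlation < 0 || score_correlation > 1) {
    stop("`score_correlation` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n >= 1)
  check_proportion(prevalence, "prevalence", open = TRUE)
  r <- score_correlation
  sim <- withr::with_seed(seed, {
    status <- stats::rbinom(n, 1L, prevalence)
    common <- stats::rnorm(n)
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    shift <- delta * status
    s1 <- sqrt(r) * common + sqrt(1 - r) * e1 + shift
    s2 <- sqrt(r) * common + sqrt(1 - r) * e2 + shift
    list(status = status, s1 = s1, s2 = s2)
  })
  c1 <- stats::pnorm(sim$s1)
  c2 <- stats::pnorm(sim$s2)
  disc <- 100 * abs(c1 - c2)
  ks <- seq(10, 90, by = 10)
  frac_gt <- vapply(ks, function(k) mean(disc > k), numeric(1))
  names(frac_gt) <- paste0("gt_", ks)
  list(
    centile_pairs = data.frame(centile_1 = c1, centile_2 = c2,
                               discordance = disc, status = sim$status),
    fraction_discordant_gt = frac_gt,
    config = list(delta = delta, score_correlation = r, n = as.integer(n),
                  seed = as.integer(seed), prevalence = prevalence,
                  rng = "Mersenne-Twister")
  )
}

#' Write / read a cohort as CSV with a JSON config sidecar
#'
#' The cohort is written as a two-column CSV (`score`, `status`); the
#' simulation config (including the seed and RNG name) goes to
#' `<path>.json`.
#'
#' @param cohort A `prs_cohort`.
#' @param path CSV file path.
#' @return `path` (write) or a `prs_cohort` (read).
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "prs_cohort")) {
    stop("expected a `prs_cohort`", call. = FALSE)
  }
  utils::write.csv(data.frame(score = cohort$score, status = cohort$status),
                   path, row.names = FALSE)
  jsonlite::write_json(cohort$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  config <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list()
  }
  new_cohort(df$score, df$status, config)
}
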