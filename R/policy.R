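# Screening-policy arithmetic: events prevented by an intervention offered
# to screen positives, the incremental yield of adding a score to a risk
# model, and the number needed to genotype (NNG) per additional event
# prevented. Pure arithmetic on supplied inputs; no demographic modelling.

#' Events prevented by treating screen positives
#'
#' Under full adherence, offering an intervention with relative risk
#' reduction `rrr` to everyone testing positive prevents
#' `n * incidence * dr * rrr` events: only the detected cases can have
#' their events averted.
#'
#' @param n Number of people screened.
#' @param incidence Event risk per person over the policy horizon, in (0, 1).
#' @param dr Detection rate of the screening rule, in \[0, 1\].
#' @param rrr Relative risk reduction of the intervention, in \[0, 1\]
#'   (e.g. 0.20 for statins against cardiovascular events).
#' @return Expected number of events prevented (real-valued).
#' @examples
#' events_prevented(100000, 0.0798, 0.61, 0.20)  # ~974
#' @export
events_prevented <- function(n, incidence, dr, rrr) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("`n` must be a single positive count", call. = FALSE)
  }
  check_proportion(incidence, "incidence", open = TRUE)
  if (!is.numeric(dr) || length(dr) != 1L || dr < 0 || dr > 1) {
    stop("`dr` must be a proportion in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rrr) || length(rrr) != 1L || rrr < 0 || rrr > 1) {
    stop("`rrr` must be a proportion in [0, 1]", call. = FALSE)
  }
  n * incidence * dr * rrr
}

#' Number needed to genotype from event counts
#'
#' Given the events prevented per `n` people screened under a baseline
#' (non-genetic) model and under the model augmented with a polygenic
#' score, the number needed to genotype to prevent one additional event is
#' `n / (events_augmented - events_baseline)`, infinite when the score
#' adds nothing.
#'
#' @param n Number of people screened (all of whom must be genotyped for
#'   the augmented model).
#' @param events_baseline,events_augmented Events prevented under each model.
#' @return An object of class `policy_outcome`: a list with
#'   `events_prevented_baseline`, `events_prevented_augmented`,
#'   `events_gained`, `nng` (unrounded) and `nng_rounded` (nearest integer;
#'   `Inf` when the gain is not positive).
#' @examples
#' nng_from_events(100000, 957, 974)  # gain 17, NNG 5882
#' @export
nng_from_events <- function(n, events_baseline, events_augmented) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("`n` must be a single positive count", call. = FALSE)
  }
  gained <- events_augmented - events_baseline
  nng <- if (gained > 0) n / gained else Inf
  structure(list(
    n_screened = n,
    events_prevented_baseline = events_baseline,
    events_prevented_augmented = events_augmented,
    events_gained = gained,
    nng = nng,
    nng_rounded = if (is.finite(nng)) round(nng) else Inf
  ), class = "policy_outcome")
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat(sprintf("Events prevented: %.1f (baseline) -> %.1f (with score); gain %.1f\n",
              x$events_prevented_baseline, x$events_prevented_augmented,
              x$events_gained))
  if (is.finite(x$nng)) {
    cat(sprintf("Number needed to genotype per additional event prevented: %d (%.2f)\n",
                as.integer(x$nng_rounded), x$nng))
  } else {
    cat("Number needed to genotype: infinite (no additional events prevented)\n")
  }
  invisible(x)
}

#' Number needed to genotype from two operating points
#'
#' Composes [events_prevented()] at the baseline and augmented detection
#' rates and passes the results to [nng_from_events()]. False positive
#' rates, when supplied, change the size of the treated population, not the
#' events prevented; treated counts are attached for transparency.
#'
#' @param n Number of people screened.
#' @param incidence Event risk over the horizon, in (0, 1).
#' @param rrr Relative risk reduction of the intervention, in \[0, 1\].
#' @param dr_baseline,dr_augmented Detection rates without / with the score.
#' @param fpr_baseline,fpr_augmented Optional false positive rates; used
#'   only for the attached `n_treated_*` fields.
#' @return A `policy_outcome` (see [nng_from_events()]), with
#'   `n_treated_baseline` / `n_treated_augmented` when FPRs are given.
#' @examples
#' nng_from_operating_points(100000, 0.0798, 0.20, 0.60, 0.61)
#' @export
nng_from_operating_points <- function(n, incidence, rrr,
                                      dr_baseline, dr_augmented,
                                      fpr_baseline = NULL,
                                      fpr_augmented = NULL) {
  eb <- events_prevented(n, incidence, dr_baseline, rrr)
  ea <- events_prevented(n, incidence, dr_augmented, rrr)
  out <- nng_from_events(n, eb, ea)
  treated <- function(dr, fpr) {
    if (is.null(fpr)) return(NA_real_)
    n * (incidence * dr + (1 - incidence) * fpr)
  }
  out$n_treated_baseline <- treated(dr_baseline, fpr_baseline)
  out$n_treated_augmented <- treated(dr_augmented, fpr_augmented)
  out
}

#' Compare screening strategies by testing burden per outcome
#'
#' Pure arithmetic over supplied per-strategy counts: adds
#' `tests_per_case_detected` and `tests_per_death_averted` columns and
#' orders strategies by tests per death averted (fewest first; ties keep
#' their input order).
#'
#' @param rows A data.frame with columns `label`, `n_tested`,
#'   `cases_detected`, `deaths_averted` (non-negative counts).
#' @return The ranked data.frame with the derived columns.
#' @examples
#' strategy_comparison(data.frame(
#'   label = "PRS-gated", n_tested = 4369703,
#'   cases_detected = 1968, deaths_averted = 102))
#' @export
strategy_comparison <- function(rows) {
  need <- c("label", "n_tested", "cases_detected", "deaths_averted")
  if (!is.data.frame(rows) || !all(need %in% names(rows))) {
    stop("`rows` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  counts <- rows[c("n_tested", "cases_detected", "deaths_averted")]
  if (any(vapply(counts, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  rows$tests_per_case_detected <-
    ifelse(rows$cases_detected > 0, rows$n_tested / rows$cases_detected, Inf)
  rows$tests_per_death_averted <-
    ifelse(rows$deaths_averted > 0, rows$n_tested / rows$deaths_averted, Inf)
  rows <- rows[order(rows$tests_per_death_averted, method = "radix"), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}
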