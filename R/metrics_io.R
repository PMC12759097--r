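# Reading tables of published performance metrics, normalising every record
# to the common separation scale (delta) and its equivalent metrics, and
# summarising DR5 by disease.

#' Read a table of published performance metrics
#'
#' Expects a delimited file (UTF-8, header required) with columns
#' `score_id`, `disease`, `metric_kind`, `value`, and optionally
#' `extreme_fraction`, `source`, `notes`. `metric_kind` must be one of the
#' kinds in [reported_metric()]. Malformed rows are collected into an error
#' report attached as attribute `"errors"` (and returned in `$errors` when
#' `simplify = FALSE`), never silently dropped.
#'
#' @param path Path to the file.
#' @param sep Field separator, `","` by default.
#' @param simplify If `TRUE` (default) return the valid records data.frame
#'   with the error report as an attribute; otherwise return
#'   `list(records, errors)`.
#' @return A data.frame of validated metric records (possibly zero rows).
#' @examples
#' path <- system.file("extdata", "reported_metrics.csv", package = "prscreen")
#' read_metric_table(path)
#' @export
read_metric_table <- function(path, sep = ",", simplify = TRUE) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fill = TRUE,
                           colClasses = "character", encoding = "UTF-8")
  need <- c("score_id", "disease", "metric_kind", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("extreme_fraction", "source", "notes")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  errors <- data.frame(row = integer(), message = character(),
                       stringsAsFactors = FALSE)
  keep <- logical(nrow(raw))
  value <- numeric(nrow(raw))
  frac <- rep(NA_real_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    msg <- NULL
    v <- suppressWarnings(as.numeric(raw$value[i]))
    f <- suppressWarnings(as.numeric(raw$extreme_fraction[i]))
    if (!nzchar(raw$score_id[i]) || is.na(raw$score_id[i])) {
      msg <- "empty score_id"
    } else if (!nzchar(raw$disease[i]) || is.na(raw$disease[i])) {
      msg <- "empty disease"
    } else if (!raw$metric_kind[i] %in% metric_kinds()) {
      msg <- paste0("unknown metric_kind '", raw$metric_kind[i], "'")
    } else if (is.na(v)) {
      msg <- "non-numeric value"
    } else {
      msg <- tryCatch({
        reported_metric(raw$metric_kind[i], v,
                        if (!is.na(f)) f else NULL)
        NULL
      }, error = function(e) conditionMessage(e))
    }
    if (is.null(msg)) {
      keep[i] <- TRUE
      value[i] <- v
      frac[i] <- f
    } else {
      errors <- rbind(errors, data.frame(row = i, message = msg,
                                         stringsAsFactors = FALSE))
    }
  }
  records <- data.frame(
    score_id = raw$score_id[keep],
    disease = raw$disease[keep],
    metric_kind = raw$metric_kind[keep],
    value = value[keep],
    extreme_fraction = frac[keep],
    source = raw$source[keep],
    notes = raw$notes[keep],
    stringsAsFactors = FALSE
  )
  if (simplify) {
    attr(records, "errors") <- errors
    records
  } else {
    list(records = records, errors = errors)
  }
}

#' Normalise metric records to the common separation scale
#'
#' Converts every record's reported metric to delta via
#' [delta_from_metric()] and attaches the four equivalent summaries:
#' `delta`, `dr5`, `auc` and `or_per_sd`. Idempotent: normalising an
#' already-normalised table recomputes identical columns.
#'
#' @param records A data.frame as returned by [read_metric_table()].
#' @return The input with `delta`, `dr5`, `auc`, `or_per_sd` columns.
#' @examples
#' recs <- data.frame(score_id = "GPS2018", disease = "CAD",
#'                    metric_kind = "or_per_sd", value = 1.49,
#'                    extreme_fraction = NA)
#' normalize_records(recs)
#' @export
normalize_records <- function(records) {
  need <- c("score_id", "disease", "metric_kind", "value")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"extreme_fraction" %in% names(records)) {
    records$extreme_fraction <- NA_real_
  }
  n <- nrow(records)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    f <- records$extreme_fraction[i]
    model <- tryCatch(
      delta_from_metric(kind = records$metric_kind[i],
                        value = records$value[i],
                        extreme_fraction = if (!is.na(f)) f else NULL),
      error = function(e) {
        stop(sprintf("record %d (%s): %s", i, records$score_id[i],
                     conditionMessage(e)), call. = FALSE)
      })
    delta[i] <- model$delta
  }
  records$delta <- delta
  records$dr5 <- stats::pnorm(delta - stats::qnorm(0.95))
  records$auc <- stats::pnorm(delta / sqrt(2))
  records$or_per_sd <- exp(delta)
  records
}

#' Summarise normalised records by disease
#'
#' Median and interquartile range of DR5 per disease. Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7); the
#' median of an even count is the midpoint mean.
#'
#' @param normalized A data.frame from [normalize_records()].
#' @return A data.frame with `disease`, `n_scores`, `median_dr5`,
#'   `iqr_lo_dr5`, `iqr_hi_dr5`, one row per disease in alphabetical order.
#' @export
summarize_by_disease <- function(normalized) {
  if (!is.data.frame(normalized) || nrow(normalized) == 0L ||
      !all(c("disease", "dr5") %in% names(normalized))) {
    stop("`normalized` must be a non-empty normalised record table",
         call. = FALSE)
  }
  split_dr5 <- split(normalized$dr5, normalized$disease)
  out <- data.frame(
    disease = names(split_dr5),
    n_scores = vapply(split_dr5, length, integer(1)),
    median_dr5 = vapply(split_dr5, stats::median, numeric(1)),
    iqr_lo_dr5 = vapply(split_dr5, stats::quantile, numeric(1),
                        probs = 0.25, names = FALSE, type = 7),
    iqr_hi_dr5 = vapply(split_dr5, stats::quantile, numeric(1),
                        probs = 0.75, names = FALSE, type = 7),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$disease, method = "radix"), , drop = FALSE]
}
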