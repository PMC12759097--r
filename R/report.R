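# Reporting conventions: computations keep full-precision proportions;
# rounding (half-to-even, as base round() does) happens only at the
# reporting boundary — integer percent for detection rates, 2 dp for AUC,
# 1 dp for delta, 1 dp for OR/SD, nearest integer for extreme-quantile ORs.

#' Format a proportion as a percentage string
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param digits Decimal places of the percentage (default 0).
#' @return Character vector like `"11%"`. Rounds half to even.
#' @export
format_percent <- function(p, digits = 0) {
  paste0(formatC(round(100 * p, digits), format = "f", digits = digits), "%")
}

trim_num <- function(x, digits) {
  formatC(round(x, digits), format = "fg", digits = 15)
}

#' Equivalent performance metrics for a model
#'
#' Tabulates the interchangeable summaries of one separation model: delta,
#' DR5, AUC, OR per SD and the extreme-quantile OR, each with its
#' full-precision value and its conventionally rounded display (integer
#' percent for DR5, 2 dp for AUC, 1 dp for delta and OR/SD, nearest
#' integer for the extreme-quantile OR).
#'
#' @param model A `separation_model` (or bare delta).
#' @param extreme_fraction Tail fraction for the extreme-quantile OR row
#'   (default 0.20, i.e. quintiles).
#' @return A data.frame with columns `metric`, `value`, `display`.
#' @examples
#' metric_equivalents(delta_from_or_per_sd(1.73))
#' @export
metric_equivalents <- function(model, extreme_fraction = 0.20) {
  delta <- as_delta(model)
  dr5 <- dr_at_fpr(delta, 0.05)
  auc <- auc_from_delta(delta)
  orsd <- or_per_sd_from_delta(delta)
  eqor <- extreme_quantile_or(delta, extreme_fraction)
  data.frame(
    metric = c("delta_sd", "dr5", "auc", "or_per_sd",
               sprintf("extreme_quantile_or_%g", extreme_fraction)),
    value = c(delta, dr5, auc, orsd, eqor),
    display = c(trim_num(delta, 1), format_percent(dr5), trim_num(auc, 2),
                trim_num(orsd, 1), trim_num(eqor, 0)),
    stringsAsFactors = FALSE
  )
}

#' Render a result as text, CSV or JSON
#'
#' A thin serialisation layer used by the command-line interface: tables
#' render as CSV/JSON/aligned text; list-like outcomes as JSON or
#' key-value text. Full-precision values are always included alongside any
#' rounded display columns.
#'
#' @param results A data.frame, `separation_model`, `policy_outcome` or
#'   plain list.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @return A single character string.
#' @export
render_report <- function(results, format = c("text", "csv", "json")) {
  format <- match.arg(format)
  UseMethod("render_report")
}

#' @export
render_report.separation_model <- function(results,
                                           format = c("text", "csv", "json")) {
  render_report(metric_equivalents(results), format)
}

#' @export
render_report.data.frame <- function(results,
                                     format = c("text", "csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  switch(format,
    csv = {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    json = jsonlite::toJSON(df, digits = NA, na = "null", pretty = TRUE),
    text = paste0(paste(utils::capture.output(print(df, row.names = FALSE)),
                        collapse = "\n"), "\n")
  )
}

#' @export
render_report.policy_outcome <- function(results,
                                         format = c("text", "csv", "json")) {
  format <- match.arg(format)
  render_report.default(unclass(results), format)
}

#' @export
render_report.default <- function(results,
                                  format = c("text", "csv", "json")) {
  format <- match.arg(format)
  x <- lapply(results, function(v) if (is.numeric(v) && any(is.infinite(v)))
    ifelse(is.infinite(v), "Inf", as.character(v)) else v)
  switch(format,
    json = jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                            na = "null", pretty = TRUE),
    csv = {
      df <- as.data.frame(x, stringsAsFactors = FALSE)
      render_report.data.frame(df, "csv")
    },
    text = paste0(paste(sprintf("%s: %s", names(x),
                                vapply(x, function(v)
                                  paste(format(v), collapse = ", "),
                                  character(1))),
                        collapse = "\n"), "\n")
  )
}
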