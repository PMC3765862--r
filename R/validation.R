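# Backcast validation: run the model over a historical window and compare
# simulated with observed headcounts. Per-year fit is the relative error
# e = |simulated - historic| / historic. Three aggregate summaries are
# computed side by side, because "mean squared error" is used loosely in this
# literature: the literal mean of squared relative errors, its square root
# (RMS), and the plain mean relative error. On a well-fitting backcast the
# last two agree at the usual 3-decimal presentation while the literal MSE is
# orders of magnitude smaller; the report prints all three so the choice of
# summary is always visible.

#' Per-year relative error
#'
#' `|simulated - historic| / historic`; unit-free, zero iff exact match.
#'
#' @param historic Observed headcount(s), positive. Vectorised.
#' @param simulated Simulated headcount(s).
#' @return Relative error(s).
#' @examples
#' relative_error(248.61, 250.39) # 0.00716
#' @export
relative_error <- function(historic, simulated) {
  if (any(historic <= 0)) {
    stop("historic values must be positive", call. = FALSE)
  }
  abs(simulated - historic) / historic
}

#' Aggregate a set of validation records
#'
#' @param records Data frame with columns `year`, `historic`, `simulated`
#'   (and optionally a precomputed `relative_error`, which is recomputed
#'   anyway), e.g. from [compare_series()].
#' @return An object of class `validation_report` with the records and the
#'   aggregates `mse_literal` (mean of squared relative errors), `rmse`
#'   (its square root), `mean_relative_error` and `n`.
#' @export
aggregate_errors <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("year", "historic", "simulated") %in% names(records))) {
    stop("records needs columns year, historic, simulated", call. = FALSE)
  }
  records$relative_error <- relative_error(records$historic, records$simulated)
  e <- records$relative_error
  mse <- mean(e^2)
  structure(
    list(records = records,
         mse_literal = mse,
         rmse = sqrt(mse),
         mean_relative_error = mean(e),
         n = nrow(records)),
    class = "validation_report"
  )
}

#' Compare a simulated series with a historic series
#'
#' @param historic,simulated Numeric vectors named by calendar year (units
#'   must match between the two; relative errors are unit-free).
#' @param years Years to compare at (default: every year present in
#'   `historic`). Both series must cover every requested year; missing years
#'   are reported explicitly.
#' @return A `validation_report`; see [aggregate_errors()].
#' @export
compare_series <- function(historic, simulated,
                           years = as.numeric(names(historic))) {
  if (is.null(names(historic)) || is.null(names(simulated))) {
    stop("historic and simulated series must be named by year", call. = FALSE)
  }
  key <- as.character(years)
  gaps_h <- years[!key %in% names(historic)]
  gaps_s <- years[!key %in% names(simulated)]
  if (length(gaps_h) || length(gaps_s)) {
    msg <- c(
      if (length(gaps_h)) sprintf("historic series missing: %s",
                                  paste(gaps_h, collapse = ", ")),
      if (length(gaps_s)) sprintf("simulated series missing: %s",
                                  paste(gaps_s, collapse = ", "))
    )
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  aggregate_errors(data.frame(
    year = years,
    historic = unname(historic[key]),
    simulated = unname(simulated[key])
  ))
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  # layout mirrors the historic / simulated / relative-error comparison table
  m <- rbind(
    `Historic data` = x$records$historic,
    `Simulation data` = x$records$simulated,
    `Relative error` = round(x$records$relative_error, digits)
  )
  colnames(m) <- x$records$year
  cat("<validation_report>", x$n, "year(s)\n")
  print(m)
  cat(sprintf("mean relative error %.6f | rmse %.6f | literal MSE (mean e^2) %.3g\n",
              x$mean_relative_error, x$rmse, x$mse_literal))
  invisible(x)
}

#' Tidy view of a validation report
#'
#' One row per compared year plus aggregate rows, ready to write as CSV.
#'
#' @param x A `validation_report`.
#' @param row.names,optional,... Unused, present for the generic.
#' @return Data frame with columns `year`, `historic`, `simulated`,
#'   `relative_error`, `statistic`, `value`.
#' @export
as.data.frame.validation_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  per_year <- cbind(x$records, statistic = NA_character_, value = NA_real_)
  agg <- data.frame(
    year = NA_real_, historic = NA_real_, simulated = NA_real_,
    relative_error = NA_real_,
    statistic = c("mean_relative_error", "rmse", "mse_literal", "n"),
    value = c(x$mean_relative_error, x$rmse, x$mse_literal, x$n),
    stringsAsFactors = FALSE
  )
  rbind(per_year, agg)
}

#' Does a backcast pass the validation threshold?
#'
#' The customary reasonableness bound for this kind of model validation is an
#' error summary below 10%; it is applied here to the root-mean-square
#' relative error.
#'
#' @param report A `validation_report`.
#' @param threshold Upper bound (default 0.1).
#' @param statistic Which aggregate to test (default `"rmse"`).
#' @return Logical.
#' @export
validation_passes <- function(report, threshold = 0.1, statistic = "rmse") {
  stopifnot(inherits(report, "validation_report"))
  report[[match.arg(statistic, c("rmse", "mse_literal", "mean_relative_error"))]] < threshold
}
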