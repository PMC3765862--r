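# Uncertainty projection: perturb the enrolment quota and the speciality
# choice fractions, re-run the forecast, and compare sufficiency levels.

#' Define a quota / speciality-choice scenario
#'
#' @param name Scenario label (used in reports and for deterministic
#'   tie-breaking).
#' @param quota_multiplier Factor applied to the enrolment quota from
#'   `start_year` onward (e.g. 1.15 for +15%).
#' @param choice_delta Change applied to one speciality's selection fraction,
#'   with the remaining specialities rescaled proportionally so the fractions
#'   still sum to 1. Interpreted per `delta_mode`.
#' @param speciality Which selection fraction `choice_delta` perturbs
#'   (default `"obgyn"`).
#' @param delta_mode `"points"` (default): `choice_delta` is in percentage
#'   points, so +1 turns 0.04 into 0.05. `"relative"`: a percentage of the
#'   current fraction, so +1 turns 0.04 into 0.0404.
#' @param start_year First year the perturbation applies; `NULL` (default)
#'   means from the simulation base year.
#' @return An object of class `scenario`.
#' @examples
#' scenario("quota +15%", quota_multiplier = 1.15)
#' scenario("OB/GYN choice +1pp", choice_delta = 1)
#' @export
scenario <- function(name, quota_multiplier = 1, choice_delta = 0,
                     speciality = "obgyn",
                     delta_mode = c("points", "relative"),
                     start_year = NULL) {
  delta_mode <- match.arg(delta_mode)
  if (quota_multiplier < 0) {
    stop("quota_multiplier must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name, quota_multiplier = quota_multiplier,
         choice_delta = choice_delta, speciality = speciality,
         delta_mode = delta_mode, start_year = start_year),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: quota x%.3f, %s choice %+g%s from %s\n",
              x$name, x$quota_multiplier, x$speciality, x$choice_delta,
              if (x$delta_mode == "points") " pp" else "% (relative)",
              if (is.null(x$start_year)) "base year" else x$start_year))
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Returns a new [parameter_set()]; the original is untouched. The quota is
#' scaled from the scenario's start year onward (cohorts already admitted are
#' never changed retroactively, so quota perturbations reach the workforce
#' only after the school delay). The perturbed selection fraction is shifted
#' and the remaining fractions rescaled by the complementary mass so the set
#' still sums to 1.
#'
#' @param params A [parameter_set()].
#' @param scn A [scenario()].
#' @param base_year Fallback start year when the scenario has none (usually
#'   `clock$base_year`). Required if `scn$start_year` is `NULL`.
#' @return The perturbed `parameter_set`.
#' @examples
#' p <- parameter_set(c(`2007` = 7625, `2008` = 7625), 0.9,
#'                    c(obgyn = 0.04, other = 0.96), 0.02,
#'                    c(obgyn = 0, other = 0))
#' apply_scenario(p, scenario("up", quota_multiplier = 1.15), base_year = 2008)
#' @export
apply_scenario <- function(params, scn, base_year = NULL) {
  stopifnot(inherits(params, "parameter_set"), inherits(scn, "scenario"))
  start <- scn$start_year
  if (is.null(start)) start <- base_year
  if (is.null(start)) {
    stop("scenario has no start_year and no base_year was given", call. = FALSE)
  }

  quota <- params$quota_series
  yrs <- as.numeric(names(quota))
  quota[yrs >= start] <- quota[yrs >= start] * scn$quota_multiplier

  fractions <- params$selection_fractions
  if (scn$choice_delta != 0) {
    sp <- scn$speciality
    if (!sp %in% names(fractions)) {
      stop(sprintf("scenario '%s': no speciality '%s' in the parameter set",
                   scn$name, sp), call. = FALSE)
    }
    old <- fractions[[sp]]
    new <- if (scn$delta_mode == "points") old + scn$choice_delta / 100
           else old * (1 + scn$choice_delta / 100)
    if (new < 0 || new > 1) {
      stop(sprintf("scenario '%s': perturbed fraction %.4f outside [0, 1]",
                   scn$name, new), call. = FALSE)
    }
    others <- setdiff(names(fractions), sp)
    rest_old <- sum(fractions[others])
    if (rest_old > 0) {
      fractions[others] <- fractions[others] * (1 - new) / rest_old
    } else if (abs(new - 1) > 1e-9) {
      stop(sprintf("scenario '%s': cannot renormalize, no mass outside '%s'",
                   scn$name, sp), call. = FALSE)
    }
    fractions[[sp]] <- new
  }

  parameter_set(
    quota_series = quota,
    pass_rate = params$pass_rate,
    selection_fractions = fractions,
    retirement_rate = params$retirement_rate,
    initial_stocks = params$initial_stocks,
    school_duration = params$school_duration,
    training_duration = params$training_duration,
    exam_policy = params$exam_policy
  )
}

#' Run a sensitivity sweep over scenarios
#'
#' Every scenario is run on the same clock and judged against the same
#' sufficiency criterion; a baseline (unperturbed) run is always computed for
#' the impact metric, which is the change in horizon-year sufficiency level
#' relative to baseline.
#'
#' @param base_params A [parameter_set()].
#' @param scenarios List of [scenario()] objects.
#' @param clock A [sim_clock()].
#' @param criterion A [sufficiency_criterion()] for the reported group.
#' @param group `"total"` for all clinical physicians, or a speciality name
#'   (e.g. `"obgyn"`) to judge that speciality's practice headcount.
#' @return A list of class `sensitivity_results`, one element per scenario,
#'   each with `name`, `series` (a [sufficiency_series()]), `crossing_year`
#'   and `impact`. The baseline series is attached as attribute `baseline`.
#' @export
run_sensitivity <- function(base_params, scenarios, clock, criterion,
                            group = "total") {
  if (!length(scenarios)) stop("no scenarios given", call. = FALSE)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario")))

  series_for <- function(params) {
    fc <- forecast_headcounts(params, clock)
    hc <- if (identical(group, "total")) fc$total else fc$speciality[[group]]
    if (is.null(hc)) {
      stop(sprintf("unknown group '%s'", group), call. = FALSE)
    }
    sufficiency_series(hc, criterion)
  }

  baseline <- series_for(base_params)
  base_final <- baseline$level[baseline$year == clock$horizon_year]

  results <- lapply(scenarios, function(scn) {
    params <- apply_scenario(base_params, scn, base_year = clock$base_year)
    ser <- tryCatch(series_for(params), error = function(e) {
      stop(sprintf("scenario '%s': %s", scn$name, conditionMessage(e)),
           call. = FALSE)
    })
    final <- ser$level[ser$year == clock$horizon_year]
    list(name = scn$name, series = ser,
         crossing_year = crossing_year(ser),
         impact = final - base_final)
  })
  names(results) <- vapply(scenarios, `[[`, character(1), "name")
  structure(results, baseline = baseline, group = group,
            class = "sensitivity_results")
}

#' @export
print.sensitivity_results <- function(x, ...) {
  cat(sprintf("<sensitivity_results> group '%s', %d scenario(s)\n",
              attr(x, "group"), length(x)))
  for (r in x) {
    cat(sprintf("  %-28s crossing %s, horizon impact %+.4f\n", r$name,
                ifelse(is.na(r$crossing_year), "never", r$crossing_year),
                r$impact))
  }
  invisible(x)
}

#' Rank scenario impacts
#'
#' Orders scenarios by the absolute value of their horizon-year impact on the
#' sufficiency level, largest first; ties are broken alphabetically by
#' scenario name so the ranking is deterministic.
#'
#' @param results A `sensitivity_results` object from [run_sensitivity()].
#' @return Data frame with columns `scenario`, `impact`, `crossing_year`,
#'   `rank`.
#' @export
rank_impacts <- function(results) {
  stopifnot(inherits(results, "sensitivity_results"))
  df <- data.frame(
    scenario = vapply(results, `[[`, character(1), "name"),
    impact = vapply(results, `[[`, numeric(1), "impact"),
    crossing_year = vapply(results, `[[`, numeric(1), "crossing_year"),
    stringsAsFactors = FALSE
  )
  ord <- order(-abs(df$impact), df$scenario)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
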