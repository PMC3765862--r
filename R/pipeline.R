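# The Japanese physician career path wired onto the stock-and-flow engine:
# enrolment -> medical school (6-year conveyor) -> national examination gate
# -> postgraduate clinical training (2-year conveyor) -> speciality choice
# -> per-speciality clinical practice stocks -> retirement.
#
# Key assumptions carried by the wiring: graduates equal the enrolment quota
# six years earlier (domestic students only, no attrition during school);
# retirement / death / speciality-movement is one constant per-capita hazard
# per practice stock; speciality choice happens once, at training completion.

#' Exogenous parameters of the career-path model
#'
#' @param quota_series Named numeric vector (names = calendar years) or a
#'   data frame with columns `year` and `quota`: the medical school enrolment
#'   quota, in persons/year. Must cover
#'   `[base_year - school_duration - training_duration, horizon_year]` for the
#'   clock the model is run under.
#' @param pass_rate National-examination pass rate, a fraction in \[0, 1\].
#' @param selection_fractions Named numeric vector of per-speciality selection
#'   fractions at training completion; must sum to 1 (tolerance 1e-9).
#' @param retirement_rate Constant per-capita hazard (fraction/year), either a
#'   single number applied to every practice stock or a named vector by
#'   speciality. Covers death and movement out of the speciality as well.
#' @param initial_stocks Named numeric vector of base-year clinical-practice
#'   headcounts by speciality (same names as `selection_fractions`). Trainees
#'   are not included here; they are back-filled into the delay chains from
#'   the quota series.
#' @param school_duration Medical school length in years (default 6).
#' @param training_duration Postgraduate clinical training length in years
#'   (default 2).
#' @param exam_policy `"one_shot"` (failures leave the system, the default) or
#'   `"retake"` (failures re-sit with the same pass rate in later years, via a
#'   retake pool stock).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(quota_series, pass_rate, selection_fractions,
                          retirement_rate, initial_stocks,
                          school_duration = 6, training_duration = 2,
                          exam_policy = c("one_shot", "retake")) {
  exam_policy <- match.arg(exam_policy)
  if (is.data.frame(quota_series)) {
    if (!all(c("year", "quota") %in% names(quota_series))) {
      stop("quota data frame needs columns 'year' and 'quota'", call. = FALSE)
    }
    quota_series <- stats::setNames(quota_series$quota,
                                    as.character(quota_series$year))
  }
  if (is.null(names(quota_series)) || anyNA(suppressWarnings(
        as.numeric(names(quota_series))))) {
    stop("quota_series must be named by calendar year", call. = FALSE)
  }
  if (any(quota_series < 0)) stop("quota must be non-negative", call. = FALSE)
  if (!is.numeric(pass_rate) || pass_rate < 0 || pass_rate > 1) {
    stop("pass_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(selection_fractions))) {
    stop("selection_fractions must be named by speciality", call. = FALSE)
  }
  if (any(selection_fractions < 0) || any(selection_fractions > 1)) {
    stop("selection fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(selection_fractions) - 1) > 1e-9) {
    stop(sprintf("selection_fractions must sum to 1 (got %.12f)",
                 sum(selection_fractions)), call. = FALSE)
  }
  specs <- names(selection_fractions)
  if (length(retirement_rate) == 1L && is.null(names(retirement_rate))) {
    retirement_rate <- stats::setNames(rep(retirement_rate, length(specs)), specs)
  }
  if (!setequal(names(retirement_rate), specs)) {
    stop("retirement_rate must be scalar or named by the same specialities",
         call. = FALSE)
  }
  if (any(retirement_rate < 0) || any(retirement_rate > 1)) {
    stop("retirement rates must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(initial_stocks), specs)) {
    stop("initial_stocks must be named by the same specialities as selection_fractions",
         call. = FALSE)
  }
  if (any(initial_stocks < 0)) {
    stop("initial stocks must be non-negative", call. = FALSE)
  }
  if (school_duration < 1 || training_duration < 0) {
    stop("invalid stage durations", call. = FALSE)
  }
  structure(
    list(quota_series = quota_series, pass_rate = pass_rate,
         selection_fractions = selection_fractions,
         retirement_rate = retirement_rate[specs],
         initial_stocks = initial_stocks[specs],
         school_duration = school_duration,
         training_duration = training_duration,
         exam_policy = exam_policy),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> quota years %s-%s; pass rate %.3f; school %dy + training %dy\n",
              min(as.numeric(names(x$quota_series))),
              max(as.numeric(names(x$quota_series))),
              x$pass_rate, x$school_duration, x$training_duration))
  cat("  specialities:", paste(sprintf("%s (f=%.3f, r=%.4f)",
      names(x$selection_fractions), x$selection_fractions,
      x$retirement_rate), collapse = ", "), "\n")
  invisible(x)
}

#' Enrolment quota for a given admission year
#'
#' @param params A [parameter_set()].
#' @param year Admission year(s).
#' @return The quota (persons/year) for each requested year.
#' @export
quota_at <- function(params, year) {
  key <- as.character(year)
  missing <- key[!key %in% names(params$quota_series)]
  if (length(missing)) {
    stop(sprintf("quota series does not cover year(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unname(params$quota_series[key])
}

#' Graduating cohort size
#'
#' The number of graduates equals the enrolment quota `school_duration` years
#' earlier: domestic students only, no attrition during school.
#'
#' @param year Graduation year.
#' @param params A [parameter_set()].
#' @return Headcount graduating in `year`.
#' @examples
#' p <- parameter_set(c(`2002` = 7625), 0.9, c(all = 1), 0.02, c(all = 0))
#' graduates(2008, p) # 7625
#' @export
graduates <- function(year, params) {
  quota_at(params, year - params$school_duration)
}

#' National-examination passes
#'
#' @param graduates Size of the sitting cohort.
#' @param pass_rate Per-attempt pass rate in \[0, 1\].
#' @param attempts Number of attempts granted (default 1, the one-shot
#'   policy). With retakes the cumulative pass count follows the geometric
#'   series `graduates * (1 - (1 - pass_rate)^attempts)`.
#' @return Cumulative number of passes.
#' @examples
#' exam_passes(8000, 0.9)              # 7200
#' exam_passes(1000, 0.9, attempts = 3) # 999
#' @export
exam_passes <- function(graduates, pass_rate, attempts = 1L) {
  if (pass_rate < 0 || pass_rate > 1) {
    stop("pass_rate must lie in [0, 1]", call. = FALSE)
  }
  if (graduates < 0) stop("graduates must be non-negative", call. = FALSE)
  if (attempts < 1) stop("attempts must be at least 1", call. = FALSE)
  graduates * (1 - (1 - pass_rate)^attempts)
}

#' Split new clinicians across specialities
#'
#' Headcounts stay real-valued; the per-speciality inflows sum exactly to the
#' input.
#'
#' @param new_clinicians Headcount completing training this year.
#' @param selection_fractions Named fractions summing to 1 (tolerance 1e-9).
#' @return Named numeric vector of per-speciality inflows.
#' @examples
#' allocate_speciality(1000, c(obgyn = 0.04, other = 0.96))
#' @export
allocate_speciality <- function(new_clinicians, selection_fractions) {
  if (new_clinicians < 0) {
    stop("new_clinicians must be non-negative", call. = FALSE)
  }
  if (abs(sum(selection_fractions) - 1) > 1e-9) {
    stop("selection fractions must sum to 1", call. = FALSE)
  }
  new_clinicians * selection_fractions
}

#' Retirement outflow from a practice stock
#'
#' A constant per-capita hazard covering retirement, death and movement out
#' of the speciality.
#'
#' @param stock Current headcount.
#' @param rate Hazard, fraction/year in \[0, 1\].
#' @return Outflow in persons/year.
#' @examples
#' retirement_outflow(200000, 0.02) # 4000
#' @export
retirement_outflow <- function(stock, rate) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (stock < 0) stop("stock must be non-negative", call. = FALSE)
  stock * rate
}

#' Wire the six-sector career-path model
#'
#' Builds the full stock-and-flow model: quota-driven enrolment into a
#' `school_duration`-year conveyor, the national-examination gate, a
#' `training_duration`-year training conveyor, speciality allocation into one
#' clinical-practice stock per speciality, and constant-hazard retirement
#' outflows. Both views the analysis needs — the all-clinicians total and a
#' single speciality such as OB/GYN — come from the same wired model: the
#' aggregate `total_clinical` counts the training conveyor plus all practice
#' stocks (licensed trainees are practising physicians in the census this
#' model is anchored to), while each speciality's headcount is its practice
#' stock alone, since speciality choice happens at training completion.
#'
#' Delay chains are back-filled at the base year from the historical quota
#' series (school: admissions of the preceding `school_duration` years;
#' training: exam passes of the preceding `training_duration` graduation
#' cohorts), so no spurious ramp-up occurs in the first years. The quota
#' series must therefore reach back
#' `school_duration + training_duration` years before the base year.
#'
#' @param params A [parameter_set()].
#' @param clock A [sim_clock()] (annual steps, `dt = 1`).
#' @return A [stock_flow_model()] ready for [run_simulation()].
#' @export
build_career_model <- function(params, clock) {
  stopifnot(inherits(params, "parameter_set"), inherits(clock, "sim_clock"))
  if (clock$dt != 1) {
    stop("the career-path model uses annual conveyors; dt must be 1",
         call. = FALSE)
  }
  base <- clock$base_year
  sd_ <- params$school_duration
  td <- params$training_duration
  need <- seq(base - sd_ - td, clock$horizon_year)
  quota_at(params, need) # errors naming any missing years

  # conveyors: cohorts[1] entered at flow-year `base`, cohorts[k] at base-k+1
  school <- delay_chain("school", sd_, cohorts = quota_at(params, base - seq_len(sd_) + 1))
  training_init <- vapply(seq_len(td), function(k) {
    exam_passes(quota_at(params, base - k + 1 - sd_), params$pass_rate)
  }, numeric(1))
  training <- delay_chain("training", td, cohorts = training_init)

  specs <- names(params$selection_fractions)
  stocks <- lapply(specs, function(s) {
    stock(paste0("practice_", s), params$initial_stocks[[s]],
          speciality = s, stage = "clinical_practice")
  })

  flows <- list(
    flow("enrolment", "external", "school",
         function(year, state, p) quota_at(p, year)),
    flow("exam_pass", "school", "training",
         function(year, state, p) state$exits[["school"]] * p$pass_rate)
  )
  if (params$exam_policy == "retake") {
    stocks <- c(stocks, list(stock("retake_pool", 0, stage = "examination")))
    flows <- c(flows, list(
      flow("exam_fail_to_pool", "school", "retake_pool",
           function(year, state, p) state$exits[["school"]] * (1 - p$pass_rate)),
      flow("retake_pass", "retake_pool", "training",
           function(year, state, p) state$stocks[["retake_pool"]] * p$pass_rate)
    ))
  }
  for (s in specs) {
    fr <- params$selection_fractions[[s]]
    rr <- params$retirement_rate[[s]]
    stock_name <- paste0("practice_", s)
    flows <- c(flows, list(
      flow(paste0("choice_", s), "training", stock_name,
           local({fr_ <- fr
                  function(year, state, p) state$exits[["training"]] * fr_})),
      flow(paste0("retirement_", s), stock_name, "external",
           local({rr_ <- rr; sn <- stock_name
                  function(year, state, p) retirement_outflow(state$stocks[[sn]], rr_)}))
    ))
  }

  practice_names <- paste0("practice_", specs)
  aggregates <- list(
    total_clinical = function(stocks, chains) {
      sum(stocks[practice_names]) + chain_occupancy(chains[["training"]])
    }
  )

  stock_flow_model(stocks = stocks, chains = list(school, training),
                   flows = flows, aggregates = aggregates)
}

#' Forecast headcount series from the career model
#'
#' Convenience wrapper: builds the model, runs it, and returns the
#' all-clinicians total and per-speciality practice series.
#'
#' @param params A [parameter_set()].
#' @param clock A [sim_clock()].
#' @return A list with `trajectory` (the full [run_simulation()] result),
#'   `total` (named numeric, total clinical physicians by year) and
#'   `speciality` (named list of per-speciality series).
#' @export
forecast_headcounts <- function(params, clock) {
  traj <- run_simulation(build_career_model(params, clock), clock, params)
  specs <- names(params$selection_fractions)
  list(
    trajectory = traj,
    total = trajectory_series(traj, "total_clinical"),
    speciality = stats::setNames(
      lapply(specs, function(s) trajectory_series(traj, paste0("practice_", s))),
      specs
    )
  )
}
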