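# Synthetic input generators. Every file the pipeline consumes — workforce
# census, enrolment quota series, required-number survey, population
# projection — can be produced here from a small config, so the whole
# analysis is testable without any government data download. All generators
# are pure functions of (config, seed).

#' Configuration for the synthetic input generators
#'
#' Defaults describe a workforce of the same order as Japan's 2008 clinical
#' physician census, with a declining population and a near-balanced need.
#'
#' @param seed Integer seed fixing every stochastic draw.
#' @param base_year,horizon_year Simulated window (defaults 2008-2030).
#' @param base_total Total clinical physicians at the base year.
#' @param obgyn_share Fraction of the base-year workforce in OB/GYN.
#' @param quota_level Enrolment quota at the base year (persons/year).
#' @param quota_trend Per-year multiplicative trend of the quota (1 = flat).
#' @param pass_rate National-examination pass rate.
#' @param retirement_rate Constant per-capita exit hazard (fraction/year).
#' @param hospital_share Fraction of physicians working in hospitals (the
#'   remainder work in clinics); drives the corrective coefficient.
#' @param population_start Population at the base year.
#' @param population_annual_change Per-year fractional population change
#'   (negative for decline).
#' @param required_ratio Required-to-supply ratio at the base year; 1 means
#'   the surveyed need exactly matches base-year supply.
#' @param corrective_coefficient Override for the corrective coefficient;
#'   `NULL` (default) derives it from the census hospital/clinic split.
#' @param school_duration,training_duration Stage lengths in years.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             base_year = 2008, horizon_year = 2030,
                             base_total = 271897, obgyn_share = 0.038,
                             quota_level = 8000, quota_trend = 1.0,
                             pass_rate = 0.9, retirement_rate = 0.013,
                             hospital_share = 0.615,
                             population_start = 127.69e6,
                             population_annual_change = -0.0042,
                             required_ratio = 1.0,
                             corrective_coefficient = NULL,
                             school_duration = 6, training_duration = 2) {
  stopifnot(base_year < horizon_year, base_total > 0,
            obgyn_share >= 0, obgyn_share <= 1,
            quota_level > 0, quota_trend > 0,
            pass_rate >= 0, pass_rate <= 1,
            retirement_rate >= 0, retirement_rate <= 1,
            hospital_share > 0, hospital_share <= 1,
            population_start > 0, required_ratio > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic workforce census
#'
#' Emulates a national physician census: one base-year row per (age band,
#' sex, speciality, workplace) cell. Cell weights follow a piecewise-linear
#' age pyramid peaking at ages 35-54 with seeded noise of up to ±5%, then the
#' cells are rescaled so the totals are exact: `base_total` overall and
#' `base_total * obgyn_share` for OB/GYN, with the workplace split matching
#' `hospital_share`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `year`, `age_band`, `sex`, `speciality`,
#'   `workplace`, `headcount` (real-valued).
#' @export
generate_workforce_census <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  age_bands <- c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")
  pyramid <- c(0.8, 1.0, 1.0, 0.7, 0.4, 0.15)
  sexes <- c(male = 0.8, female = 0.2)
  specs <- c(obgyn = config$obgyn_share, other = 1 - config$obgyn_share)
  workplaces <- c(hospital = config$hospital_share,
                  clinic = 1 - config$hospital_share)

  grid <- expand.grid(age_band = age_bands, sex = names(sexes),
                      speciality = names(specs), workplace = names(workplaces),
                      stringsAsFactors = FALSE)
  w <- pyramid[match(grid$age_band, age_bands)] *
    sexes[grid$sex] * workplaces[grid$workplace]
  noise <- with_seed(config$seed, stats::runif(nrow(grid), 0.95, 1.05))
  w <- w * noise

  # noise reshapes the age-sex pyramid only: each speciality-by-workplace
  # subtotal is rescaled to its exact target so the census totals and the
  # hospital/clinic split are exact
  headcount <- numeric(nrow(grid))
  for (s in names(specs)) {
    for (wp in names(workplaces)) {
      idx <- grid$speciality == s & grid$workplace == wp
      target <- config$base_total * specs[[s]] * workplaces[[wp]]
      headcount[idx] <- if (sum(w[idx]) > 0) w[idx] / sum(w[idx]) * target else 0
    }
  }
  out <- cbind(year = config$base_year, grid, headcount = headcount)
  rownames(out) <- NULL
  out[out$headcount > 0, , drop = FALSE]
}

#' Generate a synthetic enrolment quota series
#'
#' Geometric trend around the base-year level, covering the full span the
#' career model needs (back to
#' `base_year - school_duration - training_duration`).
#'
#' @param config A [synthetic_config()].
#' @return Named numeric vector of quotas by admission year.
#' @export
generate_quota_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- seq(config$base_year - config$school_duration - config$training_duration,
               config$horizon_year)
  stats::setNames(config$quota_level * config$quota_trend^(years - config$base_year),
                  years)
}

#' Generate a synthetic required-number survey
#'
#' Emulates the hospital-administrator survey behind the sufficiency
#' criterion: per speciality, the required hospital headcount is the census
#' hospital supply times `required_ratio`; the corrective coefficient is the
#' census ratio of all physicians to hospital physicians (so that, with
#' `required_ratio = 1`, base-year sufficiency is exactly 1).
#'
#' @param config A [synthetic_config()].
#' @param census A census table from [generate_workforce_census()].
#' @return List with `table` (data frame: `speciality`,
#'   `required_hospital_number`) and `corrective_coefficient`.
#' @export
generate_required_survey <- function(config, census) {
  if (!is.data.frame(census) || nrow(census) == 0) {
    stop("census must be a non-empty data frame", call. = FALSE)
  }
  hosp <- census[census$workplace == "hospital", ]
  supply_hospital <- tapply(hosp$headcount, hosp$speciality, sum)
  coef <- config$corrective_coefficient
  if (is.null(coef)) {
    coef <- sum(census$headcount) / sum(hosp$headcount)
  }
  list(
    table = data.frame(
      speciality = names(supply_hospital),
      required_hospital_number = as.numeric(supply_hospital) * config$required_ratio,
      stringsAsFactors = FALSE
    ),
    corrective_coefficient = unname(coef)
  )
}

#' Generate a synthetic population projection
#'
#' Deterministic geometric series
#' `population_start * (1 + population_annual_change)^(year - base_year)`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `year`, `population`.
#' @export
generate_population_projection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- seq(config$base_year, config$horizon_year)
  data.frame(
    year = years,
    population = config$population_start *
      (1 + config$population_annual_change)^(years - config$base_year)
  )
}

#' Parameter set implied by a synthetic config
#'
#' Builds the [parameter_set()] that generates the synthetic world: quota from
#' [generate_quota_series()], speciality split from `obgyn_share`, delay
#' chains back-filled from the quota, and base-year practice stocks equal to
#' `base_total` minus the trainees resident in the training conveyor.
#'
#' @param config A [synthetic_config()].
#' @return A [parameter_set()].
#' @export
synthetic_parameters <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  quota <- generate_quota_series(config)
  sd_ <- config$school_duration
  trainees <- config$pass_rate * sum(
    quota[as.character(config$base_year - sd_ - seq_len(config$training_duration) + 1)]
  )
  obgyn <- config$base_total * config$obgyn_share
  other <- config$base_total - trainees - obgyn
  if (other < 0) {
    stop("base_total too small to hold the trainee conveyor", call. = FALSE)
  }
  parameter_set(
    quota_series = quota,
    pass_rate = config$pass_rate,
    selection_fractions = c(obgyn = config$obgyn_share,
                            other = 1 - config$obgyn_share),
    retirement_rate = config$retirement_rate,
    initial_stocks = c(obgyn = obgyn, other = other),
    school_duration = sd_,
    training_duration = config$training_duration
  )
}

#' Calibrate model parameters against a historic series
#'
#' Fits free parameters of the career-path model by minimising the
#' root-mean-square relative error ([compare_series()]) between the backcast
#' total-clinical series and a historic series. The optimiser is a bounded
#' deterministic search (golden-section via [stats::optimize()] for one free
#' parameter, L-BFGS-B from the box midpoint otherwise), so repeated runs give
#' identical fits.
#'
#' @param historic Named numeric vector of observed headcounts by year, in
#'   the same units (persons) as the model.
#' @param params Template [parameter_set()]; free parameters are overwritten.
#' @param clock [sim_clock()] covering all historic years.
#' @param free Character vector of free parameters, a subset of
#'   `"retirement_rate"` (one hazard shared by every speciality),
#'   `"pass_rate"`, and `"initial_scale"` (a common factor on the base-year
#'   practice stocks).
#' @param lower,upper Optional named bounds; defaults are
#'   retirement_rate \[0.001, 0.1\], pass_rate \[0.5, 1\],
#'   initial_scale \[0.8, 1.2\].
#' @return An object of class `calibration_fit`: `estimates` (named numeric),
#'   `params` (the fitted parameter set), `rmse`, and `report` (the
#'   [compare_series()] validation report at the optimum).
#' @export
calibrate <- function(historic, params, clock, free = "retirement_rate",
                      lower = NULL, upper = NULL) {
  stopifnot(inherits(params, "parameter_set"), inherits(clock, "sim_clock"))
  if (length(historic) < 3) {
    stop("calibration needs a historic series of at least 3 years", call. = FALSE)
  }
  allowed <- c("retirement_rate", "pass_rate", "initial_scale")
  if (!length(free) || !all(free %in% allowed)) {
    stop(sprintf("free parameters must be among: %s",
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  default_lower <- c(retirement_rate = 0.001, pass_rate = 0.5, initial_scale = 0.8)
  default_upper <- c(retirement_rate = 0.1, pass_rate = 1.0, initial_scale = 1.2)
  lo <- default_lower[free]; hi <- default_upper[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  with_params <- function(theta) {
    p <- params
    if ("retirement_rate" %in% free) {
      p$retirement_rate[] <- theta[["retirement_rate"]]
    }
    if ("pass_rate" %in% free) p$pass_rate <- theta[["pass_rate"]]
    if ("initial_scale" %in% free) {
      p$initial_stocks <- p$initial_stocks * theta[["initial_scale"]]
    }
    p
  }
  objective <- function(theta) {
    names(theta) <- free
    fc <- forecast_headcounts(with_params(theta), clock)
    compare_series(historic, fc$total)$rmse
  }

  if (length(free) == 1L) {
    opt <- stats::optimize(function(x) objective(x), lower = lo, upper = hi,
                           tol = 1e-10)
    estimates <- stats::setNames(opt$minimum, free)
    rmse <- opt$objective
  } else {
    start <- (lo + hi) / 2
    opt <- stats::optim(start, objective, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(factr = 1e4))
    if (opt$convergence != 0) {
      stop(sprintf(
        "calibration did not converge (code %d: %s); best rmse so far %.6g at %s",
        opt$convergence, opt$message, opt$value,
        paste(sprintf("%s=%.6g", free, opt$par), collapse = ", ")),
        call. = FALSE)
    }
    estimates <- stats::setNames(opt$par, free)
    rmse <- opt$value
  }

  fitted <- with_params(estimates)
  fc <- forecast_headcounts(fitted, clock)
  structure(
    list(estimates = estimates, params = fitted, rmse = rmse,
         report = compare_series(historic, fc$total)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>",
      paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
            collapse = ", "),
      sprintf("| rmse %.6g\n", x$rmse))
  invisible(x)
}
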