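# Supply-versus-need evaluation. The required number of physicians comes from
# a hospital-administrator survey and covers hospitals only; a corrective
# coefficient scales it up for the missing clinic workforce. The sufficiency
# level is forecast supply over that corrected requirement; >= 1 is read as
# sufficient, < 1 as shortage, and a speciality is maldistributed when exactly
# one of {all clinicians, the speciality} is sufficient.

#' Sufficiency criterion
#'
#' @param required_hospital_number Required physician headcount claimed by
#'   hospital administrators (hospitals only; positive).
#' @param corrective_coefficient Dimensionless positive factor correcting the
#'   hospitals-only requirement for missing clinic data. Under the scale-up
#'   convention used here the effective requirement is
#'   `required_hospital_number * corrective_coefficient`, so the coefficient
#'   is > 1 when clinics add to the need (the census ratio of all physicians
#'   to hospital physicians).
#' @param time_varying If `FALSE` (default) the criterion is a constant over
#'   the horizon; `TRUE` marks requirement series supplied per year.
#' @return An object of class `sufficiency_criterion`.
#' @export
sufficiency_criterion <- function(required_hospital_number,
                                  corrective_coefficient,
                                  time_varying = FALSE) {
  if (any(required_hospital_number <= 0) || any(corrective_coefficient <= 0)) {
    stop("required number and corrective coefficient must be positive",
         call. = FALSE)
  }
  if (!time_varying && length(required_hospital_number) != 1L) {
    stop("a constant criterion takes a single required number", call. = FALSE)
  }
  structure(
    list(required_hospital_number = required_hospital_number,
         corrective_coefficient = corrective_coefficient,
         time_varying = time_varying),
    class = "sufficiency_criterion"
  )
}

#' @export
print.sufficiency_criterion <- function(x, ...) {
  cat(sprintf("<sufficiency_criterion> required (hospitals) %s x coefficient %.4g = effective %.6g\n",
              paste(format(x$required_hospital_number, big.mark = " "),
                    collapse = ", "),
              x$corrective_coefficient[1],
              x$required_hospital_number[1] * x$corrective_coefficient[1]))
  invisible(x)
}

#' Sufficiency level
#'
#' Ratio of forecast supply to the corrected requirement:
#' `forecast / (required_hospital_number * corrective_coefficient)`.
#' Homogeneous of degree 1 in the forecast, so under a constant criterion the
#' percentage growth of the level equals the percentage growth of the
#' headcount.
#'
#' @param forecast Forecast physician headcount(s), non-negative. Vectorised.
#' @param criterion A [sufficiency_criterion()].
#' @return Dimensionless level(s).
#' @examples
#' sufficiency_level(90, sufficiency_criterion(120, 1)) # 0.75
#' @export
sufficiency_level <- function(forecast, criterion) {
  stopifnot(inherits(criterion, "sufficiency_criterion"))
  if (any(forecast < 0)) stop("forecast must be non-negative", call. = FALSE)
  denom <- criterion$required_hospital_number * criterion$corrective_coefficient
  if (any(denom <= 0)) stop("criterion denominator must be positive", call. = FALSE)
  forecast / denom
}

#' Classify a sufficiency level
#'
#' Levels of at least 1 are sufficient (closed boundary); below 1 is a
#' shortage.
#'
#' @param level Sufficiency level(s), positive. Vectorised.
#' @return Character vector, `"sufficient"` or `"shortage"`.
#' @export
classify_sufficiency <- function(level) {
  if (any(level <= 0)) stop("level must be positive", call. = FALSE)
  ifelse(level >= 1, "sufficient", "shortage")
}

#' Speciality-level maldistribution flag
#'
#' TRUE when exactly one of the two groups is at a sufficient level — either
#' the speciality is short while physicians overall are sufficient, or vice
#' versa.
#'
#' @param level_all Sufficiency level of all clinical physicians. Vectorised.
#' @param level_speciality Sufficiency level of the speciality.
#' @return Logical.
#' @examples
#' maldistribution_flag(1.02, 0.85) # TRUE
#' @export
maldistribution_flag <- function(level_all, level_speciality) {
  if (any(level_all <= 0) || any(level_speciality <= 0)) {
    stop("levels must be positive", call. = FALSE)
  }
  xor(level_all >= 1, level_speciality >= 1)
}

#' Physicians per 1 000 persons
#'
#' @param headcount Physician headcount(s), non-negative.
#' @param population Population (persons, positive). Vectorised.
#' @return Physicians per 1 000 persons.
#' @examples
#' per_capita(220, 100000) # 2.2
#' @export
per_capita <- function(headcount, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(headcount < 0)) stop("headcount must be non-negative", call. = FALSE)
  1000 * headcount / population
}

#' Sufficiency level series for a forecast
#'
#' @param forecast Named numeric vector of forecast headcounts (names are
#'   calendar years), e.g. from [forecast_headcounts()].
#' @param criterion A [sufficiency_criterion()].
#' @return An object of class `sufficiency_series`: a data frame with columns
#'   `year`, `level` and `classification`.
#' @export
sufficiency_series <- function(forecast, criterion) {
  if (is.null(names(forecast))) {
    stop("forecast must be named by calendar year", call. = FALSE)
  }
  lev <- sufficiency_level(unname(forecast), criterion)
  out <- data.frame(year = as.numeric(names(forecast)), level = lev,
                    classification = classify_sufficiency(lev),
                    stringsAsFactors = FALSE)
  class(out) <- c("sufficiency_series", "data.frame")
  out
}

#' First year a series reaches a threshold
#'
#' @param series A `sufficiency_series`, or a numeric vector named by year
#'   (e.g. a per-capita series).
#' @param threshold Value to reach (default 1, the sufficiency boundary;
#'   closed: the crossing year itself satisfies `value >= threshold`).
#' @return The first calendar year whose value is at least `threshold`, or
#'   `NA` if the threshold is never reached within the series.
#' @examples
#' crossing_year(c(`2025` = 0.99, `2026` = 1.01)) # 2026
#' @export
crossing_year <- function(series, threshold = 1) {
  if (inherits(series, "sufficiency_series")) {
    years <- series$year
    values <- series$level
  } else {
    if (is.null(names(series))) {
      stop("series must be a sufficiency_series or a year-named vector",
           call. = FALSE)
    }
    years <- as.numeric(names(series))
    values <- unname(series)
  }
  if (!length(values)) stop("series is empty", call. = FALSE)
  ord <- order(years)
  years <- years[ord]; values <- values[ord]
  hit <- which(values >= threshold)
  if (!length(hit)) NA_real_ else years[hit[1]]
}

#' @export
plot.sufficiency_series <- function(x, ...) {
  graphics::plot(x$year, x$level, type = "l", xlab = "year",
                 ylab = "sufficiency level", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
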