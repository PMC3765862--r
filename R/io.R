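# Plain-text interchange: CSV readers/writers for the pipeline's inputs and
# outputs and a YAML round-trip for parameter sets.

#' Read an enrolment quota series from CSV
#'
#' Expects columns `year` and `quota`.
#'
#' @param path File path.
#' @return Named numeric vector of quotas by admission year.
#' @export
read_quota_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "quota") %in% names(df))) {
    stop("quota CSV needs columns 'year' and 'quota'", call. = FALSE)
  }
  stats::setNames(df$quota, df$year)
}

#' Read a workforce census from CSV
#'
#' Expects the tidy census layout of [generate_workforce_census()]:
#' `year`, `age_band`, `sex`, `speciality`, `workplace`, `headcount`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "age_band", "sex", "speciality", "workplace", "headcount")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("census CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a population projection from CSV
#'
#' Expects columns `year` and `population`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "population") %in% names(df))) {
    stop("population CSV needs columns 'year' and 'population'", call. = FALSE)
  }
  df
}

#' Write a trajectory as tidy CSV
#'
#' Columns: `year`, `stock`, `speciality`, `headcount`.
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a sufficiency evaluation as CSV
#'
#' One row per (year, group) with the level, its classification and the
#' speciality-maldistribution flag (computed against the `"total"` group).
#'
#' @param series_list Named list of [sufficiency_series()] objects; must
#'   contain an element `"total"`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_sufficiency_csv <- function(series_list, path) {
  if (!"total" %in% names(series_list)) {
    stop("series_list needs a 'total' element for the maldistribution flag",
         call. = FALSE)
  }
  total <- series_list$total
  rows <- lapply(names(series_list), function(g) {
    s <- series_list[[g]]
    lev_all <- total$level[match(s$year, total$year)]
    data.frame(year = s$year, group = g, level = s$level,
               classification = s$classification,
               maldistribution = maldistribution_flag(lev_all, s$level),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a validation report as CSV
#'
#' Mirrors the historic / simulated / relative-error comparison layout plus
#' the aggregate statistics; see [as.data.frame.validation_report()].
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter set from YAML
#'
#' The YAML mirrors [parameter_set()]: mappings `quota_series` (year: quota),
#' `selection_fractions`, `retirement_rate` (scalar or mapping),
#' `initial_stocks`, and scalars `pass_rate`, `school_duration`,
#' `training_duration`, `exam_policy`.
#'
#' @param path File path.
#' @return A [parameter_set()].
#' @export
read_parameter_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("quota_series", "pass_rate", "selection_fractions",
            "retirement_rate", "initial_stocks")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop(sprintf("parameter YAML missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  as_named <- function(x) stats::setNames(as.numeric(unlist(x)), names(unlist(x)))
  rr <- y$retirement_rate
  parameter_set(
    quota_series = as_named(y$quota_series),
    pass_rate = y$pass_rate,
    selection_fractions = as_named(y$selection_fractions),
    retirement_rate = if (is.list(rr)) as_named(rr) else rr,
    initial_stocks = as_named(y$initial_stocks),
    school_duration = y$school_duration %||% 6,
    training_duration = y$training_duration %||% 2,
    exam_policy = y$exam_policy %||% "one_shot"
  )
}

#' Write a parameter set to YAML
#'
#' @param params A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_yaml <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  yaml::write_yaml(list(
    quota_series = as.list(stats::setNames(unname(params$quota_series),
                                           names(params$quota_series))),
    pass_rate = params$pass_rate,
    selection_fractions = as.list(params$selection_fractions),
    retirement_rate = as.list(params$retirement_rate),
    initial_stocks = as.list(params$initial_stocks),
    school_duration = params$school_duration,
    training_duration = params$training_duration,
    exam_policy = params$exam_policy
  ), path)
  invisible(path)
}

#' Emit the full synthetic input bundle
#'
#' Writes everything the pipeline consumes into a directory: census CSV,
#' quota CSV, population CSV, required-number CSV and a parameter YAML, all
#' generated from one [synthetic_config()].
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_input_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  census <- generate_workforce_census(config)
  survey <- generate_required_survey(config, census)
  quota <- generate_quota_series(config)
  paths <- c(
    census = file.path(dir, "census.csv"),
    quota = file.path(dir, "quota.csv"),
    population = file.path(dir, "population.csv"),
    required = file.path(dir, "required.csv"),
    parameters = file.path(dir, "parameters.yml")
  )
  utils::write.csv(census, paths[["census"]], row.names = FALSE)
  utils::write.csv(data.frame(year = as.numeric(names(quota)),
                              quota = unname(quota)),
                   paths[["quota"]], row.names = FALSE)
  utils::write.csv(generate_population_projection(config),
                   paths[["population"]], row.names = FALSE)
  req <- survey$table
  req$corrective_coefficient <- survey$corrective_coefficient
  utils::write.csv(req, paths[["required"]], row.names = FALSE)
  write_parameter_yaml(synthetic_parameters(config), paths[["parameters"]])
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
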