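test_that("the synthetic census hits its totals exactly and deterministically", {
  cfg <- synthetic_config(seed = 42, base_total = 271897, obgyn_share = 0.038)
  census <- generate_workforce_census(cfg)
  expect_equal(sum(census$headcount), 271897, tolerance = 1e-9)
  expect_equal(sum(census$headcount[census$speciality == "obgyn"]),
               271897 * 0.038, tolerance = 1e-9)
  expect_identical(census, generate_workforce_census(cfg))
  different <- generate_workforce_census(synthetic_config(seed = 43))
  expect_false(identical(census$headcount, different$headcount))
})

test_that("a zero OB/GYN share yields no OB/GYN rows", {
  census <- generate_workforce_census(synthetic_config(obgyn_share = 0))
  expect_false("obgyn" %in% census$speciality[census$headcount > 0])
  expect_equal(sum(census$headcount), 271897, tolerance = 1e-9)
})

test_that("the census generator does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(generate_workforce_census(synthetic_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("the required survey makes base-year sufficiency 1/required_ratio", {
  for (ratio in c(1.0, 1.1, 0.8)) {
    cfg <- synthetic_config(seed = 5, required_ratio = ratio)
    census <- generate_workforce_census(cfg)
    survey <- generate_required_survey(cfg, census)
    req_total <- sum(survey$table$required_hospital_number)
    crit <- sufficiency_criterion(req_total, survey$corrective_coefficient)
    expect_equal(sufficiency_level(sum(census$headcount), crit), 1 / ratio,
                 tolerance = 1e-9)
  }
})

test_that("the corrective coefficient is the all-to-hospital supply ratio", {
  cfg <- synthetic_config(seed = 5, hospital_share = 0.6)
  survey <- generate_required_survey(cfg, generate_workforce_census(cfg))
  expect_equal(survey$corrective_coefficient, 1 / 0.6, tolerance = 1e-9)
  expect_error(generate_required_survey(cfg, data.frame()), "non-empty")
})

test_that("the population projection follows the geometric closed form", {
  flat <- generate_population_projection(
    synthetic_config(population_annual_change = 0))
  expect_equal(flat$population, rep(flat$population[1], nrow(flat)))
  cfg <- synthetic_config(population_start = 123e6,
                          population_annual_change = -0.0025)
  pop <- generate_population_projection(cfg)
  expect_equal(pop$population[pop$year == 2030], 123e6 * 0.9975^22,
               tolerance = 1e-12)
  expect_equal(pop$population[pop$year == 2030] / 1e6, 116.41,
               tolerance = 1e-4)
})

test_that("the fixture population reproduces the printed per-capita anchor", {
  fx <- study_fixture()
  pop <- fixture_population()
  expect_equal(per_capita(fx$forecast_total_2030,
                          pop$population[pop$year == 2030]),
               fx$per_capita_2030, tolerance = 1e-6)
})

test_that("a generated world run with its own parameters follows the implied recurrence", {
  cfg <- synthetic_config(seed = 3, quota_level = 7800, quota_trend = 1.005,
                          retirement_rate = 0.02)
  params <- synthetic_parameters(cfg)
  clock <- sim_clock(cfg$base_year, cfg$horizon_year)
  fc <- forecast_headcounts(params, clock)

  # independent recurrence on the total: trainees tracked by hand
  q <- params$quota_series
  pass <- cfg$pass_rate
  entrants <- function(y) pass * q[[as.character(y - cfg$school_duration)]]
  total <- fc$total[["2008"]]
  practice <- total - entrants(2008) - entrants(2007)
  for (y in 2009:2030) {
    practice <- practice + entrants(y - 2) - cfg$retirement_rate * practice
    total_y <- practice + entrants(y) + entrants(y - 1)
    expect_equal(unname(fc$total[[as.character(y)]]), total_y,
                 tolerance = 1e-6)
  }
})

test_that("calibration recovers a known retirement rate", {
  cfg <- synthetic_config(seed = 11, retirement_rate = 0.025)
  truth <- synthetic_parameters(cfg)
  clock <- sim_clock(2008, 2020)
  historic <- forecast_headcounts(truth, clock)$total
  fit <- calibrate(historic, synthetic_parameters(
    synthetic_config(seed = 11, retirement_rate = 0.01)), clock)
  expect_equal(unname(fit$estimates[["retirement_rate"]]), 0.025,
               tolerance = 4e-5)
  expect_lt(fit$rmse, 1e-6)
})

test_that("calibration validates its inputs", {
  cfg <- synthetic_config()
  params <- synthetic_parameters(cfg)
  clock <- sim_clock(2008, 2020)
  historic <- forecast_headcounts(params, clock)$total
  expect_error(calibrate(historic[1:2], params, clock), "at least 3")
  expect_error(calibrate(historic, params, clock, free = "quota"), "among")
})

test_that("the input bundle round-trips through plain-text files", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 9)
  paths <- write_input_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  quota <- read_quota_csv(paths[["quota"]])
  expect_equal(quota, generate_quota_series(cfg), tolerance = 1e-9)
  census <- read_census_csv(paths[["census"]])
  expect_equal(sum(census$headcount), cfg$base_total, tolerance = 1e-6)
  pop <- read_population_csv(paths[["population"]])
  expect_equal(nrow(pop), 23)
  params <- read_parameter_yaml(paths[["parameters"]])
  truth <- synthetic_parameters(cfg)
  expect_equal(params$selection_fractions, truth$selection_fractions)
  expect_equal(params$quota_series, truth$quota_series, tolerance = 1e-9)
  expect_equal(params$initial_stocks, truth$initial_stocks, tolerance = 1e-9)
})

test_that("trajectory and sufficiency CSV writers emit the tidy layouts", {
  params <- fixture_parameters()
  clock <- sim_clock(2008, 2012)
  traj <- run_simulation(build_career_model(params, clock), clock, params)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  tidy <- utils::read.csv(path)
  expect_setequal(names(tidy), c("year", "stock", "speciality", "headcount"))
  expect_equal(nrow(tidy), 5 * ncol(traj$values))

  fc <- forecast_headcounts(params, sim_clock(2008, 2030))
  crits <- fixture_criteria()
  out <- write_sufficiency_csv(
    list(total = sufficiency_series(fc$total, crits$total),
         obgyn = sufficiency_series(fc$speciality$obgyn, crits$obgyn)),
    withr::local_tempfile(fileext = ".csv"))
  expect_true(any(out$maldistribution[out$group == "obgyn"]))
})
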