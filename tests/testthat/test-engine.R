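test_that("step_stock does Euler arithmetic and validates its inputs", {
  expect_equal(step_stock(100, 10, 5, 1), 105)
  expect_equal(step_stock(0, 0, 0, 1), 0)
  expect_error(step_stock(100, 10, 5, -1), "dt")
  expect_error(step_stock(100, -1, 5, 1), "non-negative")
  expect_error(step_stock(100, 1, -5, 1), "non-negative")
})

test_that("repeated proportional outflow follows geometric decay", {
  v <- 100
  for (i in 1:10) v <- step_stock(v, 0, 0.1 * v, 1)
  expect_equal(v, 100 * 0.9^10, tolerance = 1e-12)
})

test_that("outflow is clamped so a stock cannot go negative", {
  expect_equal(step_stock(10, 0, 50, 1), 0)
  expect_gte(step_stock(3, 1, 50, 0.5), 0)
})

test_that("a unit delay chain is identity-with-lag", {
  adv <- advance_delay_chain(delay_chain("d", 1, 50), 60)
  expect_equal(adv$exits, 50)
  expect_equal(adv$chain$cohorts, 60)
})

test_that("a conveyor releases cohorts exactly duration steps after entry", {
  chain <- delay_chain("d", 3)
  exits <- numeric(5)
  for (i in 1:5) {
    adv <- advance_delay_chain(chain, 10)
    chain <- adv$chain
    exits[i] <- adv$exits
  }
  expect_equal(exits, c(0, 0, 0, 10, 10))
})

test_that("a draining conveyor conserves its initial occupancy", {
  chain <- delay_chain("d", 6, cohorts = c(100, 150, 50, 120, 80, 100))
  expect_equal(chain_occupancy(chain), 600)
  total_exits <- 0
  for (i in 1:6) {
    adv <- advance_delay_chain(chain, 0)
    chain <- adv$chain
    total_exits <- total_exits + adv$exits
  }
  expect_equal(total_exits, 600)
  expect_equal(chain_occupancy(chain), 0)
  expect_error(advance_delay_chain(chain, -1), "non-negative")
})

test_that("delay chain construction checks duration and cohort shape", {
  expect_error(delay_chain("d", 0), "positive integer")
  expect_error(delay_chain("d", 3, cohorts = c(1, 2)), "length 3")
  expect_error(delay_chain("d", 2, cohorts = c(-1, 2)), "non-negative")
})

test_that("constant inflow accumulates linearly", {
  model <- single_stock_model(0, 100, 0)
  traj <- run_simulation(model, sim_clock(2000, 2005))
  expect_equal(unname(trajectory_series(traj, "pool")[["2005"]]), 500)
})

test_that("constant hazard with no inflow matches the closed form", {
  model <- single_stock_model(1000, 0, 0.07)
  traj <- run_simulation(model, sim_clock(2000, 2020))
  got <- trajectory_series(traj, "pool")
  years <- as.numeric(names(got))
  expect_equal(unname(got), 1000 * (1 - 0.07)^(years - 2000), tolerance = 1e-14)
})

test_that("inflow I against hazard r converges monotonically to I/r", {
  model <- single_stock_model(0, 100, 0.1)
  traj <- run_simulation(model, sim_clock(2000, 2080))
  dist <- abs(trajectory_series(traj, "pool") - 100 / 0.1)
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[["2080"]], 1)
})

test_that("a closed subsystem conserves total headcount", {
  model <- closed_loop_model()
  traj <- run_simulation(model, sim_clock(2000, 2030))
  total <- trajectory_series(traj, "a") + trajectory_series(traj, "b") +
    trajectory_series(traj, "pipe")
  expect_equal(unname(total), rep(660, length(total)), tolerance = 1e-9)
})

test_that("trajectory bookkeeping: each stock's change equals its net flow", {
  params <- fixture_parameters()
  clock <- sim_clock(2008, 2030)
  traj <- run_simulation(build_career_model(params, clock), clock, params)
  flows <- attr(traj, "flows")
  for (s in c("practice_obgyn", "practice_other")) {
    series <- trajectory_series(traj, s)
    inflow <- flows[, paste0("choice_", sub("practice_", "", s))]
    outflow <- flows[, paste0("retirement_", sub("practice_", "", s))]
    expect_equal(unname(diff(series)), unname((inflow - outflow)[-1]),
                 tolerance = 1e-12)
  }
})

test_that("an independent ledger reproduces a 30-year run exactly", {
  params <- fixture_backcast_parameters()
  clock <- sim_clock(1998, 2028)
  traj <- run_simulation(build_career_model(params, clock), clock, params)
  chain_states <- attr(traj, "chain_states")
  years <- clock_years(clock)
  for (i in seq_len(length(years) - 1)) {
    y <- as.character(years[i]); y1 <- as.character(years[i + 1])
    step <- career_ledger_step(
      stocks = stats::setNames(traj$values[y, "practice_all"], "practice_all"),
      school = chain_states[[y]]$school,
      training = chain_states[[y]]$training,
      year_next = years[i + 1],
      params = params
    )
    expect_equal(unname(step$stocks[["practice_all"]]),
                 unname(traj$values[y1, "practice_all"]))
    expect_equal(unname(step$school), unname(chain_states[[y1]]$school))
    expect_equal(unname(step$training), unname(chain_states[[y1]]$training))
  }
})

test_that("pointwise-larger inflows never decrease a downstream stock", {
  base <- fixture_parameters()
  for (k in 1:5) {
    set.seed(100 + k)
    bumped <- base
    yrs <- names(bumped$quota_series)
    bumped$quota_series <- bumped$quota_series +
      stats::runif(length(yrs), 0, 500)
    clock <- sim_clock(2008, 2030)
    t0 <- forecast_headcounts(base, clock)
    t1 <- forecast_headcounts(bumped, clock)
    expect_true(all(t1$total >= t0$total - 1e-9))
    expect_true(all(t1$speciality$obgyn >= t0$speciality$obgyn - 1e-9))
  }
})

test_that("model wiring is validated", {
  expect_error(
    stock_flow_model(
      stocks = list(stock("a", 1)),
      flows = list(flow("f", "a", "nowhere", function(y, s, p) 0))
    ),
    "unknown endpoint"
  )
  expect_error(flow("f", "a", "a", function(y, s, p) 0), "differ")
  expect_error(stock("", 1), "non-empty")
  expect_error(stock("a", -1), "non-negative")
})

test_that("negative or non-scalar flow rates are rejected at run time", {
  bad <- stock_flow_model(
    stocks = list(stock("a", 10)),
    flows = list(flow("f", "external", "a", function(y, s, p) -1))
  )
  expect_error(run_simulation(bad, sim_clock(2000, 2002)), "negative rate")
})

test_that("the clock validates its calendar", {
  expect_error(sim_clock(2030, 2008), "precede")
  expect_error(sim_clock(2008, 2030, dt = 0), "positive")
  expect_error(sim_clock(2008, 2010, dt = 0.3), "multiple")
  expect_equal(clock_years(sim_clock(2008, 2010, dt = 0.5)),
               seq(2008, 2010, by = 0.5))
})
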