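# Small models and oracles shared across tests.

# single stock fed at a constant rate, drained by a constant per-capita hazard
single_stock_model <- function(init, inflow_rate, hazard) {
  stock_flow_model(
    stocks = list(stock("pool", init)),
    flows = list(
      flow("in", "external", "pool", function(y, s, p) inflow_rate),
      flow("out", "pool", "external",
           function(y, s, p) s$stocks[["pool"]] * hazard)
    )
  )
}

# closed loop: two stocks exchanging a fraction each step, plus a conveyor;
# no external flows, so total headcount must be conserved
closed_loop_model <- function(a0 = 400, b0 = 200, chain0 = c(30, 20, 10)) {
  stock_flow_model(
    stocks = list(stock("a", a0), stock("b", b0)),
    chains = list(delay_chain("pipe", 3, cohorts = chain0)),
    flows = list(
      flow("a_to_pipe", "a", "pipe", function(y, s, p) 0.1 * s$stocks[["a"]]),
      flow("pipe_to_b", "pipe", "b", function(y, s, p) s$exits[["pipe"]]),
      flow("b_to_a", "b", "a", function(y, s, p) 0.25 * s$stocks[["b"]])
    )
  )
}

# hand-rolled ledger for the career-path model: recompute year y+1 from the
# recorded year-y state with plain arithmetic, independent of the engine loop
career_ledger_step <- function(stocks, school, training, year_next, params) {
  specs <- names(params$selection_fractions)
  exits_school <- school[length(school)]
  exits_training <- training[length(training)]
  passes <- exits_school * params$pass_rate
  school_next <- c(unname(params$quota_series[as.character(year_next)]),
                   school[-length(school)])
  training_next <- c(passes, training[-length(training)])
  stocks_next <- stocks
  for (s in specs) {
    nm <- paste0("practice_", s)
    stocks_next[[nm]] <- stocks[[nm]] +
      exits_training * params$selection_fractions[[s]] -
      stocks[[nm]] * params$retirement_rate[[s]]
  }
  list(stocks = stocks_next, school = school_next, training = training_next)
}

fixture_total_criterion <- function() fixture_criteria()$total
fixture_obgyn_criterion <- function() fixture_criteria()$obgyn
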