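# Discrete-time stock-and-flow engine with conveyor delay chains.
#
# Conventions used throughout:
#  * The state labelled with calendar year y is the state at the START of
#    year y. One step advances the state from year y to year y + dt.
#  * Flows applied during that step are labelled with the END year y + dt,
#    so that stock(y + dt) = stock(y) + net_flow(y + dt) * dt. All rate rules
#    are evaluated synchronously against the start-of-step state.
#  * A delay chain advanced during the step ending at year y releases the
#    cohort that entered at flow-year y - duration.

#' Simulation clock
#'
#' Defines the simulated calendar: a base year whose state is given by the
#' initial conditions, a horizon year, and the step width in years.
#'
#' @param base_year Integer calendar year of the initial state.
#' @param horizon_year Integer calendar year the simulation runs to
#'   (inclusive).
#' @param dt Step width in years (default 1, matching annual census data).
#'   `(horizon_year - base_year)` must be an integer multiple of `dt`.
#' @return An object of class `sim_clock`.
#' @examples
#' sim_clock(2008, 2030)
#' @export
sim_clock <- function(base_year, horizon_year, dt = 1) {
  if (!is.numeric(base_year) || !is.numeric(horizon_year) || !is.numeric(dt)) {
    stop("base_year, horizon_year and dt must be numeric", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (base_year >= horizon_year) {
    stop("base_year must precede horizon_year", call. = FALSE)
  }
  n_steps <- (horizon_year - base_year) / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("(horizon_year - base_year) must be an integer multiple of dt",
         call. = FALSE)
  }
  structure(
    list(base_year = base_year, horizon_year = horizon_year, dt = dt,
         n_steps = as.integer(round(n_steps))),
    class = "sim_clock"
  )
}

#' @export
print.sim_clock <- function(x, ...) {
  cat(sprintf("<sim_clock> %d -> %d, dt = %g year(s), %d steps\n",
              x$base_year, x$horizon_year, x$dt, x$n_steps))
  invisible(x)
}

#' Years covered by a clock
#'
#' @param clock A [sim_clock()].
#' @return Numeric vector of calendar years from base to horizon.
#' @export
clock_years <- function(clock) {
  seq(clock$base_year, clock$horizon_year, by = clock$dt)
}

#' One Euler step of a single stock
#'
#' Advances a headcount stock by `(inflow - outflow) * dt`. The outflow is
#' capped at the level that would empty the stock within the step, so
#' headcounts never go negative.
#'
#' @param value Current headcount (non-negative).
#' @param inflow,outflow Rates in persons/year (non-negative).
#' @param dt Step width in years.
#' @return The updated headcount.
#' @examples
#' step_stock(100, 10, 5, 1) # 105
#' @export
step_stock <- function(value, inflow, outflow, dt = 1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (inflow < 0 || outflow < 0) {
    stop("inflow and outflow rates must be non-negative", call. = FALSE)
  }
  outflow <- min(outflow, value / dt)
  value + (inflow - outflow) * dt
}

#' Stock constructor
#'
#' A stock is an accumulating level variable (e.g. practising OB/GYN
#' specialists) tagged with optional labels.
#'
#' @param name Identifier, unique within a model.
#' @param value Initial headcount (non-negative).
#' @param speciality Optional speciality tag carried into tidy output.
#' @param stage Optional career-stage tag.
#' @return An object of class `sd_stock`.
#' @export
stock <- function(name, value, speciality = NA_character_, stage = NA_character_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("stock name must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop("stock value must be a single non-negative number", call. = FALSE)
  }
  structure(list(name = name, value = value,
                 speciality = speciality, stage = stage),
            class = "sd_stock")
}

#' Flow constructor
#'
#' A flow moves persons/year between two endpoints. Endpoints are names of
#' stocks or delay chains declared in the same model, or the keyword
#' `"external"` for flows crossing the system boundary. The rate rule is
#' evaluated once per step against the start-of-step state and must return a
#' single non-negative rate.
#'
#' @param name Identifier, unique within a model.
#' @param source,sink Endpoint names (`"external"` allowed; `source != sink`).
#' @param rate A function `function(year, state, params)` returning
#'   persons/year. `state` has elements `stocks` (named numeric), `exits`
#'   (named numeric, this step's delay-chain releases) and `chains` (named
#'   list of cohort vectors).
#' @return An object of class `sd_flow`.
#' @export
flow <- function(name, source, sink, rate) {
  if (!is.function(rate)) stop("rate must be a function", call. = FALSE)
  if (identical(source, sink)) {
    stop("flow source and sink must differ", call. = FALSE)
  }
  structure(list(name = name, source = source, sink = sink, rate = rate),
            class = "sd_flow")
}

#' Conveyor delay chain
#'
#' A fixed-duration pipeline stage (medical school, postgraduate training):
#' the cohort entering at flow-year t exits, undiminished, at flow-year
#' t + duration. Occupancy is the sum of the resident cohorts; `cohorts[1]`
#' is the most recent entry cohort and `cohorts[duration]` exits next step.
#'
#' @param name Identifier.
#' @param duration Stage length in steps (a positive integer).
#' @param cohorts Optional initial occupancy, newest first; defaults to an
#'   empty chain. Length must equal `duration`.
#' @return An object of class `delay_chain`.
#' @examples
#' delay_chain("school", 6)
#' @export
delay_chain <- function(name, duration, cohorts = rep(0, duration)) {
  if (!is.numeric(duration) || length(duration) != 1L ||
      duration < 1 || abs(duration - round(duration)) > 1e-9) {
    stop("duration must be a positive integer number of steps", call. = FALSE)
  }
  duration <- as.integer(round(duration))
  if (length(cohorts) != duration) {
    stop(sprintf("chain '%s': cohorts must have length %d", name, duration),
         call. = FALSE)
  }
  if (any(cohorts < 0)) {
    stop("chain cohorts must be non-negative", call. = FALSE)
  }
  structure(list(name = name, duration = duration, cohorts = as.numeric(cohorts)),
            class = "delay_chain")
}

#' Advance a delay chain by one step
#'
#' Releases the oldest cohort and admits this step's entrants. Occupancy is
#' conserved: new occupancy = old occupancy + entrants - exits.
#'
#' @param chain A [delay_chain()].
#' @param entrants Persons entering this step (non-negative).
#' @return A list with elements `chain` (the updated chain) and `exits`
#'   (the released headcount).
#' @examples
#' advance_delay_chain(delay_chain("train", 1, 50), 60) # exits 50
#' @export
advance_delay_chain <- function(chain, entrants) {
  if (!inherits(chain, "delay_chain")) stop("not a delay_chain", call. = FALSE)
  if (!is.numeric(entrants) || length(entrants) != 1L || is.na(entrants) ||
      entrants < 0) {
    stop("entrants must be a single non-negative number", call. = FALSE)
  }
  d <- chain$duration
  exits <- chain$cohorts[d]
  chain$cohorts <- c(entrants, chain$cohorts[-d])
  list(chain = chain, exits = exits)
}

#' Occupancy of a delay chain
#' @param chain A [delay_chain()].
#' @return Total headcount currently resident in the chain.
#' @export
chain_occupancy <- function(chain) sum(chain$cohorts)

#' Assemble a stock-and-flow model
#'
#' Validates the wiring: every flow endpoint must resolve to a declared stock,
#' a declared delay chain, or `"external"`. Flows are evaluated in the order
#' given, which together with the synchronous update makes runs deterministic.
#'
#' Flows whose sink is a delay chain are that chain's entrants. Flows whose
#' source is a delay chain route part (or all) of the chain's current step
#' release, available to rate rules as `state$exits[[chain]]`; any unrouted
#' remainder leaves the system (e.g. examination failures).
#'
#' @param stocks List of [stock()] objects.
#' @param chains List of [delay_chain()] objects (may be empty).
#' @param flows List of [flow()] objects.
#' @param aggregates Optional named list of functions
#'   `function(stocks, chains)` (named numeric vector, named list of chains)
#'   returning a derived per-year scalar recorded alongside the stocks
#'   (e.g. total clinical physicians).
#' @return An object of class `stock_flow_model`.
#' @export
stock_flow_model <- function(stocks, chains = list(), flows, aggregates = list()) {
  if (!all(vapply(stocks, inherits, logical(1), "sd_stock"))) {
    stop("stocks must be a list of stock() objects", call. = FALSE)
  }
  if (!all(vapply(chains, inherits, logical(1), "delay_chain"))) {
    stop("chains must be a list of delay_chain() objects", call. = FALSE)
  }
  if (!all(vapply(flows, inherits, logical(1), "sd_flow"))) {
    stop("flows must be a list of flow() objects", call. = FALSE)
  }
  stock_names <- vapply(stocks, `[[`, character(1), "name")
  chain_names <- vapply(chains, `[[`, character(1), "name")
  all_names <- c(stock_names, chain_names)
  if (anyDuplicated(all_names)) {
    stop("stock and chain names must be unique", call. = FALSE)
  }
  endpoints <- c(all_names, "external")
  for (f in flows) {
    bad <- setdiff(c(f$source, f$sink), endpoints)
    if (length(bad)) {
      stop(sprintf("flow '%s': unknown endpoint(s) %s",
                   f$name, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
  }
  if (length(aggregates) &&
      (is.null(names(aggregates)) || any(!nzchar(names(aggregates))))) {
    stop("aggregates must be a named list of functions", call. = FALSE)
  }
  names(stocks) <- stock_names
  names(chains) <- chain_names
  structure(list(stocks = stocks, chains = chains, flows = flows,
                 aggregates = aggregates),
            class = "stock_flow_model")
}

#' @export
print.stock_flow_model <- function(x, ...) {
  cat(sprintf("<stock_flow_model> %d stock(s), %d delay chain(s), %d flow(s)\n",
              length(x$stocks), length(x$chains), length(x$flows)))
  for (s in x$stocks) cat(sprintf("  stock %-22s init %.1f\n", s$name, s$value))
  for (ch in x$chains) {
    cat(sprintf("  chain %-22s duration %d, occupancy %.1f\n",
                ch$name, ch$duration, chain_occupancy(ch)))
  }
  invisible(x)
}

# Evaluate all flow rates against a frozen state; returns named numeric.
eval_flow_rates <- function(model, year, state, params) {
  rates <- vapply(model$flows, function(f) {
    r <- f$rate(year, state, params)
    if (!is.numeric(r) || length(r) != 1L || is.na(r)) {
      stop(sprintf("flow '%s' returned a non-scalar or NA rate at year %s",
                   f$name, year), call. = FALSE)
    }
    if (r < 0) {
      stop(sprintf("flow '%s' returned a negative rate (%g) at year %s",
                   f$name, r, year), call. = FALSE)
    }
    r
  }, numeric(1))
  names(rates) <- vapply(model$flows, `[[`, character(1), "name")
  rates
}

#' Run a stock-and-flow simulation
#'
#' Advances the model from the clock's base year to its horizon with a
#' synchronous explicit Euler update: all flow rates for a step are evaluated
#' against the start-of-step state, delay chains release and admit cohorts,
#' and stocks are updated by their net flow. If the outflows drawn from a
#' stock would exceed its current level within a step they are scaled down
#' proportionally so the stock bottoms out at zero.
#'
#' @param model A [stock_flow_model()].
#' @param clock A [sim_clock()].
#' @param params Arbitrary parameter object passed to every rate rule
#'   (typically a [parameter_set()]).
#' @return A `trajectory` object; see [as.data.frame.trajectory()]. The
#'   per-step flow rates and delay-chain states are kept in attributes
#'   `flows` and `chain_states` so that each year's mass balance can be
#'   audited.
#' @export
run_simulation <- function(model, clock, params = NULL) {
  stopifnot(inherits(model, "stock_flow_model"), inherits(clock, "sim_clock"))
  dt <- clock$dt
  years <- clock_years(clock)
  n <- length(years)

  stock_names <- names(model$stocks)
  chain_names <- names(model$chains)
  agg_names <- names(model$aggregates)
  col_names <- c(stock_names, chain_names, agg_names)

  values <- matrix(NA_real_, nrow = n, ncol = length(col_names),
                   dimnames = list(years, col_names))
  flow_names <- vapply(model$flows, `[[`, character(1), "name")
  flow_rec <- matrix(0, nrow = n, ncol = length(flow_names),
                     dimnames = list(years, flow_names))
  chain_states <- vector("list", n)
  names(chain_states) <- years

  stocks <- vapply(model$stocks, `[[`, numeric(1), "value")
  names(stocks) <- stock_names
  chains <- model$chains

  record <- function(i) {
    occ <- vapply(chains, chain_occupancy, numeric(1))
    aggs <- vapply(model$aggregates, function(f) f(stocks, chains), numeric(1))
    values[i, ] <<- c(stocks, occ, aggs)
    chain_states[[i]] <<- lapply(chains, `[[`, "cohorts")
  }
  record(1L)

  src <- vapply(model$flows, `[[`, character(1), "source")
  snk <- vapply(model$flows, `[[`, character(1), "sink")

  for (i in seq_len(n - 1L)) {
    year_end <- years[i + 1L]
    exits <- vapply(chains, function(ch) ch$cohorts[ch$duration], numeric(1))
    state <- list(stocks = stocks, exits = exits,
                  chains = lapply(chains, `[[`, "cohorts"))
    rates <- eval_flow_rates(model, year_end, state, params)

    # cap outflows drawn from each stock at the available headcount,
    # scaling competing outflows proportionally
    for (s in stock_names) {
      out_idx <- which(src == s)
      total_out <- sum(rates[out_idx])
      if (total_out * dt > stocks[[s]] && total_out > 0) {
        rates[out_idx] <- rates[out_idx] * (stocks[[s]] / (total_out * dt))
      }
    }

    new_stocks <- stocks
    for (s in stock_names) {
      inflow <- sum(rates[snk == s])
      outflow <- sum(rates[src == s])
      new_stocks[[s]] <- stocks[[s]] + (inflow - outflow) * dt
    }
    new_chains <- chains
    for (cn in chain_names) {
      entrants <- sum(rates[snk == cn]) * dt
      adv <- advance_delay_chain(chains[[cn]], entrants)
      new_chains[[cn]] <- adv$chain
    }

    stocks <- new_stocks
    chains <- new_chains
    flow_rec[i + 1L, ] <- rates
    record(i + 1L)
  }

  structure(
    list(years = years, values = values),
    flows = flow_rec,
    chain_states = chain_states,
    clock = clock,
    stock_meta = data.frame(
      stock = stock_names,
      speciality = vapply(model$stocks, `[[`, character(1), "speciality"),
      stage = vapply(model$stocks, `[[`, character(1), "stage"),
      stringsAsFactors = FALSE
    ),
    class = "trajectory"
  )
}

#' Extract one series from a trajectory
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param name A stock, delay-chain or aggregate name.
#' @return Named numeric vector (names are calendar years).
#' @export
trajectory_series <- function(traj, name) {
  stopifnot(inherits(traj, "trajectory"))
  if (!name %in% colnames(traj$values)) {
    stop(sprintf("no series named '%s' in trajectory; available: %s", name,
                 paste(colnames(traj$values), collapse = ", ")), call. = FALSE)
  }
  stats::setNames(traj$values[, name], rownames(traj$values))
}

#' Tidy view of a trajectory
#'
#' @param x A `trajectory`.
#' @param row.names,optional Unused, present for the generic.
#' @param ... Unused.
#' @return A data frame with columns `year`, `stock`, `speciality`,
#'   `headcount`, one row per (year, series).
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  meta <- attr(x, "stock_meta")
  spec_of <- stats::setNames(meta$speciality, meta$stock)
  series <- colnames(x$values)
  out <- data.frame(
    year = rep(x$years, times = length(series)),
    stock = rep(series, each = length(x$years)),
    speciality = rep(unname(spec_of[series]), each = length(x$years)),
    headcount = as.vector(x$values),
    stringsAsFactors = FALSE
  )
  out[order(out$year, out$stock), , drop = FALSE]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> years %s-%s; series: %s\n",
              min(x$years), max(x$years),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, series = colnames(x$values)[1], ...) {
  y <- trajectory_series(x, series)
  graphics::plot(x$years, y, type = "l", xlab = "year",
                 ylab = "headcount", main = series, ...)
  invisible(x)
}
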