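base_params <- fixture_parameters()
clock22 <- sim_clock(2008, 2030)

test_that("quota multipliers scale the series from the start year onward", {
  scn <- scenario("up", quota_multiplier = 1.15, start_year = 2008)
  p <- apply_scenario(base_params, scn)
  expect_equal(unname(p$quota_series[["2008"]]),
               unname(base_params$quota_series[["2008"]]) * 1.15)
  expect_equal(p$quota_series[["2007"]], base_params$quota_series[["2007"]])
  expect_equal(7625 * 1.15, 8768.75)
  expect_equal(unname(apply_scenario(
    parameter_set(c(`2007` = 7625, `2008` = 7625), 0.9, c(all = 1), 0.02,
                  c(all = 0)),
    scn)$quota_series[["2008"]]), 8768.75)
})

test_that("the identity scenario leaves parameters untouched", {
  p <- apply_scenario(base_params, scenario("baseline"), base_year = 2008)
  expect_equal(p$quota_series, base_params$quota_series)
  expect_equal(p$selection_fractions, base_params$selection_fractions)
})

test_that("choice deltas shift one fraction and renormalize the rest", {
  p0 <- parameter_set(stats::setNames(rep(8000, 40), 1991:2030), 0.9,
                      c(obgyn = 0.04, surgery = 0.16, other = 0.80),
                      0.02, c(obgyn = 0, surgery = 0, other = 0))
  p1 <- apply_scenario(p0, scenario("plus1", choice_delta = 1),
                       base_year = 2008)
  expect_equal(unname(p1$selection_fractions[["obgyn"]]), 0.05)
  expect_equal(unname(p1$selection_fractions[["surgery"]]),
               0.16 * 0.95 / 0.96)
  expect_equal(sum(p1$selection_fractions), 1, tolerance = 1e-12)
  # relative mode: +1% of the fraction itself
  p2 <- apply_scenario(p0, scenario("rel", choice_delta = 1,
                                    delta_mode = "relative"),
                       base_year = 2008)
  expect_equal(unname(p2$selection_fractions[["obgyn"]]), 0.04 * 1.01)
  expect_error(apply_scenario(p0, scenario("bad", choice_delta = 97),
                              base_year = 2008), "outside")
})

test_that("quota multipliers compose multiplicatively", {
  a <- apply_scenario(base_params, scenario("a", quota_multiplier = 1.1),
                      base_year = 2008)
  ab <- apply_scenario(a, scenario("b", quota_multiplier = 1.2),
                       base_year = 2008)
  direct <- apply_scenario(base_params, scenario("c", quota_multiplier = 1.32),
                           base_year = 2008)
  expect_equal(ab$quota_series, direct$quota_series, tolerance = 1e-12)
})

test_that("sensitivity runs are deterministic and baseline has zero impact", {
  scns <- list(scenario("baseline"), scenario("same"),
               scenario("up", quota_multiplier = 1.15))
  res1 <- run_sensitivity(base_params, scns, clock22,
                          fixture_total_criterion())
  res2 <- run_sensitivity(base_params, scns, clock22,
                          fixture_total_criterion())
  expect_equal(res1$up$series$level, res2$up$series$level)
  expect_equal(res1$baseline$impact, 0)
  expect_equal(res1$same$impact, 0)
  expect_equal(res1$same$series$level, res1$baseline$series$level)
})

test_that("horizon sufficiency is monotone in the quota multiplier", {
  mults <- c(0.85, 0.95, 1, 1.05, 1.15)
  scns <- lapply(mults, function(m) {
    scenario(sprintf("m%.2f", m), quota_multiplier = m)
  })
  res <- run_sensitivity(base_params, scns, clock22,
                         fixture_total_criterion())
  finals <- vapply(res, function(r) r$series$level[r$series$year == 2030],
                   numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("symmetric scenarios bracket the baseline after the pipeline delay", {
  scns <- list(scenario("up", quota_multiplier = 1.15),
               scenario("down", quota_multiplier = 0.85))
  res <- run_sensitivity(base_params, scns, clock22,
                         fixture_total_criterion())
  base <- attr(res, "baseline")
  late <- base$year >= 2008 + base_params$school_duration
  expect_true(all(res$up$series$level[late] >= base$level[late]))
  expect_true(all(res$down$series$level[late] <= base$level[late]))
})

test_that("impact ranking is by absolute impact with name tie-breaks", {
  scns <- list(scenario("baseline"),
               scenario("quota +15%", quota_multiplier = 1.15),
               scenario("choice +1pp", choice_delta = 1))
  res <- run_sensitivity(base_params, scns, clock22,
                         fixture_obgyn_criterion(), group = "obgyn")
  ranking <- rank_impacts(res)
  expect_equal(ranking$scenario[1], "choice +1pp")
  expect_equal(ranking$rank, 1:3)
  expect_equal(ranking$impact[ranking$scenario == "baseline"], 0)
  single <- rank_impacts(run_sensitivity(base_params,
                                         list(scenario("only")),
                                         clock22, fixture_total_criterion()))
  expect_equal(nrow(single), 1)
})

test_that("scenario errors carry the scenario name", {
  expect_error(
    run_sensitivity(base_params,
                    list(scenario("broken", choice_delta = 99)),
                    clock22, fixture_total_criterion()),
    "broken")
})
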