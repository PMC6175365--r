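test_that("cycle age distributions keep equal area in every state", {
  expect_equal(cycle_age_distribution(30, 30), 0:29)
  expect_equal(cycle_age_distribution(5, 30), rep(0:4, each = 6))
  expect_error(cycle_age_distribution(7, 30), "not divisible")
})

test_that("scenario specs encode the published configurations", {
  s <- scenario_spec("2.3")
  expect_equal(s$cycle_length, 5)
  expect_equal(s$spare_fraction, 5 / 6)
  expect_equal(s$spare_kind, "abandoned_secondary")
  expect_equal(scenario_spec("3.1")$spare_kind, "old_growth")
  expect_equal(scenario_spec("baseline")$cycle_length, 30)
  expect_error(scenario_spec("x9"), "unknown scenario")
  expect_error(scenario_spec("x", cycle_length = 15, spare_fraction = 0.37,
                             spare_kind = "old_growth"), "integer")
  expect_error(scenario_spec("x", cycle_length = 15, spare_fraction = 0.4,
                             spare_kind = "old_growth"), "not divisible")
})

test_that("build_landscape places spared and cycled parcels", {
  of <- build_landscape(scenario_spec("OF"))
  expect_equal(nrow(of), 30)
  expect_true(all(of$kind == "old_growth"))

  s31 <- build_landscape(scenario_spec("3.1"))
  expect_equal(sum(s31$kind == "old_growth"), 15)
  expect_equal(sort(s31$age[s31$kind != "old_growth"]),
               sort(cycle_age_distribution(15, 15)))

  s23 <- build_landscape(scenario_spec("2.3"))
  expect_equal(sum(s23$kind == "abandoned"), 25)
  # the oldest 25 states of the initial 30-yr landscape: ages 5..29
  expect_equal(sort(s23$age[s23$kind == "abandoned"]), 5:29)
  expect_equal(sort(s23$age[s23$kind %in% c("farmland", "fallow")]), 0:4)

  s4 <- build_landscape(scenario_spec("4"))
  expect_equal(sort(s4$age), 0:29)
})

test_that("advance rotates cycles and ages abandoned parcels", {
  st <- build_landscape(scenario_spec("baseline"))
  # a 29-yr fallow advanced one year is cleared to farmland
  idx <- which(st$age == 29)
  st1 <- advance(st, 1)
  expect_equal(st1$kind[idx], "farmland")
  expect_equal(st1$age[idx], 0)
  # periodicity: a full cycle returns the same age multiset
  expect_equal(sort(advance(st, 30)$age), sort(st$age))
  st15 <- build_landscape(scenario_spec("1.1"))
  expect_equal(sort(advance(st15, 15)$age), sort(st15$age))

  s2 <- build_landscape(scenario_spec("2.1"))
  s2a <- advance(s2, 10)
  expect_equal(sort(s2a$age[s2a$kind == "abandoned"]), 25:39)
  expect_true(all(s2a$kind[s2a$kind == "abandoned"] == "abandoned"))
})

test_that("landscape draws conserve the parcel sum and respect samplers", {
  st <- build_landscape(scenario_spec("OF"))
  const <- make_constant_sampler(100)
  tot <- draw_landscape_carbon(st, list(old_growth = const))
  expect_equal(as.numeric(tot), 3000)
  expect_equal(as.numeric(tot), sum(attr(tot, "parcels")))

  mixed <- build_landscape(scenario_spec("3.1"))
  samplers <- list(old_growth = make_constant_sampler(400),
                   farmland = make_constant_sampler(10),
                   fallow = make_constant_sampler(50))
  tot2 <- draw_landscape_carbon(mixed, samplers)
  expect_equal(as.numeric(tot2), 15 * 400 + 1 * 10 + 14 * 50)
  expect_error(draw_landscape_carbon(mixed, list(fallow = const)),
               "no carbon sampler")
})

test_that("simulate matches closed forms for constant samplers", {
  samplers <- list(old_growth = make_constant_sampler(441.4),
                   farmland = make_constant_sampler(10),
                   fallow = make_constant_sampler(50))
  for (id in c("OF", "baseline", "2.2", "3.3")) {
    spec <- scenario_spec(id, n_sims = 50)
    st <- advance(build_landscape(spec), 30)
    expected <- sum(ifelse(st$kind == "old_growth", 441.4,
                           ifelse(st$kind == "farmland", 10, 50)))
    sim <- simulate_scenario(spec, samplers, seed = 1)
    expect_equal(sim$mean, expected, info = id)
    expect_equal(sim$sd, 0, info = id)
  }
})

test_that("simulation is reproducible and consistent with its summaries", {
  tab <- generate_plot_carbon(default_params(), seed = 4)
  samplers <- list(
    farmland = make_empirical_sampler(
      tab$total_carbon[tab$habitat == "farmland"]),
    old_growth = make_empirical_sampler(
      tab$total_carbon[tab$habitat == "old_growth"]),
    fallow = make_model_sampler(calibrated_growth_fit(248)))
  a <- simulate_scenario(scenario_spec("2.1", n_sims = 200), samplers,
                         seed = 42)
  b <- simulate_scenario(scenario_spec("2.1", n_sims = 200), samplers,
                         seed = 42)
  expect_identical(a$totals, b$totals)
  expect_equal(a$mean, mean(a$totals))
  expect_equal(a$sd, sd(a$totals))
  expect_equal(unname(a$quartiles),
               unname(quantile(a$totals, c(0.25, 0.5, 0.75))))
  c_ <- simulate_scenario(scenario_spec("2.1", n_sims = 200), samplers,
                          seed = 43)
  expect_false(identical(a$totals, c_$totals))
})

test_that("mean landscape carbon is monotone in cycle length and sparing", {
  fit <- calibrated_growth_fit(248)
  samplers <- list(old_growth = make_constant_sampler(441.4),
                   farmland = make_constant_sampler(10),
                   fallow = make_model_sampler(fit, mode = "mean"))
  mean_of <- function(id) simulate_scenario(
    scenario_spec(id, n_sims = 2), samplers, seed = 1)$mean
  m <- vapply(c("1.3", "1.2", "1.1", "baseline"), mean_of, numeric(1))
  expect_true(all(diff(m) > 0))   # 5 < 10 < 15 < 30 yr cycles
  s <- vapply(c("baseline", "3.1", "3.2", "3.3", "OF"), mean_of, numeric(1))
  expect_true(all(diff(s) > 0))   # sparing 0 < 1/2 < 2/3 < 5/6 < 1
})

test_that("sparing_mixture and relative_change reproduce arithmetic identities", {
  expect_equal(sparing_mixture(0.5, 13261.7, 1179.8), 7220.75)
  expect_equal(sparing_mixture(0, 3, 5), 5)
  expect_equal(sparing_mixture(1, 3, 5), 3)
  expect_error(sparing_mixture(1.2, 3, 5), "\\[0, 1\\]")
  expect_equal(relative_change(5, 5)$change_pct, 0)
  expect_equal(relative_change(2699.7, 13261.7)$change_pct, -79.6,
               tolerance = 1e-3)
  expect_error(relative_change(5, 0), "zero")
})

test_that("sensitivity samplers return medians or literature constants", {
  vals <- c(300, 400, 500, 600, 700)
  med <- sensitivity_of_sampler("median", values = vals)
  expect_equal(med(NA, 3), rep(500, 3))
  lit <- sensitivity_of_sampler("literature", value = 321.29)
  expect_equal(lit(NA, 2), rep(321.29, 2))
  st <- build_landscape(scenario_spec("OF"))
  expect_equal(as.numeric(draw_landscape_carbon(st, list(old_growth = lit))),
               30 * 321.29)
})
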