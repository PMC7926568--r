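# Orchestration: full runs, variants, comparisons and sweeps.

test_that("a full run reproduces the hand-computed known-answer projection", {
  ka <- known_answer_scenario()
  res <- run_scenario(ka$scenario)
  ex <- ka$expected
  d <- res$cadres
  yk <- as.character(d$year)

  expect_equal(setNames(d$need_fte, yk), ex$need_fte, tolerance = 1e-12)
  expect_equal(setNames(d$supply_fte, yk), ex$supply_fte, tolerance = 1e-12)
  expect_equal(setNames(d$need, yk), ex$need)
  expect_equal(setNames(d$supply, yk), ex$supply)
  expect_equal(setNames(d$gap, yk), ex$gap)
  expect_equal(setNames(d$sar, yk), ex$sar, tolerance = 1e-12)
  expect_equal(setNames(d$income, yk), ex$income, tolerance = 1e-12)
  expect_equal(setNames(d$cost_of_need, yk), ex$cost_of_need,
               tolerance = 1e-12)
  expect_equal(setNames(d$cost_of_supply, yk), ex$cost_of_supply,
               tolerance = 1e-12)

  sv <- res$services
  for (sid in c("antenatal", "screening")) {
    rows <- sv[sv$service_id == sid, ]
    expect_equal(setNames(rows$volume, rows$year),
                 ex[[paste0("volume_", sid)]], tolerance = 1e-12)
  }
})

test_that("result invariants hold on synthetic runs", {
  res <- run_scenario(generate_synthetic_scenario(seed = 5))
  d <- res$cadres
  expect_equal(d$gap, d$supply - d$need)
  ok <- !is.na(d$sar)
  expect_equal(d$sar[ok], d$supply[ok] / d$need[ok])
  expect_true(all(d$need_fte >= 0))
  expect_true(all(d$supply_fte >= 0))
  expect_true(all(res$services$volume >= 0))
})

test_that("runs are deterministic: identical scenarios give identical results", {
  a <- run_scenario(generate_synthetic_scenario(seed = 9))
  b <- run_scenario(generate_synthetic_scenario(seed = 9))
  expect_identical(a, b)
})

test_that("zero population yields zero need and untouched supply", {
  scn <- tiny_scenario(0, years = 2020:2022)
  res <- run_scenario(scn)
  expect_equal(res$cadres$need_fte, rep(0, 3))
  expect_equal(res$cadres$supply_fte, rep(10, 3))
})

test_that("a variant with all flags at defaults equals the base run", {
  scn <- generate_synthetic_scenario(seed = 13)
  noop <- scenario_variant("noop", list())
  res_b <- run_scenario(scn)
  res_v <- run_scenario(apply_variant(scn, noop))
  expect_equal(res_v$cadres, res_b$cadres)
  expect_equal(res_v$services, res_b$services)
})

test_that("switching a positive rate of change off strictly lowers need after the first year", {
  scn <- tiny_scenario(1000, h = 0.2, rate = 0.05, years = 2020:2025)
  base <- run_scenario(scn)
  varnt <- run_scenario(apply_variant(scn, "no-rate-change"))
  cmp <- compare_scenarios(base, varnt)
  need_diff <- cmp[cmp$metric == "need", ]
  expect_equal(need_diff$diff[need_diff$year == 2020], 0)
  expect_true(all(need_diff$diff[need_diff$year > 2020] < 0))
})

test_that("doubling service standards (tertiary setting) exactly doubles need", {
  pop <- data.frame(age_cohort = "a", gender = "female", location = "all",
                    year = 2020:2023, count = 1000)
  scn <- validate_scenario(scenario(
    "settings", 2020, 2023, pop,
    indicators = list(health_indicator("i", 0.2, 2020,
                                       rate_of_change = 0.03)),
    services = list(service_norm("s", "i", 4,
                                 c(primary = 0.5, tertiary = 1.0),
                                 c(w = 1))),
    cadres = list(cadre_profile("w", 10))))
  base <- run_scenario(scn)
  tert <- run_scenario(apply_variant(scn, "tertiary-standards"))
  expect_equal(tert$cadres$need_fte, 2 * base$cadres$need_fte,
               tolerance = 1e-12)
})

test_that("dropping the support adjustment divides need by SAAF", {
  scn <- tiny_scenario(1000, sas = c(0.125, 0.05), years = 2020:2022)
  base <- run_scenario(scn)
  nosup <- run_scenario(apply_variant(scn, "no-support-adjustment"))
  expect_equal(base$cadres$need_fte,
               nosup$cadres$need_fte / (1 - 0.175), tolerance = 1e-12)
})

test_that("comparison is zero on identical runs and errors on mismatched horizons", {
  res <- run_scenario(generate_synthetic_scenario(seed = 2))
  cmp <- compare_scenarios(res, res)
  expect_true(all(cmp$diff == 0, na.rm = TRUE))
  expect_true(all(cmp$pct_diff == 0, na.rm = TRUE))

  other <- run_scenario(generate_synthetic_scenario(seed = 2,
                                                    horizon_end = 2023))
  expect_error(compare_scenarios(res, other), "horizons differ")
})

test_that("parameter overrides follow paths and reject unknown ones", {
  scn <- generate_synthetic_scenario(seed = 4)
  scn2 <- scenario_override(scn, "cadres[cadre_a].attrition_rate", 0.5)
  expect_equal(get_attr <- scn2$cadres[[1]]$attrition_rate, 0.5)
  scn3 <- scenario_override(scn, "practice_setting", "tertiary")
  expect_equal(scn3$practice_setting, "tertiary")
  scn4 <- scenario_override(scn, "flags.apply_rate_of_change", FALSE)
  expect_false(scn4$apply_rate_of_change)
  expect_error(scenario_override(scn, "cadres[ghost].attrition_rate", 0.1),
               "does not exist")
  expect_error(apply_variant(scn, scenario_variant(
    "bad", list("services[ghost].frequency" = 2))), "does not exist")
})

test_that("degenerate sweep ranges reproduce the base trajectory", {
  scn <- generate_synthetic_scenario(seed = 21, horizon_end = 2022)
  a0 <- scn$cadres[[1]]$attrition_rate
  sw <- sensitivity_sweep(scn,
                          list("cadres[cadre_a].attrition_rate" = c(a0, a0)),
                          n_samples = 3, seed = 5)
  base_need <- sw$base$cadres$need_fte
  env_need <- sw$envelope[sw$envelope$metric == "need", ]
  expect_equal(env_need$min, env_need$max)
  expect_equal(env_need$min[order(env_need$cadre_id, env_need$year)],
               base_need[order(sw$base$cadres$cadre_id,
                               sw$base$cadres$year)])
})

test_that("sweep envelopes contain the base trajectory and are seed-reproducible", {
  scn <- generate_synthetic_scenario(seed = 22, horizon_end = 2022)
  ranges <- list("cadres[cadre_a].attrition_rate" = c(0.02, 0.08),
                 "cadres[cadre_a].participation_rate" = c(0.75, 0.95),
                 "indicators[indicator_1].rate_of_change" = c(0, 0.05))
  sw1 <- sensitivity_sweep(scn, ranges, n_samples = 8, seed = 7)
  sw2 <- sensitivity_sweep(scn, ranges, n_samples = 8, seed = 7)
  expect_identical(sw1$envelope, sw2$envelope)
  expect_identical(sw1$samples, sw2$samples)

  base_vals <- sw1$base$cadres
  env <- sw1$envelope
  expect_true(all(env$min <= env$max))
  need_env <- env[env$metric == "need", ]
  m <- merge(need_env, base_vals[c("cadre_id", "year", "need_fte")])
  expect_true(all(m$min <= m$need_fte + 1e-9 & m$need_fte <= m$max + 1e-9))

  # monotone response: minimum supply is attained at maximum attrition
  hi_a <- run_scenario(scenario_override(scn,
                                         "cadres[cadre_a].attrition_rate",
                                         0.08))
  sup_env <- env[env$metric == "supply", ]
  m2 <- merge(sup_env, hi_a$cadres[c("cadre_id", "year", "supply_fte")])
  m2 <- m2[m2$cadre_id == "cadre_a", ]
  expect_true(all(m2$min <= m2$supply_fte + 1e-9))

  expect_error(sensitivity_sweep(scn, list("cadres[cadre_a].attrition_rate" =
                                             c(0.5, 0.1))), "low <= high")
})
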