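# Needs engine: rates of change, indicator projection, service volumes,
# standard workloads, SAAF and workforce requirements.

test_that("rate of change estimation matches independent arithmetic for both conventions", {
  # no change forces a zero rate
  expect_equal(estimate_rate_of_change(0.10, 2007, 0.10, 2017), 0)

  # geometric: solve 0.1 * (1+r)^10 = 0.2 numerically as the oracle
  r_oracle <- uniroot(function(r) 0.1 * (1 + r)^10 - 0.2,
                      c(0, 1), tol = 1e-12)$root
  expect_equal(estimate_rate_of_change(0.10, 2007, 0.20, 2017, "geometric"),
               r_oracle, tolerance = 1e-9)
  expect_equal(round(r_oracle, 5), 0.07177)

  # continuous: ln 2 / 10
  expect_equal(estimate_rate_of_change(0.10, 2007, 0.20, 2017, "continuous"),
               log(2) / 10)

  # declining indicator gives a negative rate
  expect_lt(estimate_rate_of_change(0.3, 2010, 0.2, 2015), 0)

  expect_error(estimate_rate_of_change(0, 2007, 0.2, 2017), "undefined")
  expect_error(estimate_rate_of_change(0.1, 2017, 0.2, 2017), "after")
})

test_that("health status projection compounds annually with clamping", {
  flat <- health_indicator("i", 0.2, 2020, rate_of_change = 0)
  expect_equal(unname(project_health_status(flat, 2020:2025)), rep(0.2, 6))

  growing <- health_indicator("i", 0.2, 2020, rate_of_change = 0.05)
  h <- project_health_status(growing, 2020:2022)
  expect_equal(unname(h), c(0.2, 0.2 * 1.05, 0.2 * 1.05^2))
  expect_equal(h[["2022"]], 0.2205)

  # clamped at 1: 0.9 * 1.2^3 = 1.5552 exceeds 1
  fast <- health_indicator("i", 0.9, 2020, rate_of_change = 0.2)
  expect_equal(unname(project_health_status(fast, 2023)), 1.0)

  # apply_rate = FALSE holds baseline regardless of the rate
  expect_equal(unname(project_health_status(growing, 2020:2025,
                                            apply_rate = FALSE)),
               rep(0.2, 6))

  expect_error(project_health_status(growing, 2019), "before its baseline")
})

test_that("rate resolved from two waves reproduces the second wave under geometric compounding", {
  ind <- health_indicator("i", 0.10, 2007, second_value = 0.20,
                          second_year = 2017)
  h <- project_health_status(ind, c(2007, 2017, 2020))
  expect_equal(h[["2007"]], 0.10)
  expect_equal(h[["2017"]], 0.20, tolerance = 1e-9)
})

test_that("service need sums population x level x frequency over matched strata", {
  # one stratum: 1000 x 0.1 x 4 = 400
  scn <- tiny_scenario(1000, h = 0.1, rate = 0, freq = 4)
  expect_equal(compute_service_need(scn, "svc", 2020), 400)

  # additivity over strata: 400 + 200 = 600
  pop <- rbind(
    data.frame(age_cohort = "a", gender = "female", location = "all",
               year = 2020, count = 1000),
    data.frame(age_cohort = "b", gender = "female", location = "all",
               year = 2020, count = 500))
  scn2 <- validate_scenario(scenario(
    "two-strata", 2020, 2020, pop,
    indicators = list(
      health_indicator("ia", 0.1, 2020, rate_of_change = 0,
                       age_cohort = "a"),
      health_indicator("ib", 0.2, 2020, rate_of_change = 0,
                       age_cohort = "b")),
    services = list(
      service_norm("sa", "ia", 4, 1, c(w = 1)),
      service_norm("sb", "ib", 2, 1, c(w = 1))),
    cadres = list(cadre_profile("w", 10))))
  expect_equal(compute_service_need(scn2, "sa", 2020) +
                 compute_service_need(scn2, "sb", 2020), 600)

  expect_error(compute_service_need(scn, service_norm("x", "ghost", 1, 1,
                                                      c(worker = 1)), 2020),
               "unknown indicator")
})

test_that("available working time follows the WISN absence arithmetic", {
  expect_equal(compute_awt(awt_components(260, 9, 21, 5, 4, 8)), 1768)
  expect_equal(compute_awt(awt_components(260, 0, 0, 0, 0, 8)), 2080)
  expect_error(compute_awt(awt_components(260, 100, 100, 100, 0, 8)),
               "absences exceed")
})

test_that("standard workload is AWT over the service standard", {
  expect_equal(compute_standard_workload(1768, 0.5), 3536)
  expect_equal(compute_standard_workload(1768, 1768), 1)
  expect_equal(compute_standard_workload(2080, 1.0), 2080)
  expect_error(compute_standard_workload(1768, 0), "> 0")
})

test_that("SAAF inflates by the inverse of time left for direct care", {
  expect_equal(compute_saaf(c(0.125, 0.05)), 1 / (1 - 0.175))
  expect_equal(round(compute_saaf(c(0.125, 0.05)), 3), 1.212)
  expect_equal(round((compute_saaf(0.15) - 1) * 100, 1), 17.6)
  expect_equal(compute_saaf(list()), 1.0)
  expect_equal(compute_saaf(list(support_activity("handover", 0.125),
                                 support_activity("meetings", 0.05))),
               1 / (1 - 0.175))
  expect_gte(compute_saaf(runif(3, 0, 0.2)), 1)
  expect_error(compute_saaf(c(0.6, 0.5)), ">= 1")
})

test_that("workforce requirement divides shared volume by standard workload and applies SAAF", {
  # volume 3536 at SW 3536 is exactly one FTE
  scn <- tiny_scenario(3536, h = 1, rate = 0, freq = 1, ss = 0.5)
  expect_equal(compute_workforce_requirement(scn, "worker", 2020), 1.0)

  # same with SAS totalling 0.175: exactly SAAF FTE
  scn_s <- tiny_scenario(3536, h = 1, rate = 0, freq = 1, ss = 0.5,
                         sas = c(0.125, 0.05))
  expect_equal(compute_workforce_requirement(scn_s, "worker", 2020),
               1 / (1 - 0.175))

  # a cadre with no service share: zero with a warning
  scn2 <- scn
  scn2$cadres <- c(scn2$cadres, list(cadre_profile("idle", 5)))
  scn2 <- validate_scenario(scn2)
  expect_warning(req <- compute_workforce_requirement(scn2, "idle", 2020),
                 "shares in no service")
  expect_equal(req, 0)
})

test_that("need is homogeneous of degree one in population", {
  scn <- generate_synthetic_scenario(seed = 11, horizon_end = 2022)
  doubled <- scn
  doubled$population$count <- doubled$population$count * 2
  doubled <- validate_scenario(doubled)
  for (cid in vapply(scn$cadres, `[[`, character(1), "cadre_id")) {
    expect_equal(compute_workforce_requirement(doubled, cid, 2022),
                 2 * compute_workforce_requirement(scn, cid, 2022),
                 tolerance = 1e-12)
  }
  svc1 <- scn$services[[1]]
  expect_equal(compute_service_need(doubled, svc1, 2021),
               2 * compute_service_need(scn, svc1, 2021),
               tolerance = 1e-12)
})

test_that("with rates off and constant population, need is flat across the horizon", {
  scn <- tiny_scenario(1000, h = 0.3, rate = 0.08, freq = 2,
                       years = 2020:2026, apply_rate = FALSE)
  needs <- vapply(2020:2026,
                  function(y) compute_workforce_requirement(scn, "worker", y),
                  numeric(1))
  expect_equal(needs, rep(needs[1], 7))
})

test_that("raising an indicator's rate of change never decreases later-year need", {
  for (r_lo in c(0, 0.01, 0.03)) {
    lo <- tiny_scenario(1000, h = 0.2, rate = r_lo, years = 2020:2025)
    hi <- tiny_scenario(1000, h = 0.2, rate = r_lo + 0.02, years = 2020:2025)
    for (y in 2021:2025) {
      expect_gte(compute_workforce_requirement(hi, "worker", y),
                 compute_workforce_requirement(lo, "worker", y))
    }
  }
})

test_that("support adjustment multiplies direct need by SAAF exactly", {
  scn_direct <- tiny_scenario(1000, sas = c(0.12, 0.07),
                              apply_support = FALSE)
  scn_adj <- tiny_scenario(1000, sas = c(0.12, 0.07), apply_support = TRUE)
  expect_equal(compute_workforce_requirement(scn_adj, "worker", 2021),
               compute_workforce_requirement(scn_direct, "worker", 2021) *
                 (1 / (1 - 0.19)),
               tolerance = 1e-12)
})

test_that("vectorized need equals the per-stratum per-service loop oracle on random scenarios", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    scn <- generate_synthetic_scenario(
      seed = seed, n_age_cohorts = sample(2:5, 1), n_locations = 2,
      n_services = sample(2:6, 1), n_cadres = sample(2:3, 1),
      horizon_end = 2023)
    yrs <- sample(2020:2023, 2)
    for (cid in vapply(scn$cadres, `[[`, character(1), "cadre_id")) {
      for (y in yrs) {
        expect_equal(compute_workforce_requirement(scn, cid, y),
                     oracle_need_fte(scn, cid, y),
                     tolerance = 1e-9)
      }
    }
  }
})
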