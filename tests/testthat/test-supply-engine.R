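# Supply engine: attrition, pipeline inflow and the stock-and-flow
# recursion.

test_that("attrition rate is exits over opening stock with boundary handling", {
  expect_equal(compute_attrition_rate(50, 1000), 0.05)
  expect_equal(compute_attrition_rate(0, 1000), 0)
  expect_equal(compute_attrition_rate(1000, 1000), 1) # complete turnover
  expect_error(compute_attrition_rate(1001, 1000), "exceed")
  expect_error(compute_attrition_rate(5, 0), "> 0")
})

test_that("pipeline inflow applies dropout, immigration and pass rate in order", {
  pl <- education_pipeline(enrolment_by_year = c(`2020` = 100),
                           dropout_rate = 0.1, training_duration = 0,
                           pass_rate = 1)
  expect_equal(compute_pipeline_inflow(pl, 2020), 90)

  pl2 <- education_pipeline(enrolment_by_year = c(`2020` = 100),
                            dropout_rate = 0.1, pass_rate = 0.8,
                            immigration_by_year = c(`2020` = 10))
  expect_equal(compute_pipeline_inflow(pl2, 2020), (90 + 10) * 0.8)

  # lagged enrolment lookup
  pl3 <- education_pipeline(enrolment_by_year = c(`2018` = 100),
                            dropout_rate = 0.1, training_duration = 3,
                            pass_rate = 1)
  expect_equal(compute_pipeline_inflow(pl3, 2021), 90)

  # missing lagged year: domestic term 0 (warned), immigration still flows
  pl4 <- education_pipeline(enrolment_by_year = c(`2015` = 100),
                            pass_rate = 0.8,
                            immigration_by_year = c(`2020` = 5))
  expect_warning(inflow <- compute_pipeline_inflow(pl4, 2020),
                 "no enrolment recorded")
  expect_equal(inflow, 4)
  expect_silent(compute_pipeline_inflow(pl4, 2020, quiet = TRUE))
})

test_that("stock-and-flow recursion matches one-step arithmetic and the closed form", {
  # closed system: constant supply
  cad0 <- cadre_profile("c", 100)
  s0 <- project_supply(cad0, 2020:2025)
  expect_equal(unname(s0$effective_supply_by_year), rep(100, 6))

  # one step: (100 * 0.95 + 10) * 0.9 = 94.5
  cad1 <- cadre_profile("c", 100, attrition_rate = 0.05,
                        participation_rate = 0.9,
                        pipeline = education_pipeline(
                          enrolment_by_year = c(`2021` = 10)))
  s1 <- project_supply(cad1, 2020:2021)
  expect_equal(s1$effective_supply_by_year[["2021"]], 94.5)

  # pure decay over 10 years: 100 * 0.95^10
  cad2 <- cadre_profile("c", 100, attrition_rate = 0.05)
  s2 <- project_supply(cad2, 2020:2030)
  expect_equal(s2$registered_stock_by_year[["2030"]], 100 * 0.95^10,
               tolerance = 1e-12)
  expect_equal(round(s2$registered_stock_by_year[["2030"]], 2), 59.87)

  # effective supply is registered stock times participation, every year
  expect_equal(s1$effective_supply_by_year,
               s1$registered_stock_by_year * 0.9)
})

test_that("recursion equals the closed-form geometric sum on varying-inflow cases", {
  for (seed in 1:10) {
    set.seed(seed)
    years <- 2020:2028
    cad <- cadre_profile(
      "c", baseline_stock = runif(1, 10, 1000),
      attrition_rate = runif(1, 0, 0.2),
      participation_rate = runif(1, 0.5, 1),
      pipeline = education_pipeline(
        enrolment_by_year = setNames(runif(9, 0, 200),
                                     as.character(2019:2027)),
        dropout_rate = runif(1, 0, 0.3),
        training_duration = sample(0:2, 1),
        pass_rate = runif(1, 0.6, 1),
        immigration_by_year = setNames(runif(8, 0, 20),
                                       as.character(2021:2028))))
    got <- suppressWarnings(project_supply(cad, years))
    expect_equal(got$effective_supply_by_year, oracle_supply(cad, years),
                 tolerance = 1e-9)
  }
})

test_that("supply responds monotonically to attrition, inflow and participation", {
  set.seed(42)
  for (i in 1:10) {
    t0 <- runif(1, 50, 500)
    a <- runif(1, 0.02, 0.2)
    enrol <- setNames(runif(5, 10, 100), as.character(2021:2025))
    p <- runif(1, 0.5, 1)
    mk <- function(a., enrol., p.) {
      project_supply(cadre_profile(
        "c", t0, attrition_rate = a., participation_rate = p.,
        pipeline = education_pipeline(enrolment_by_year = enrol.)),
        2020:2025)$effective_supply_by_year
    }
    base <- mk(a, enrol, p)
    expect_true(all(mk(a + 0.05, enrol, p) <= base))
    expect_true(all(mk(a, enrol * 1.5, p) >= base))
    expect_true(all(mk(a, enrol, min(1, p + 0.1)) >= base))
  }
})

test_that("missing enrolment years are consolidated into one warning per projection", {
  cad <- cadre_profile("c", 100, attrition_rate = 0.05,
                       pipeline = education_pipeline(
                         enrolment_by_year = c(`2021` = 10)))
  w <- capture_warnings(project_supply(cad, 2020:2024))
  expect_length(w, 1)
  expect_match(w, "2022, 2023, 2024")
})
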