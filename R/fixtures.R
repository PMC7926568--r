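# Reference fixtures.
#
# The Ghana maternal-and-newborn-care application published with the model
# prints only its OUTPUT series (annual needs-based requirements, annual
# supply, wage bills, support-activity standards); the raw inputs behind
# them (population tables, indicator levels, enrolments) are not printed.
# ghana_printed_fixture() therefore embeds the printed outputs as fixed
# inputs for the gap/SAR/cost/growth operations, while the needs and supply
# engines are validated against synthetic known-answer scenarios whose full
# arithmetic is reproducible by hand.

#' Printed Ghana output series
#'
#' The published annual needs-based requirements and anticipated supply of
#' midwives and obstetrician/gynaecologists for 2020-2030, the
#' support-activity standards of both cadres, and the wage-bill components
#' for 2020/2025/2030, exactly as printed. Used as fixed inputs to the
#' integration operations (gaps, SAR, growth, cost aggregation); not an
#' output of this package's engines.
#'
#' @return a list with elements
#'   \describe{
#'     \item{need}{data frame `cadre_id`, `year`, `need` (persons);}
#'     \item{supply}{data frame `cadre_id`, `year`, `supply` (persons);}
#'     \item{support_activities}{named list, cadre_id -> named numeric
#'       vector of SAS proportions;}
#'     \item{costs}{data frame `cadre_id`, `year`, `cost_of_need`,
#'       `cost_of_supply` (US$).}
#'   }
#' @export
#' @examples
#' fx <- ghana_printed_fixture()
#' subset(fx$need, year == 2020)
ghana_printed_fixture <- function() {
  years <- 2020:2030
  mw <- "midwife"
  ob <- "obstetrician_gynaecologist"
  need <- rbind(
    data.frame(cadre_id = mw, year = years,
               need = c(16462, 16997, 17556, 18139, 18749, 19409,
                        20076, 20774, 21504, 22268, 23161)),
    data.frame(cadre_id = ob, year = years,
               need = c(723, 747, 772, 798, 825, 854,
                        883, 913, 945, 977, 1013))
  )
  supply <- rbind(
    data.frame(cadre_id = mw, year = years,
               supply = c(11930, 14057, 15878, 17438, 18775, 19919,
                          20900, 21739, 22459, 23075, 23602)),
    data.frame(cadre_id = ob, year = years,
               supply = c(189, 216, 242, 266, 290, 313,
                          335, 356, 377, 396, 415))
  )
  support <- list(
    midwife = c(handing_over = 0.125, clinical_meetings = 0.05),
    obstetrician_gynaecologist = c(clinical_meetings = 0.15)
  )
  costs <- rbind(
    data.frame(cadre_id = mw, year = c(2020, 2025, 2030),
               cost_of_need = c(176988192.56, 285949683.80, 433445908.15),
               cost_of_supply = c(118759613, 293467630, 441711580)),
    data.frame(cadre_id = ob, year = c(2020, 2025, 2030),
               cost_of_need = c(14278392.77, 23090373.91, 34820936.99),
               cost_of_supply = c(3454061, 11214559, 20921755))
  )
  list(need = need, supply = supply, support_activities = support,
       costs = costs)
}

#' Known-answer scenario
#'
#' A deliberately small scenario — 3 years, 2 population strata, 2
#' services, 1 cadre — whose entire projection is reproduced here by
#' straight-line arithmetic, independently of the engines. Used to pin the
#' engines to hand-checkable numbers.
#'
#' @return a list with `scenario` (a validated `hwf_scenario`) and
#'   `expected`, itself a list of named-by-year vectors: `h_a`, `h_b`
#'   (projected indicator levels), `volume_antenatal`, `volume_screening`
#'   (service volumes), `need_fte`, `registered_stock`, `supply_fte`,
#'   `need`, `supply` (rounded), `gap`, `sar`, `income`, `cost_of_need`,
#'   `cost_of_supply`.
#' @export
known_answer_scenario <- function() {
  years <- 2020:2022
  pop <- rbind(
    data.frame(age_cohort = "15-49", gender = "female", location = "all",
               year = years, count = c(100000, 110000, 120000)),
    data.frame(age_cohort = "50+", gender = "female", location = "all",
               year = years, count = c(50000, 50000, 50000))
  )
  scn <- scenario(
    name = "known-answer",
    base_year = 2020, horizon_end = 2022,
    population = pop,
    indicators = list(
      health_indicator("preg_rate", baseline_value = 0.2,
                       baseline_year = 2020, rate_of_change = 0.05,
                       age_cohort = "15-49"),
      health_indicator("screen_gap", baseline_value = 0.1,
                       baseline_year = 2020, rate_of_change = 0,
                       age_cohort = "50+")
    ),
    services = list(
      service_norm("antenatal", "preg_rate", frequency = 4,
                   service_standard = c(primary = 0.5, tertiary = 1.0),
                   work_division = c(midwife = 1)),
      service_norm("screening", "screen_gap", frequency = 2,
                   service_standard = 1.0,
                   work_division = c(midwife = 1))
    ),
    cadres = list(
      cadre_profile(
        "midwife", baseline_stock = 100, attrition_rate = 0.1,
        participation_rate = 0.9,
        awt = awt_components(260, 9, 21, 5, 4, 8), # 221 days x 8 h = 1768 h
        support_activities = list(support_activity("handover", 0.1)),
        pipeline = education_pipeline(
          enrolment_by_year = c(`2021` = 20, `2022` = 30),
          dropout_rate = 0.1, training_duration = 0, pass_rate = 0.9,
          immigration_by_year = c(`2021` = 5, `2022` = 5)),
        baseline_income = 10000, income_inflation = 0.05)
    ),
    practice_setting = "primary"
  )
  scn <- validate_scenario(scn)

  ## --- expected values, straight-line arithmetic, no engine calls ---
  yk <- as.character(years)
  nm <- function(x) stats::setNames(x, yk)
  # indicator paths: compounding at 5% and 0%
  h_a <- nm(c(0.2, 0.2 * 1.05, 0.2 * 1.05 * 1.05))
  h_b <- nm(c(0.1, 0.1, 0.1))
  # service volumes: population x level x frequency, stratum by stratum
  vol_a <- nm(c(100000 * 0.2 * 4,
                110000 * (0.2 * 1.05) * 4,
                120000 * (0.2 * 1.05 * 1.05) * 4))
  vol_b <- nm(c(50000 * 0.1 * 2, 50000 * 0.1 * 2, 50000 * 0.1 * 2))
  # standard workloads: AWT 1768 h over 0.5 h and 1.0 h standards
  sw_a <- 1768 / 0.5
  sw_b <- 1768 / 1.0
  saaf <- 1 / (1 - 0.1)
  need_fte <- nm((vol_a / sw_a + vol_b / sw_b) * saaf)
  # stock-and-flow: inflows (enrolment x 0.9 + immigration) x pass 0.9
  t0 <- 100
  t1 <- t0 * 0.9 + (20 * 0.9 + 5) * 0.9 # 90 + 20.7
  t2 <- t1 * 0.9 + (30 * 0.9 + 5) * 0.9 # 99.63 + 28.8
  stock <- nm(c(t0, t1, t2))
  supply_fte <- stock * 0.9
  need_r <- round_half_up(need_fte)
  supply_r <- round_half_up(supply_fte)
  income <- nm(10000 * 1.05^(0:2))
  list(
    scenario = scn,
    expected = list(
      h_a = h_a, h_b = h_b,
      volume_antenatal = vol_a, volume_screening = vol_b,
      need_fte = need_fte,
      registered_stock = stock,
      supply_fte = supply_fte,
      need = need_r, supply = supply_r,
      gap = supply_r - need_r,
      sar = supply_r / need_r,
      income = income,
      cost_of_need = need_r * income,
      cost_of_supply = supply_fte * income
    )
  )
}
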