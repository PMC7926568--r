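# Seeded synthetic scenario generator.
#
# Produces fully specified, valid-by-construction scenarios so every engine
# is testable with no external data. The generator emulates the shape of a
# national planning dataset — stratified population projections with smooth
# exponential growth, prevalence/coverage indicators with annual rates of
# change, WISN-style service norms with primary and tertiary activity
# standards, and cadres with absence calendars, support activities and
# education pipelines. It does not emulate survey noise, demographic shocks
# or behavioural supply responses: real data are messier than anything it
# emits.

#' Generate a synthetic planning scenario
#'
#' Deterministic under `seed`: two calls with identical arguments return
#' identical scenarios. The output always passes [validate_scenario()]
#' (sampling ranges are constrained so every invariant holds by
#' construction), covers at least two stratum dimensions (age x gender,
#' plus location when `n_locations > 1`), and — when `n_cadres >= 2` —
#' contains at least one service whose work division spans two cadres.
#'
#' @param seed integer seed for all sampling.
#' @param n_age_cohorts,n_locations number of age-cohort and location
#'   strata (both genders are always present).
#' @param n_services,n_cadres number of service norms and cadres.
#' @param base_year,horizon_end projection horizon (inclusive).
#' @param pop_size_range baseline persons per stratum (uniform).
#' @param pop_growth_range annual population growth rate per stratum.
#' @param h_baseline_range baseline indicator level (proportion in need).
#' @param rate_of_change_range annual indicator rate of change.
#' @param frequency_range services/person-in-need/year.
#' @param service_standard_range hours/service under the primary setting;
#'   the tertiary standard is 1.2-2x the primary one.
#' @param sas_range SAS proportion per support activity (each cadre draws
#'   0-2 activities; `2 * max < 1` is required so SAAF stays defined).
#' @param attrition_range,participation_range supply-side rates.
#' @param enrolment_range annual students enrolled.
#' @param dropout_range,pass_range pipeline rates.
#' @param income_range,inflation_range baseline income (currency/year) and
#'   annual income growth.
#' @return a validated `hwf_scenario`.
#' @export
#' @examples
#' scn <- generate_synthetic_scenario(seed = 42)
#' run_scenario(scn)
generate_synthetic_scenario <- function(
    seed = 1,
    n_age_cohorts = 3, n_locations = 2,
    n_services = 3, n_cadres = 2,
    base_year = 2020, horizon_end = 2025,
    pop_size_range = c(1000, 50000),
    pop_growth_range = c(-0.01, 0.03),
    h_baseline_range = c(0.05, 0.6),
    rate_of_change_range = c(-0.02, 0.05),
    frequency_range = c(0.5, 6),
    service_standard_range = c(0.25, 2),
    sas_range = c(0.02, 0.15),
    attrition_range = c(0.02, 0.08),
    participation_range = c(0.7, 1),
    enrolment_range = c(10, 500),
    dropout_range = c(0, 0.3),
    pass_range = c(0.7, 1),
    income_range = c(5000, 50000),
    inflation_range = c(0, 0.1)) {
  rng <- function(r, name, lo_ok = -Inf, hi_ok = Inf) {
    if (!is.numeric(r) || length(r) != 2L || r[1L] > r[2L] ||
        r[1L] < lo_ok || r[2L] > hi_ok) {
      stop(sprintf("infeasible range for `%s`", name), call. = FALSE)
    }
    r
  }
  rng(pop_size_range, "pop_size_range", 0)
  rng(pop_growth_range, "pop_growth_range", -1)
  rng(h_baseline_range, "h_baseline_range", 0, 1)
  rng(rate_of_change_range, "rate_of_change_range", -1)
  rng(frequency_range, "frequency_range", 0)
  rng(service_standard_range, "service_standard_range")
  if (service_standard_range[1L] <= 0) {
    stop("infeasible range for `service_standard_range`", call. = FALSE)
  }
  rng(sas_range, "sas_range", 0, 1)
  if (2 * sas_range[2L] >= 1) {
    stop("infeasible range for `sas_range`: 2 * max must stay below 1",
         call. = FALSE)
  }
  rng(attrition_range, "attrition_range", 0, 1 - 1e-9)
  rng(participation_range, "participation_range", 1e-9, 1)
  rng(enrolment_range, "enrolment_range", 0)
  rng(dropout_range, "dropout_range", 0, 1)
  rng(pass_range, "pass_range", 1e-9, 1)
  rng(income_range, "income_range", 0)
  rng(inflation_range, "inflation_range", -1)
  if (base_year > horizon_end) {
    stop("`base_year` must not exceed `horizon_end`", call. = FALSE)
  }

  set.seed(as.integer(seed))
  years <- base_year:horizon_end
  runif1 <- function(r, n = 1L) stats::runif(n, r[1L], r[2L])

  cohorts <- paste0("age_", seq_len(n_age_cohorts))
  genders <- c("female", "male")
  locations <- if (n_locations == 1L) "all" else
    paste0("loc_", seq_len(n_locations))

  pop <- do.call(rbind, lapply(cohorts, function(ac) {
    do.call(rbind, lapply(genders, function(g) {
      do.call(rbind, lapply(locations, function(loc) {
        base_n <- runif1(pop_size_range)
        growth <- runif1(pop_growth_range)
        data.frame(age_cohort = ac, gender = g, location = loc,
                   year = years,
                   count = base_n * (1 + growth)^(years - base_year))
      }))
    }))
  }))

  cadre_names <- paste0("cadre_", letters[seq_len(n_cadres)])
  indicators <- vector("list", n_services)
  services <- vector("list", n_services)
  for (i in seq_len(n_services)) {
    ind_id <- paste0("indicator_", i)
    # selectors exercise the stratum dimensions: sometimes a specific
    # cohort, sometimes a specific gender; location left composite
    sel_cohort <- if (stats::runif(1) < 0.5) sample(cohorts, 1L) else NULL
    sel_gender <- if (stats::runif(1) < 0.5) sample(genders, 1L) else NULL
    indicators[[i]] <- health_indicator(
      ind_id,
      baseline_value = runif1(h_baseline_range),
      baseline_year = base_year,
      rate_of_change = runif1(rate_of_change_range),
      age_cohort = sel_cohort, gender = sel_gender)
    ss_primary <- runif1(service_standard_range)
    ss <- c(primary = ss_primary,
            tertiary = ss_primary * stats::runif(1, 1.2, 2))
    # round-robin primary cadre; service 1 always splits across two
    # cadres when possible
    lead <- cadre_names[(i - 1L) %% n_cadres + 1L]
    if (n_cadres >= 2L && (i == 1L || stats::runif(1) < 0.5)) {
      partner <- sample(setdiff(cadre_names, lead), 1L)
      w_lead <- stats::runif(1, 0.3, 0.7)
      wd <- stats::setNames(c(w_lead, 1 - w_lead), c(lead, partner))
    } else {
      wd <- stats::setNames(1, lead)
    }
    services[[i]] <- service_norm(
      paste0("service_", i), ind_id,
      frequency = runif1(frequency_range),
      service_standard = ss, work_division = wd)
  }
  # every cadre must share in at least one service
  covered <- unique(unlist(lapply(services, function(s) names(s$work_division))))
  for (cid in setdiff(cadre_names, covered)) {
    j <- sample(n_services, 1L)
    wd <- services[[j]]$work_division
    w_new <- stats::runif(1, 0.2, 0.5)
    wd <- c(wd * (1 - w_new), stats::setNames(w_new, cid))
    services[[j]]$work_division <- wd
  }

  cadres <- lapply(cadre_names, function(cid) {
    n_support <- sample(0:2, 1L)
    support <- if (n_support > 0L) {
      lapply(seq_len(n_support), function(k) {
        support_activity(paste0(cid, "_support_", k), runif1(sas_range))
      })
    } else {
      list()
    }
    duration <- sample(0:2, 1L)
    enrol_years <- (base_year + 1L - duration):(horizon_end - duration)
    enrol <- stats::setNames(runif1(enrolment_range, length(enrol_years)),
                             as.character(enrol_years))
    imm <- stats::setNames(stats::runif(length(years) - 1L, 0, 20),
                           as.character(years[-1L]))
    cadre_profile(
      cid,
      baseline_stock = stats::runif(1, 50, 2000),
      attrition_rate = runif1(attrition_range),
      participation_rate = runif1(participation_range),
      awt = awt_components(
        possible_working_days = 260,
        public_holidays = stats::runif(1, 5, 15),
        annual_leave = stats::runif(1, 15, 30),
        sick_leave = stats::runif(1, 3, 10),
        other_absences = stats::runif(1, 0, 5),
        hours_per_day = 8),
      support_activities = support,
      pipeline = education_pipeline(
        enrolment_by_year = enrol,
        dropout_rate = runif1(dropout_range),
        training_duration = duration,
        pass_rate = runif1(pass_range),
        immigration_by_year = imm),
      baseline_income = runif1(income_range),
      income_inflation = runif1(inflation_range))
  })

  validate_scenario(scenario(
    name = sprintf("synthetic-seed-%d", as.integer(seed)),
    base_year = base_year, horizon_end = horizon_end,
    population = pop, indicators = indicators, services = services,
    cadres = cadres, practice_setting = "primary"))
}
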