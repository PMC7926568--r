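# Independent oracles: plain-loop / closed-form arithmetic written without
# reference to the engine code paths they check.

# Needs-based FTE for one cadre-year by explicit per-stratum, per-service
# loops.
oracle_need_fte <- function(scn, cadre_id, year) {
  cad <- NULL
  for (cc in scn$cadres) if (cc$cadre_id == cadre_id) cad <- cc
  awt_days <- cad$awt$possible_working_days - cad$awt$public_holidays -
    cad$awt$annual_leave - cad$awt$sick_leave - cad$awt$other_absences
  awt <- awt_days * cad$awt$hours_per_day
  total <- 0
  for (svc in scn$services) {
    if (!cadre_id %in% names(svc$work_division)) next
    ind <- NULL
    for (ii in scn$indicators) {
      if (ii$indicator_id == svc$indicator_id) ind <- ii
    }
    if (!is.null(ind$rate_of_change)) {
      r <- ind$rate_of_change
    } else {
      dt <- ind$second_year - ind$baseline_year
      r <- if (ind$rate_method == "continuous") {
        log(ind$second_value / ind$baseline_value) / dt
      } else {
        (ind$second_value / ind$baseline_value)^(1 / dt) - 1
      }
    }
    h <- ind$baseline_value
    if (scn$apply_rate_of_change) {
      y <- ind$baseline_year
      while (y < year) {
        y <- y + 1
        h <- min(1, max(0, h * (1 + r)))
      }
    }
    vol <- 0
    for (i in seq_len(nrow(scn$population))) {
      row <- scn$population[i, ]
      if (row$year != year) next
      if (!is.null(ind$age_cohort) &&
          !(row$age_cohort %in% ind$age_cohort)) next
      if (!is.null(ind$gender) && !(row$gender %in% ind$gender)) next
      if (!is.null(ind$location) && !(row$location %in% ind$location)) next
      vol <- vol + row$count * h * svc$frequency
    }
    ss <- svc$service_standard
    ssv <- if (length(ss) == 1 && is.null(names(ss))) {
      ss
    } else {
      ss[[scn$practice_setting]]
    }
    total <- total + vol * svc$work_division[[cadre_id]] / (awt / ssv)
  }
  if (scn$apply_support_adjustment) {
    s <- 0
    for (sa in cad$support_activities) s <- s + sa$sas
    total <- total / (1 - s)
  }
  total
}

# Effective supply by the closed-form geometric-decay sum
# T_t = T0 (1-a)^t + sum_k I_k (1-a)^(t-k), rather than the recursion.
oracle_supply <- function(cadre, years) {
  base <- years[1]
  a <- cadre$attrition_rate
  inflow_at <- function(y) {
    pl <- cadre$pipeline
    key <- as.character(y - pl$training_duration)
    enrol <- if (key %in% names(pl$enrolment_by_year)) {
      pl$enrolment_by_year[[key]]
    } else {
      0
    }
    imm_key <- as.character(y)
    imm <- if (imm_key %in% names(pl$immigration_by_year)) {
      pl$immigration_by_year[[imm_key]]
    } else {
      0
    }
    (enrol * (1 - pl$dropout_rate) + imm) * pl$pass_rate
  }
  out <- vapply(years, function(y) {
    t <- y - base
    stock <- cadre$baseline_stock * (1 - a)^t
    if (t > 0) {
      for (k in seq_len(t)) {
        stock <- stock + inflow_at(base + k) * (1 - a)^(t - k)
      }
    }
    stock * cadre$participation_rate
  }, numeric(1))
  stats::setNames(out, as.character(years))
}

# Small scenario builder used across tests: one cadre, hand-settable
# population/indicator/service parameters.
tiny_scenario <- function(strata_counts, h = 0.1, rate = 0, freq = 4,
                          ss = 0.5, years = 2020:2022, sas = numeric(0),
                          awt = awt_components(260, 9, 21, 5, 4, 8),
                          apply_rate = TRUE, apply_support = TRUE) {
  pop <- do.call(rbind, lapply(seq_along(strata_counts), function(i) {
    data.frame(age_cohort = paste0("a", i), gender = "female",
               location = "all", year = years,
               count = rep(strata_counts[i], length(years)))
  }))
  support <- lapply(seq_along(sas), function(i) {
    support_activity(paste0("s", i), sas[i])
  })
  validate_scenario(scenario(
    name = "tiny", base_year = min(years), horizon_end = max(years),
    population = pop,
    indicators = list(health_indicator("ind", baseline_value = h,
                                       baseline_year = min(years),
                                       rate_of_change = rate)),
    services = list(service_norm("svc", "ind", frequency = freq,
                                 service_standard = ss,
                                 work_division = c(worker = 1))),
    cadres = list(cadre_profile("worker", baseline_stock = 10,
                                awt = awt, support_activities = support)),
    apply_rate_of_change = apply_rate,
    apply_support_adjustment = apply_support))
}
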