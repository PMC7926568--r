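# Needs-side engine: evidence-based service requirements and their
# translation into workforce requirements.
#
# Need for services in year t is the sum over population strata of
#   P (stratum size) x H_t (proportion in need) x L (services/person/year),
# with H_t compounded annually from its baseline at rate R. Dividing the
# cadre's share of each service volume by the standard workload
# (AWT / service standard) and inflating by the support-activities
# adjustment factor yields the needs-based FTE requirement.

#' Estimate the annual rate of change of a health indicator
#'
#' Given the indicator's level at two time points (typically two survey
#' waves), returns the annual rate at which it has been changing.
#'
#' @param value_1,value_2 indicator levels (proportions in `(0, 1]`) at
#'   `year_1` and `year_2`.
#' @param year_1,year_2 calendar years, `year_2 > year_1`.
#' @param method `"geometric"` solves `value_1 * (1 + r)^dt = value_2`
#'   (consistent with the discrete annual compounding the projection
#'   applies); `"continuous"` returns `log(value_2/value_1)/dt`, the
#'   instantaneous exponential rate. Geometric is the default.
#' @return signed annual rate; its sign reflects the direction of change.
#' @export
#' @examples
#' estimate_rate_of_change(0.10, 2007, 0.20, 2017) # doubling over a decade
estimate_rate_of_change <- function(value_1, year_1, value_2, year_2,
                                    method = c("geometric", "continuous")) {
  method <- match.arg(method)
  assert_scalar_num(value_1, "value_1")
  assert_scalar_num(value_2, "value_2")
  assert_scalar_num(year_1, "year_1")
  assert_scalar_num(year_2, "year_2")
  if (year_2 <= year_1) {
    stop("`year_2` must be after `year_1`", call. = FALSE)
  }
  if (value_1 <= 0) {
    stop("rate of change undefined for a zero/negative starting value",
         call. = FALSE)
  }
  if (value_2 < 0) stop("`value_2` must be non-negative", call. = FALSE)
  dt <- year_2 - year_1
  switch(method,
         geometric = (value_2 / value_1)^(1 / dt) - 1,
         continuous = log(value_2 / value_1) / dt)
}

# Internal: the indicator's annual rate — as given, or estimated from the
# two observations using the indicator's own method.
resolve_rate <- function(indicator) {
  if (!is.null(indicator$rate_of_change)) return(indicator$rate_of_change)
  estimate_rate_of_change(indicator$baseline_value, indicator$baseline_year,
                          indicator$second_value, indicator$second_year,
                          method = indicator$rate_method)
}

#' Project a health indicator over a year range
#'
#' Compounds the indicator annually from its baseline:
#' `H_t = H_{t-1} * (1 + R)`, clamped to `[0, 1]` each year (the indicator
#' is a proportion). With `apply_rate = FALSE` the baseline level is held
#' constant — the "constant level of health" assumption of earlier
#' needs-based models.
#'
#' @param indicator a [health_indicator()].
#' @param years integer vector of calendar years, none earlier than the
#'   indicator's `baseline_year`.
#' @param apply_rate apply the annual rate of change? Default `TRUE`.
#' @return named numeric vector, year -> projected proportion.
#' @export
project_health_status <- function(indicator, years, apply_rate = TRUE) {
  years <- as.integer(years)
  if (!isTRUE(apply_rate)) {
    return(stats::setNames(rep(indicator$baseline_value, length(years)),
                           as.character(years)))
  }
  if (any(years < indicator$baseline_year)) {
    stop(sprintf("cannot project indicator '%s' before its baseline year %d",
                 indicator$indicator_id, indicator$baseline_year),
         call. = FALSE)
  }
  rate <- resolve_rate(indicator)
  max_year <- max(years)
  h <- clamp(indicator$baseline_value)
  path <- stats::setNames(numeric(max_year - indicator$baseline_year + 1L),
                          as.character(indicator$baseline_year:max_year))
  path[1L] <- h
  yr <- indicator$baseline_year
  while (yr < max_year) {
    yr <- yr + 1L
    h <- clamp(h * (1 + rate))
    path[as.character(yr)] <- h
  }
  path[as.character(years)]
}

#' Evidence-based need for one service in one year
#'
#' Sums, over the population strata matched by the driving indicator's
#' selector, stratum size x projected proportion in need x service
#' frequency.
#'
#' @param scn a validated scenario.
#' @param service a [service_norm()] or a service_id present in the
#'   scenario.
#' @param year calendar year within the scenario horizon.
#' @return services/year (non-negative).
#' @export
compute_service_need <- function(scn, service, year) {
  assert_validated(scn)
  if (is.character(service)) service <- get_service(scn, service)
  indicator <- get_indicator(scn, service$indicator_id)
  h <- project_health_status(indicator, year,
                             apply_rate = scn$apply_rate_of_change)
  strata <- match_strata(scn, indicator)
  rows <- strata[strata$year == as.integer(year), , drop = FALSE]
  sum(rows$count * h * service$frequency)
}

#' Available working time
#'
#' Annual hours a professional is available for work after all absences:
#' `(possible_working_days - public_holidays - annual_leave - sick_leave -
#' other_absences) * hours_per_day`.
#'
#' @param components an [awt_components()] object.
#' @return hours/year.
#' @export
#' @examples
#' compute_awt(awt_components(260, 9, 21, 5, 4, 8)) # 221 days x 8 h = 1768
compute_awt <- function(components) {
  if (!inherits(components, "hwf_awt")) {
    stop("`components` must be awt_components()", call. = FALSE)
  }
  days <- components$possible_working_days - components$public_holidays -
    components$annual_leave - components$sick_leave -
    components$other_absences
  if (days <= 0) {
    stop(sprintf("available working days = %g; absences exceed the calendar",
                 days), call. = FALSE)
  }
  days * components$hours_per_day
}

#' Standard workload
#'
#' Annual units of one service a professional could deliver working on it
#' exclusively: available working time divided by the service standard.
#'
#' @param awt available working time, hours/year (positive).
#' @param service_standard hours per service (positive).
#' @return services/person/year.
#' @export
#' @examples
#' compute_standard_workload(1768, 0.5) # 3536 services a year
compute_standard_workload <- function(awt, service_standard) {
  assert_scalar_num(awt, "awt")
  assert_scalar_num(service_standard, "service_standard")
  if (awt <= 0) stop("`awt` must be > 0", call. = FALSE)
  if (service_standard <= 0) {
    stop("`service_standard` must be > 0", call. = FALSE)
  }
  awt / service_standard
}

#' Support-activities adjustment factor
#'
#' `SAAF = 1 / (1 - sum(SAS))`: the factor by which direct-care workforce
#' requirements are inflated so the planned headcount also covers indirect
#' (non-countable) activities such as handovers and clinical meetings.
#' Always >= 1; equals 1 when there are no support activities.
#'
#' @param support_activities list of [support_activity()] objects, or a
#'   bare numeric vector of SAS proportions.
#' @return adjustment factor >= 1.
#' @export
#' @examples
#' compute_saaf(c(0.125, 0.05)) # 1.2121...: a 21.2% upward adjustment
compute_saaf <- function(support_activities) {
  sas <- if (is.numeric(support_activities)) {
    support_activities
  } else {
    vapply(support_activities, `[[`, numeric(1), "sas")
  }
  if (any(sas < 0)) stop("SAS proportions must be >= 0", call. = FALSE)
  total <- sum(sas)
  if (total >= 1) {
    stop(sprintf("sum of SAS = %g >= 1: no time left for direct care",
                 total), call. = FALSE)
  }
  1 / (1 - total)
}

# Internal: the service standard that applies under the scenario's practice
# setting.
select_service_standard <- function(service, practice_setting) {
  ss <- service$service_standard
  if (length(ss) == 1L && is.null(names(ss))) return(unname(ss))
  if (!is.null(names(ss)) && practice_setting %in% names(ss)) {
    return(unname(ss[[practice_setting]]))
  }
  if (length(ss) == 1L) return(unname(ss[[1L]]))
  stop(sprintf("service '%s' has no service_standard for setting '%s'",
               service$service_id, practice_setting), call. = FALSE)
}

#' Needs-based workforce requirement for one cadre in one year
#'
#' For each service the cadre shares in, takes the cadre's work-division
#' share of the service volume and divides by the cadre's standard workload
#' for that service; the sum over services is then multiplied by the cadre's
#' support-activities adjustment factor (unless the scenario disables the
#' adjustment).
#'
#' @param scn a validated scenario.
#' @param cadre_id cadre label.
#' @param year calendar year within the horizon.
#' @return required full-time equivalents (real-valued; rounding to whole
#'   persons happens only at gap/reporting stage).
#' @export
compute_workforce_requirement <- function(scn, cadre_id, year) {
  assert_validated(scn)
  cadre <- get_cadre(scn, cadre_id)
  awt <- compute_awt(cadre$awt)
  fte <- 0
  involved <- FALSE
  for (svc in scn$services) {
    if (!cadre_id %in% names(svc$work_division)) next
    w <- svc$work_division[[cadre_id]]
    if (w == 0) next
    involved <- TRUE
    volume <- compute_service_need(scn, svc, year)
    ss <- select_service_standard(svc, scn$practice_setting)
    sw <- compute_standard_workload(awt, ss)
    fte <- fte + volume * w / sw
  }
  if (!involved) {
    warning(sprintf("cadre '%s' shares in no service; requirement is 0",
                    cadre_id), call. = FALSE)
    return(0)
  }
  if (scn$apply_support_adjustment) {
    fte <- fte * compute_saaf(cadre$support_activities)
  }
  fte
}
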