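# Scenario domain types.
#
# A scenario is a closed, self-consistent description of one planning world:
# the projected population by stratum, the health-status indicators that
# drive service need, the service norms that translate need into countable
# activities, and the cadre profiles that supply the workforce. Every engine
# reads from a validated scenario and nothing else.

#' Health-status indicator
#'
#' A stratified measure of the proportion of a population stratum in need of
#' a service (a disease prevalence, a coverage gap, a risk-factor rate).
#' The annual rate of change is either supplied directly or estimated from a
#' second observation (e.g. two survey waves) via
#' [estimate_rate_of_change()].
#'
#' @param indicator_id unique label.
#' @param baseline_value proportion in `[0, 1]` observed at `baseline_year`.
#' @param baseline_year calendar year of the baseline observation.
#' @param second_value,second_year optional second observation used to
#'   estimate the annual rate of change. Exactly one of `rate_of_change` or
#'   the second observation must be given.
#' @param rate_of_change optional signed annual rate, applied by discrete
#'   compounding.
#' @param age_cohort,gender,location optional stratum selectors; `NULL` (or
#'   `"all"`) matches every level of that dimension. Matching is by exact
#'   label against the scenario's population strata.
#' @param rate_method `"geometric"` (default) or `"continuous"`; how the rate
#'   is estimated from two observations when `rate_of_change` is not given.
#' @return an object of class `hwf_indicator`.
#' @seealso [project_health_status()]
#' @export
health_indicator <- function(indicator_id, baseline_value, baseline_year,
                             second_value = NULL, second_year = NULL,
                             rate_of_change = NULL,
                             age_cohort = NULL, gender = NULL, location = NULL,
                             rate_method = c("geometric", "continuous")) {
  assert_scalar_chr(indicator_id, "indicator_id")
  assert_scalar_num(baseline_value, "baseline_value")
  assert_scalar_num(baseline_year, "baseline_year")
  rate_method <- match.arg(rate_method)
  norm_sel <- function(x) {
    if (is.null(x) || identical(x, "all")) NULL else as.character(x)
  }
  structure(
    list(
      indicator_id = indicator_id,
      baseline_value = as.numeric(baseline_value),
      baseline_year = as.integer(baseline_year),
      second_value = if (is.null(second_value)) NULL else as.numeric(second_value),
      second_year = if (is.null(second_year)) NULL else as.integer(second_year),
      rate_of_change = if (is.null(rate_of_change)) NULL else as.numeric(rate_of_change),
      age_cohort = norm_sel(age_cohort),
      gender = norm_sel(gender),
      location = norm_sel(location),
      rate_method = rate_method
    ),
    class = "hwf_indicator"
  )
}

#' Service norm
#'
#' One countable service activity, driven by a health indicator: every person
#' in need receives `frequency` services per year, each taking
#' `service_standard` hours of professional time, split across cadres by
#' `work_division`.
#'
#' @param service_id unique label.
#' @param indicator_id label of the driving [health_indicator()].
#' @param frequency services per person in need per year (non-negative).
#' @param service_standard hours per service (positive). Either a single
#'   value, or a named vector keyed by practice setting (e.g.
#'   `c(primary = 0.5, tertiary = 0.75)`); the scenario's `practice_setting`
#'   selects which applies.
#' @param work_division named numeric vector, cadre_id -> proportion of the
#'   service volume performed by that cadre; must sum to 1.
#' @return an object of class `hwf_service_norm`.
#' @export
service_norm <- function(service_id, indicator_id, frequency,
                         service_standard, work_division) {
  assert_scalar_chr(service_id, "service_id")
  assert_scalar_chr(indicator_id, "indicator_id")
  assert_scalar_num(frequency, "frequency")
  if (!is.numeric(service_standard) || length(service_standard) < 1L) {
    stop("`service_standard` must be numeric (scalar or named by setting)",
         call. = FALSE)
  }
  if (!is.numeric(work_division) || is.null(names(work_division)) ||
      any(!nzchar(names(work_division)))) {
    stop("`work_division` must be a named numeric vector (cadre_id -> share)",
         call. = FALSE)
  }
  structure(
    list(
      service_id = service_id,
      indicator_id = indicator_id,
      frequency = as.numeric(frequency),
      service_standard = service_standard,
      work_division = work_division
    ),
    class = "hwf_service_norm"
  )
}

#' Available-working-time components
#'
#' The annual absence calendar of a cadre, from which available working time
#' (AWT, hours/year) is derived as
#' `(possible_working_days - holidays - leave - absences) * hours_per_day`.
#'
#' @param possible_working_days working days in the year before absences.
#' @param public_holidays,annual_leave,sick_leave,other_absences days/year.
#' @param hours_per_day contracted hours per working day.
#' @return an object of class `hwf_awt`.
#' @seealso [compute_awt()]
#' @export
awt_components <- function(possible_working_days = 260, public_holidays = 0,
                           annual_leave = 0, sick_leave = 0,
                           other_absences = 0, hours_per_day = 8) {
  vals <- c(possible_working_days = possible_working_days,
            public_holidays = public_holidays, annual_leave = annual_leave,
            sick_leave = sick_leave, other_absences = other_absences,
            hours_per_day = hours_per_day)
  for (nm in names(vals)) assert_scalar_num(vals[[nm]], nm)
  structure(as.list(vals), class = "hwf_awt")
}

#' Support activity
#'
#' One indirect (non-countable) activity of a cadre — handovers, unit
#' meetings, reporting — expressed as a support allowance standard (SAS):
#' the fraction of available working time it consumes.
#'
#' @param name label.
#' @param sas proportion of AWT in `[0, 1)`.
#' @return an object of class `hwf_support_activity`.
#' @seealso [compute_saaf()]
#' @export
support_activity <- function(name, sas) {
  assert_scalar_chr(name, "name")
  assert_scalar_num(sas, "sas")
  structure(list(name = name, sas = as.numeric(sas)),
            class = "hwf_support_activity")
}

#' Education pipeline
#'
#' The domestic training pathway of a cadre plus immigration. The inflow in
#' year `t` is `(enrolment[t - training_duration] * (1 - dropout_rate) +
#' immigration[t]) * pass_rate`.
#'
#' @param enrolment_by_year named numeric vector, year -> students enrolled.
#'   May be empty for a cadre with no domestic pipeline.
#' @param dropout_rate proportion of each intake cohort lost before
#'   graduation, in `[0, 1]`.
#' @param training_duration whole years from enrolment to graduation; `0`
#'   means the enrolment series is already expressed as annual output.
#' @param pass_rate licensure-examination pass rate in `(0, 1]`, applied to
#'   graduates and immigrants alike.
#' @param immigration_by_year named numeric vector, year -> immigrating
#'   professionals (before licensure adjustment).
#' @return an object of class `hwf_pipeline`.
#' @seealso [compute_pipeline_inflow()]
#' @export
education_pipeline <- function(enrolment_by_year = NULL, dropout_rate = 0,
                               training_duration = 0, pass_rate = 1,
                               immigration_by_year = NULL) {
  assert_scalar_num(dropout_rate, "dropout_rate")
  assert_scalar_num(training_duration, "training_duration")
  assert_scalar_num(pass_rate, "pass_rate")
  structure(
    list(
      enrolment_by_year = as_year_map(enrolment_by_year, "enrolment_by_year"),
      dropout_rate = as.numeric(dropout_rate),
      training_duration = as.integer(training_duration),
      pass_rate = as.numeric(pass_rate),
      immigration_by_year = as_year_map(immigration_by_year,
                                        "immigration_by_year")
    ),
    class = "hwf_pipeline"
  )
}

#' Cadre profile
#'
#' All supply-side, productivity and income parameters of one health
#' professional category.
#'
#' @param cadre_id unique label.
#' @param baseline_stock registered stock at the scenario base year.
#' @param attrition_rate annual proportion of the registered stock lost to
#'   death, retirement, ill health and out-migration, in `[0, 1)`.
#' @param participation_rate proportion of the registered stock engaged in
#'   direct service delivery, in `(0, 1]`.
#' @param awt an [awt_components()] object.
#' @param support_activities list of [support_activity()] objects; their SAS
#'   values must sum to less than 1.
#' @param pipeline an [education_pipeline()] object.
#' @param baseline_income average annual income (salary, allowances,
#'   monetary benefits) per person at the base year, in scenario currency.
#' @param income_inflation annual income growth rate applied by compounding.
#' @return an object of class `hwf_cadre`.
#' @export
cadre_profile <- function(cadre_id, baseline_stock, attrition_rate = 0,
                          participation_rate = 1,
                          awt = awt_components(),
                          support_activities = list(),
                          pipeline = education_pipeline(),
                          baseline_income = 0, income_inflation = 0) {
  assert_scalar_chr(cadre_id, "cadre_id")
  assert_scalar_num(baseline_stock, "baseline_stock")
  assert_scalar_num(attrition_rate, "attrition_rate")
  assert_scalar_num(participation_rate, "participation_rate")
  if (!inherits(awt, "hwf_awt")) stop("`awt` must be awt_components()",
                                      call. = FALSE)
  if (!inherits(pipeline, "hwf_pipeline")) {
    stop("`pipeline` must be education_pipeline()", call. = FALSE)
  }
  if (!is.list(support_activities) ||
      !all(vapply(support_activities, inherits, logical(1),
                  "hwf_support_activity"))) {
    stop("`support_activities` must be a list of support_activity()",
         call. = FALSE)
  }
  structure(
    list(
      cadre_id = cadre_id,
      baseline_stock = as.numeric(baseline_stock),
      attrition_rate = as.numeric(attrition_rate),
      participation_rate = as.numeric(participation_rate),
      awt = awt,
      support_activities = support_activities,
      pipeline = pipeline,
      baseline_income = as.numeric(baseline_income),
      income_inflation = as.numeric(income_inflation)
    ),
    class = "hwf_cadre"
  )
}

#' Assemble a planning scenario
#'
#' @param name scenario label.
#' @param base_year first projection year.
#' @param horizon_end last projection year (inclusive).
#' @param population data frame with columns `age_cohort`, `gender`,
#'   `location`, `year`, `count`: the projected population of every stratum
#'   for every year of the horizon. Strata are free-form labels; a location
#'   of `"all"` conventionally denotes a composite (non-disaggregated)
#'   analysis.
#' @param indicators list of [health_indicator()] objects.
#' @param services list of [service_norm()] objects.
#' @param cadres list of [cadre_profile()] objects.
#' @param practice_setting label selecting which `service_standard` variant
#'   applies when a service carries several (e.g. `"primary"` vs
#'   `"tertiary"`).
#' @param apply_rate_of_change if `FALSE`, health indicators are held at
#'   their baseline value over the whole horizon (the "constant level of
#'   health" assumption of earlier needs-based models).
#' @param apply_support_adjustment if `FALSE`, workforce requirements cover
#'   direct care only (no SAAF inflation).
#' @return an unvalidated object of class `hwf_scenario`; pass it through
#'   [validate_scenario()] before projecting.
#' @seealso [validate_scenario()], [run_scenario()]
#' @export
scenario <- function(name, base_year, horizon_end, population,
                     indicators, services, cadres,
                     practice_setting = "primary",
                     apply_rate_of_change = TRUE,
                     apply_support_adjustment = TRUE) {
  assert_scalar_chr(name, "name")
  assert_scalar_num(base_year, "base_year")
  assert_scalar_num(horizon_end, "horizon_end")
  if (!is.data.frame(population)) {
    stop("`population` must be a data frame", call. = FALSE)
  }
  needed <- c("age_cohort", "gender", "location", "year", "count")
  missing_cols <- setdiff(needed, names(population))
  if (length(missing_cols)) {
    stop("`population` is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  population <- as.data.frame(population)[needed]
  population$age_cohort <- as.character(population$age_cohort)
  population$gender <- as.character(population$gender)
  population$location <- as.character(population$location)
  population$year <- as.integer(population$year)
  population$count <- as.numeric(population$count)
  chk_list <- function(x, cls, nm) {
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), cls))) {
      stop(sprintf("`%s` must be a list of %s objects", nm, cls),
           call. = FALSE)
    }
    x
  }
  structure(
    list(
      name = name,
      base_year = as.integer(base_year),
      horizon_end = as.integer(horizon_end),
      population = population,
      indicators = chk_list(indicators, "hwf_indicator", "indicators"),
      services = chk_list(services, "hwf_service_norm", "services"),
      cadres = chk_list(cadres, "hwf_cadre", "cadres"),
      practice_setting = practice_setting,
      apply_rate_of_change = isTRUE(apply_rate_of_change),
      apply_support_adjustment = isTRUE(apply_support_adjustment)
    ),
    class = "hwf_scenario"
  )
}

#' @export
print.hwf_scenario <- function(x, ...) {
  strata <- unique(x$population[c("age_cohort", "gender", "location")])
  cat("<hwf_scenario> ", x$name, "\n", sep = "")
  cat("  horizon: ", x$base_year, "-", x$horizon_end,
      " (", x$horizon_end - x$base_year + 1L, " years)\n", sep = "")
  cat("  population strata: ", nrow(strata),
      " | indicators: ", length(x$indicators),
      " | services: ", length(x$services),
      " | cadres: ", length(x$cadres), "\n", sep = "")
  cat("  practice setting: ", x$practice_setting,
      " | rate of change: ", x$apply_rate_of_change,
      " | support adjustment: ", x$apply_support_adjustment, "\n", sep = "")
  if (isTRUE(attr(x, "validated"))) cat("  validated\n")
  invisible(x)
}

scenario_years <- function(scn) seq.int(scn$base_year, scn$horizon_end)

find_by_id <- function(items, field, id) {
  for (it in items) if (identical(it[[field]], id)) return(it)
  NULL
}

get_indicator <- function(scn, indicator_id) {
  ind <- find_by_id(scn$indicators, "indicator_id", indicator_id)
  if (is.null(ind)) {
    stop(sprintf("unknown indicator '%s'", indicator_id), call. = FALSE)
  }
  ind
}

get_service <- function(scn, service_id) {
  svc <- find_by_id(scn$services, "service_id", service_id)
  if (is.null(svc)) {
    stop(sprintf("unknown service '%s'", service_id), call. = FALSE)
  }
  svc
}

get_cadre <- function(scn, cadre_id) {
  cad <- find_by_id(scn$cadres, "cadre_id", cadre_id)
  if (is.null(cad)) {
    stop(sprintf("unknown cadre '%s'", cadre_id), call. = FALSE)
  }
  cad
}

cadre_ids <- function(scn) {
  vapply(scn$cadres, `[[`, character(1), "cadre_id")
}

# Rows of scn$population matched by an indicator's stratum selector.
match_strata <- function(scn, indicator) {
  pop <- scn$population
  keep <- rep(TRUE, nrow(pop))
  if (!is.null(indicator$age_cohort)) {
    keep <- keep & pop$age_cohort %in% indicator$age_cohort
  }
  if (!is.null(indicator$gender)) keep <- keep & pop$gender %in% indicator$gender
  if (!is.null(indicator$location)) {
    keep <- keep & pop$location %in% indicator$location
  }
  pop[keep, , drop = FALSE]
}

#' List the invariant violations of a scenario
#'
#' Checks every domain invariant — dense population series over the horizon,
#' non-negative counts, indicator rate specification and ranges, work
#' divisions summing to 1, positive service standards, referential integrity
#' of indicator and cadre labels, SAS sums below 1, positive available
#' working time, rate ranges — and reports each violation with the path of
#' the offending parameter.
#'
#' @param scn an `hwf_scenario`.
#' @return character vector of violation messages; empty when the scenario
#'   is valid. Each message starts with the parameter path, e.g.
#'   `services[anc].work_division`.
#' @seealso [validate_scenario()]
#' @export
scenario_violations <- function(scn) {
  if (!inherits(scn, "hwf_scenario")) {
    stop("`scn` must be an hwf_scenario", call. = FALSE)
  }
  v <- character(0)
  add <- function(path, msg) v <<- c(v, sprintf("%s: %s", path, msg))

  if (scn$base_year > scn$horizon_end) {
    add("horizon_end", sprintf("base_year %d > horizon_end %d",
                               scn$base_year, scn$horizon_end))
  }
  years <- if (scn$base_year <= scn$horizon_end) scenario_years(scn) else
    integer(0)

  ## population: dense years, non-negative counts
  pop <- scn$population
  if (nrow(pop) == 0L) {
    add("population", "no population strata defined")
  } else {
    key <- paste(pop$age_cohort, pop$gender, pop$location, sep = "|")
    for (k in unique(key)) {
      rows <- pop[key == k, , drop = FALSE]
      path <- sprintf("population[%s]", gsub("\\|", ",", k))
      miss <- setdiff(years, rows$year)
      if (length(miss)) {
        add(path, sprintf("missing counts for year(s) %s",
                          paste(miss, collapse = ", ")))
      }
      if (anyDuplicated(rows$year)) {
        add(path, "duplicated year entries")
      }
      bad <- rows$year[!is.na(rows$count) & rows$count < 0]
      if (length(bad)) {
        add(path, sprintf("negative count in year(s) %s",
                          paste(bad, collapse = ", ")))
      }
      if (anyNA(rows$count)) add(path, "missing (NA) counts")
    }
  }

  ## indicators
  ind_ids <- vapply(scn$indicators, `[[`, character(1), "indicator_id")
  if (anyDuplicated(ind_ids)) {
    add("indicators", sprintf("duplicated indicator_id(s): %s",
                              paste(unique(ind_ids[duplicated(ind_ids)]),
                                    collapse = ", ")))
  }
  for (ind in scn$indicators) {
    path <- sprintf("indicators[%s]", ind$indicator_id)
    has_rate <- !is.null(ind$rate_of_change)
    has_second <- !is.null(ind$second_value) && !is.null(ind$second_year)
    if (has_rate == has_second) {
      add(path, paste0("exactly one of rate_of_change or ",
                       "(second_value, second_year) must be supplied"))
    }
    if (ind$baseline_value < 0 || ind$baseline_value > 1) {
      add(paste0(path, ".baseline_value"),
          sprintf("%g outside [0, 1]", ind$baseline_value))
    }
    if (has_second) {
      if (ind$second_value < 0 || ind$second_value > 1) {
        add(paste0(path, ".second_value"),
            sprintf("%g outside [0, 1]", ind$second_value))
      }
      if (ind$second_year <= ind$baseline_year) {
        add(paste0(path, ".second_year"),
            sprintf("%d not after baseline_year %d",
                    ind$second_year, ind$baseline_year))
      }
    }
    if (nrow(match_strata(scn, ind)) == 0L && nrow(pop) > 0L) {
      add(path, "stratum selector matches no population stratum")
    }
  }

  ## services
  known_cadres <- cadre_ids(scn)
  svc_ids <- vapply(scn$services, `[[`, character(1), "service_id")
  if (anyDuplicated(svc_ids)) {
    add("services", sprintf("duplicated service_id(s): %s",
                            paste(unique(svc_ids[duplicated(svc_ids)]),
                                  collapse = ", ")))
  }
  for (svc in scn$services) {
    path <- sprintf("services[%s]", svc$service_id)
    if (!svc$indicator_id %in% ind_ids) {
      add(paste0(path, ".indicator_id"),
          sprintf("references unknown indicator '%s'", svc$indicator_id))
    }
    if (svc$frequency < 0) {
      add(paste0(path, ".frequency"), sprintf("%g < 0", svc$frequency))
    }
    if (any(svc$service_standard <= 0)) {
      add(paste0(path, ".service_standard"), "must be > 0")
    }
    ss <- svc$service_standard
    if (length(ss) > 1L && !scn$practice_setting %in% names(ss)) {
      add(paste0(path, ".service_standard"),
          sprintf("no value for practice setting '%s'", scn$practice_setting))
    }
    wsum <- sum(svc$work_division)
    if (abs(wsum - 1) > 1e-8) {
      add(paste0(path, ".work_division"),
          sprintf("sums to %g != 1", wsum))
    }
    if (any(svc$work_division < 0 | svc$work_division > 1)) {
      add(paste0(path, ".work_division"), "proportions outside [0, 1]")
    }
    unknown <- setdiff(names(svc$work_division), known_cadres)
    if (length(unknown)) {
      add(paste0(path, ".work_division"),
          sprintf("references unknown cadre(s): %s",
                  paste(unknown, collapse = ", ")))
    }
  }

  ## cadres
  if (anyDuplicated(known_cadres)) {
    add("cadres", sprintf("duplicated cadre_id(s): %s",
                          paste(unique(known_cadres[duplicated(known_cadres)]),
                                collapse = ", ")))
  }
  for (cad in scn$cadres) {
    path <- sprintf("cadres[%s]", cad$cadre_id)
    if (cad$baseline_stock < 0) {
      add(paste0(path, ".baseline_stock"),
          sprintf("%g < 0", cad$baseline_stock))
    }
    if (cad$attrition_rate < 0 || cad$attrition_rate >= 1) {
      add(paste0(path, ".attrition_rate"),
          sprintf("%g outside [0, 1)", cad$attrition_rate))
    }
    if (cad$participation_rate <= 0 || cad$participation_rate > 1) {
      add(paste0(path, ".participation_rate"),
          sprintf("%g outside (0, 1]", cad$participation_rate))
    }
    aw <- cad$awt
    avail <- aw$possible_working_days - aw$public_holidays -
      aw$annual_leave - aw$sick_leave - aw$other_absences
    if (avail <= 0) {
      add(paste0(path, ".awt"),
          sprintf("available days = %g <= 0", avail))
    }
    if (aw$hours_per_day <= 0) {
      add(paste0(path, ".awt.hours_per_day"),
          sprintf("%g <= 0", aw$hours_per_day))
    }
    sas_sum <- sum(vapply(cad$support_activities, `[[`, numeric(1), "sas"))
    if (length(cad$support_activities) &&
        any(vapply(cad$support_activities, `[[`, numeric(1), "sas") < 0)) {
      add(paste0(path, ".support_activities"), "negative SAS value")
    }
    if (sas_sum >= 1) {
      add(paste0(path, ".support_activities"),
          sprintf("sum of SAS = %g >= 1", sas_sum))
    }
    pl <- cad$pipeline
    ppath <- paste0(path, ".pipeline")
    if (pl$dropout_rate < 0 || pl$dropout_rate > 1) {
      add(paste0(ppath, ".dropout_rate"),
          sprintf("%g outside [0, 1]", pl$dropout_rate))
    }
    if (pl$pass_rate <= 0 || pl$pass_rate > 1) {
      add(paste0(ppath, ".pass_rate"),
          sprintf("%g outside (0, 1]", pl$pass_rate))
    }
    if (pl$training_duration < 0) {
      add(paste0(ppath, ".training_duration"),
          sprintf("%d < 0", pl$training_duration))
    }
    if (any(pl$enrolment_by_year < 0)) {
      add(paste0(ppath, ".enrolment_by_year"), "negative enrolment")
    }
    if (any(pl$immigration_by_year < 0)) {
      add(paste0(ppath, ".immigration_by_year"), "negative immigration")
    }
  }
  v
}

#' Validate a scenario
#'
#' Runs every invariant check in [scenario_violations()]; on success returns
#' the scenario marked as validated (validation is idempotent: validating a
#' validated scenario returns it unchanged), on failure throws an error
#' listing each violation with its parameter path.
#'
#' @param scn an `hwf_scenario` from [scenario()] or [load_scenario()].
#' @return the validated `hwf_scenario`.
#' @export
#' @examples
#' scn <- generate_synthetic_scenario(seed = 1)
#' scn <- validate_scenario(scn) # already valid by construction
validate_scenario <- function(scn) {
  v <- scenario_violations(scn)
  if (length(v)) {
    stop("invalid scenario '", scn$name, "' (", length(v), " violation",
         if (length(v) > 1L) "s", "):\n",
         paste0("  - ", v, collapse = "\n"), call. = FALSE)
  }
  attr(scn, "validated") <- TRUE
  scn
}

# Internal: engines call this to insist on prior validation without paying
# for re-validation on every operation.
assert_validated <- function(scn) {
  if (!inherits(scn, "hwf_scenario")) {
    stop("expected an hwf_scenario", call. = FALSE)
  }
  if (!isTRUE(attr(scn, "validated"))) {
    v <- scenario_violations(scn)
    if (length(v)) {
      stop("scenario '", scn$name, "' is invalid; run validate_scenario() ",
           "for details", call. = FALSE)
    }
  }
  invisible(scn)
}
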