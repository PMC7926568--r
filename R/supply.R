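# Supply-side engine: stock-and-flow projection of each cadre.
#
# Registered stock evolves as T_t = T_{t-1} * (1 - a) + I_t: the previous
# stock survives attrition, then the year's pipeline inflow enters (new
# graduates are not attrited in their entry year). Effective supply is the
# registered stock scaled by the labour participation rate.

#' Attrition rate from observed exits
#'
#' The proportion of an opening stock lost over a period to death,
#' retirement, ill health and out-migration.
#'
#' @param exits persons who left during the period, `0 <= exits <=
#'   opening_stock`.
#' @param opening_stock persons at the start of the period (positive).
#' @return proportion in `[0, 1]`.
#' @export
#' @examples
#' compute_attrition_rate(50, 1000) # 5% annual attrition
compute_attrition_rate <- function(exits, opening_stock) {
  assert_scalar_num(exits, "exits")
  assert_scalar_num(opening_stock, "opening_stock")
  if (opening_stock <= 0) stop("`opening_stock` must be > 0", call. = FALSE)
  if (exits < 0) stop("`exits` must be >= 0", call. = FALSE)
  if (exits > opening_stock) {
    stop("`exits` cannot exceed `opening_stock`", call. = FALSE)
  }
  exits / opening_stock
}

#' Education-pipeline inflow for one year
#'
#' New entrants to the registered stock in year `t`: the enrolment cohort of
#' `t - training_duration` survives dropout, immigrants are added, and the
#' total is adjusted by the licensure pass rate:
#' `I_t = (enrolment[t - duration] * (1 - dropout) + immigration[t]) * pass`.
#'
#' When the enrolment series is non-empty but has no entry for the lagged
#' year, the domestic term is taken as zero (with a warning unless `quiet`).
#'
#' @param pipeline an [education_pipeline()].
#' @param year entry year `t`.
#' @param quiet suppress the missing-enrolment warning (used internally by
#'   [project_supply()], which consolidates them).
#' @return persons entering the stock in year `t`.
#' @export
compute_pipeline_inflow <- function(pipeline, year, quiet = FALSE) {
  if (!inherits(pipeline, "hwf_pipeline")) {
    stop("`pipeline` must be education_pipeline()", call. = FALSE)
  }
  lag_year <- as.integer(year) - pipeline$training_duration
  enrol <- year_lookup(pipeline$enrolment_by_year, lag_year)
  if (is.na(enrol)) {
    if (length(pipeline$enrolment_by_year) && !isTRUE(quiet)) {
      warning(sprintf(
        "no enrolment recorded for year %d (inflow year %d); domestic pipeline taken as 0",
        lag_year, as.integer(year)), call. = FALSE)
    }
    enrol <- 0
  }
  imm <- year_lookup(pipeline$immigration_by_year, year)
  if (is.na(imm)) imm <- 0
  (enrol * (1 - pipeline$dropout_rate) + imm) * pipeline$pass_rate
}

#' Project the supply of a cadre
#'
#' Stock-and-flow recursion from the cadre's baseline registered stock:
#' `T_t = T_{t-1} * (1 - attrition) + I_t` for each year after the first,
#' with `I_t` from [compute_pipeline_inflow()]. Effective supply each year
#' is `T_t * participation_rate`. Headcounts stay real-valued; rounding
#' happens only at reporting.
#'
#' @param cadre a [cadre_profile()].
#' @param years integer vector of consecutive calendar years; the first is
#'   treated as the base year at which `baseline_stock` holds.
#' @return object of class `hwf_supply_series`: a list with `cadre_id`,
#'   `registered_stock_by_year` and `effective_supply_by_year` (named
#'   numeric vectors, year -> persons).
#' @export
#' @examples
#' cad <- cadre_profile("midwife", baseline_stock = 100,
#'                      attrition_rate = 0.05, participation_rate = 0.9,
#'                      pipeline = education_pipeline(
#'                        enrolment_by_year = c(`2021` = 10, `2022` = 10)))
#' project_supply(cad, 2020:2022)
project_supply <- function(cadre, years) {
  if (!inherits(cadre, "hwf_cadre")) {
    stop("`cadre` must be cadre_profile()", call. = FALSE)
  }
  years <- as.integer(years)
  if (length(years) == 0L) stop("`years` must be non-empty", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("`years` must be consecutive calendar years", call. = FALSE)
  }
  stock <- stats::setNames(numeric(length(years)), as.character(years))
  stock[1L] <- cadre$baseline_stock
  missing_years <- integer(0)
  if (length(years) > 1L) {
    for (i in 2L:length(years)) {
      lag_year <- years[i] - cadre$pipeline$training_duration
      if (length(cadre$pipeline$enrolment_by_year) &&
          is.na(year_lookup(cadre$pipeline$enrolment_by_year, lag_year))) {
        missing_years <- c(missing_years, years[i])
      }
      inflow <- compute_pipeline_inflow(cadre$pipeline, years[i],
                                        quiet = TRUE)
      stock[i] <- stock[i - 1L] * (1 - cadre$attrition_rate) + inflow
    }
  }
  if (length(missing_years)) {
    warning(sprintf(
      "cadre '%s': no enrolment recorded for inflow year(s) %s; domestic pipeline taken as 0 there",
      cadre$cadre_id, paste(missing_years, collapse = ", ")),
      call. = FALSE)
  }
  structure(
    list(cadre_id = cadre$cadre_id,
         registered_stock_by_year = stock,
         effective_supply_by_year = stock * cadre$participation_rate),
    class = "hwf_supply_series"
  )
}

#' @export
print.hwf_supply_series <- function(x, ...) {
  cat("<hwf_supply_series> ", x$cadre_id, "\n", sep = "")
  print(rbind(registered = round(x$registered_stock_by_year, 1),
              effective = round(x$effective_supply_by_year, 1)))
  invisible(x)
}
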