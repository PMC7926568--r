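# Gap, staff-availability-ratio and wage-bill analysis.
#
# Need and supply series are integrated on headcounts rounded half-up to
# whole persons (you employ whole people); the absolute gap is
# supply - need (negative = shortage, the number still to be trained) and
# the staff availability ratio SAR = supply / need (1 = equilibrium).
# Wage bills multiply headcounts by average income compounded for
# inflation.

#' Absolute workforce gap
#'
#' `supply - need`: negative values are needs-based shortages (the number
#' "needed to be trained"), positive values a needs-based oversupply.
#'
#' @param supply,need persons (non-negative).
#' @return signed persons.
#' @export
#' @examples
#' absolute_gap(11930, 16462) # a shortage of 4532
absolute_gap <- function(supply, need) {
  if (any(supply < 0) || any(need < 0)) {
    stop("`supply` and `need` must be >= 0", call. = FALSE)
  }
  supply - need
}

#' Staff availability ratio
#'
#' `supply / need`: the proportion of the needs-based requirement met by
#' the anticipated supply. 1 indicates equilibrium, below 1 a shortage
#' (workload pressure on the staff in post), above 1 a needs-based
#' oversupply.
#'
#' @param supply persons (non-negative).
#' @param need persons (strictly positive; the ratio is undefined at zero
#'   need).
#' @return ratio; multiply by 100 for the conventional percent report.
#' @export
#' @examples
#' staff_availability_ratio(11930, 16462) # 0.7247 -> reported as 72.5%
staff_availability_ratio <- function(supply, need) {
  if (any(supply < 0)) stop("`supply` must be >= 0", call. = FALSE)
  if (any(need <= 0)) {
    stop("SAR undefined: `need` must be > 0", call. = FALSE)
  }
  supply / need
}

#' Project average income under inflation
#'
#' `baseline_income * (1 + inflation)^years_elapsed`.
#'
#' @param baseline_income currency/person/year at the base year.
#' @param inflation annual income growth rate (proportion/year).
#' @param years_elapsed whole years since the base year (>= 0).
#' @return currency/person/year.
#' @export
project_income <- function(baseline_income, inflation, years_elapsed) {
  if (any(years_elapsed < 0)) {
    stop("`years_elapsed` must be >= 0", call. = FALSE)
  }
  baseline_income * (1 + inflation)^years_elapsed
}

#' Wage-bill cost series
#'
#' Elementwise product of a headcount series and an income series over the
#' same years. Aggregate across cadres by summing the resulting series.
#'
#' @param headcount_by_year,income_by_year named numeric vectors keyed by
#'   year; the year ranges must match exactly.
#' @return named numeric vector, year -> currency.
#' @export
cost_series <- function(headcount_by_year, income_by_year) {
  if (is.null(names(headcount_by_year)) || is.null(names(income_by_year)) ||
      !identical(names(headcount_by_year), names(income_by_year))) {
    stop("headcount and income series must cover identical years",
         call. = FALSE)
  }
  headcount_by_year * income_by_year
}

#' Growth summary of an annual series
#'
#' Year-on-year percentage changes and the compound annual growth rate
#' (CAGR) over the whole series, the convention in which workforce
#' projections are reported ("increases on average by x% annually").
#'
#' @param series_by_year named numeric vector of strictly positive values
#'   keyed by consecutive years; at least two years.
#' @return a list with `annual_pct` (named vector of year-on-year % changes,
#'   labelled by the later year), `total_pct` (% change from first to last
#'   year) and `cagr_pct` (`((last/first)^(1/intervals) - 1) * 100`).
#' @export
#' @examples
#' summarize_growth(c(`2020` = 16462, `2025` = 19409)) # 17.9% total
summarize_growth <- function(series_by_year) {
  x <- series_by_year
  if (length(x) < 2L) stop("need at least two years", call. = FALSE)
  if (any(x <= 0)) {
    stop("growth summary undefined for non-positive values", call. = FALSE)
  }
  if (is.null(names(x))) {
    names(x) <- as.character(seq_along(x))
  }
  n_int <- length(x) - 1L
  annual <- (x[-1L] / x[-length(x)] - 1) * 100
  list(
    annual_pct = annual,
    total_pct = unname((x[[length(x)]] / x[[1L]] - 1) * 100),
    cagr_pct = unname(((x[[length(x)]] / x[[1L]])^(1 / n_int) - 1) * 100)
  )
}

#' Gap and SAR table from need and supply series
#'
#' Rounds both series half-up to whole persons, then computes the absolute
#' gap and staff availability ratio per year. This printed-input arithmetic
#' is the reporting convention of the model: gaps reconcile exactly with the
#' rounded headcount tables. SAR is `NA` for years with zero rounded need.
#'
#' @param cadre_id label carried into the output.
#' @param need_by_year,supply_by_year named numeric vectors keyed by the
#'   same years.
#' @return data frame with columns `cadre_id`, `year`, `need`, `supply`,
#'   `gap`, `sar` (ratio) and `sar_pct` (rounded half-up to 0.1%).
#' @export
gap_table <- function(cadre_id, need_by_year, supply_by_year) {
  if (is.null(names(need_by_year)) || is.null(names(supply_by_year)) ||
      !identical(names(need_by_year), names(supply_by_year))) {
    stop("need and supply series must cover identical years", call. = FALSE)
  }
  need_r <- round_half_up(need_by_year)
  supply_r <- round_half_up(supply_by_year)
  sar <- ifelse(need_r > 0, supply_r / need_r, NA_real_)
  data.frame(
    cadre_id = cadre_id,
    year = as.integer(names(need_by_year)),
    need = unname(need_r),
    supply = unname(supply_r),
    gap = unname(supply_r - need_r),
    sar = unname(sar),
    sar_pct = unname(round_half_up(sar * 100, 1)),
    row.names = NULL
  )
}
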