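# Internal helpers shared across the engines.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the IEC 60559 banker's
#' rounding used by [base::round()]. Headcounts reported by the planning
#' model are rounded this way so that, e.g., 0.5 of a person becomes 1.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), digits = 0)
#' round_half_up(72.47, digits = 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

# scalar checks used by constructors; stop early on structural misuse
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_scalar_chr <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("`%s` must be a single non-empty string", name),
         call. = FALSE)
  }
  invisible(x)
}

# Named numeric vector keyed by year ("2020" etc.); accepts NULL -> empty.
as_year_map <- function(x, name) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(sprintf("`%s` must be a named numeric vector keyed by year", name),
         call. = FALSE)
  }
  yrs <- suppressWarnings(as.integer(names(x)))
  if (anyNA(yrs)) {
    stop(sprintf("`%s` has non-integer year names", name), call. = FALSE)
  }
  stats::setNames(as.numeric(x), as.character(yrs))
}

year_lookup <- function(map, year) {
  key <- as.character(year)
  if (key %in% names(map)) unname(map[[key]]) else NA_real_
}

# Proportions may arrive from configuration as "12.5%"; convert at the
# I/O boundary only — internally everything is a fraction in [0, 1].
parse_proportion <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x)) {
    pct <- grepl("%\\s*$", x)
    out <- suppressWarnings(as.numeric(sub("%\\s*$", "", x)))
    out[pct] <- out[pct] / 100
    return(out)
  }
  stop("proportion values must be numeric or percent strings", call. = FALSE)
}
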