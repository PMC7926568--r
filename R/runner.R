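# Orchestration: full projections, scenario variants and sensitivity
# sweeps. Everything here is deterministic given the scenario (and, for
# sweeps, the seed).

#' Run a full projection
#'
#' Projects, for every cadre and every year of the horizon: the needs-based
#' FTE requirement, the stock-and-flow supply, the absolute gap and staff
#' availability ratio (on headcounts rounded half-up to whole persons), and
#' the wage-bill cost of need (rounded need x income) and of supply
#' (un-rounded effective supply x income). Per-service annual volumes are
#' returned alongside.
#'
#' @param scn a validated [scenario()]. An unvalidated scenario is validated
#'   first.
#' @return an object of class `hwf_projection`: a list with
#'   \describe{
#'     \item{scenario_name, practice_setting, years}{run metadata;}
#'     \item{cadres}{data frame with columns `cadre_id`, `year`, `need_fte`,
#'       `need` (rounded), `supply_fte`, `supply` (rounded), `gap`, `sar`,
#'       `sar_pct`, `income`, `cost_of_need`, `cost_of_supply`;}
#'     \item{services}{data frame with columns `service_id`, `year`,
#'       `volume`.}
#'   }
#'   `sar` is `NA` where rounded need is zero.
#' @export
#' @examples
#' scn <- generate_synthetic_scenario(seed = 1)
#' res <- run_scenario(scn)
#' head(res$cadres)
run_scenario <- function(scn) {
  if (!isTRUE(attr(scn, "validated"))) scn <- validate_scenario(scn)
  years <- scenario_years(scn)
  ykey <- as.character(years)

  services <- do.call(rbind, lapply(scn$services, function(svc) {
    data.frame(
      service_id = svc$service_id,
      year = years,
      volume = vapply(years, function(y) compute_service_need(scn, svc, y),
                      numeric(1)),
      row.names = NULL
    )
  }))
  if (is.null(services)) {
    services <- data.frame(service_id = character(0), year = integer(0),
                           volume = numeric(0))
  }

  cadres <- do.call(rbind, lapply(scn$cadres, function(cad) {
    need_fte <- vapply(
      years, function(y) compute_workforce_requirement(scn, cad$cadre_id, y),
      numeric(1))
    supply <- project_supply(cad, years)$effective_supply_by_year
    gaps <- gap_table(cad$cadre_id,
                      stats::setNames(need_fte, ykey),
                      stats::setNames(unname(supply), ykey))
    income <- project_income(cad$baseline_income, cad$income_inflation,
                             years - scn$base_year)
    data.frame(
      cadre_id = cad$cadre_id,
      year = years,
      need_fte = need_fte,
      need = gaps$need,
      supply_fte = unname(supply),
      supply = gaps$supply,
      gap = gaps$gap,
      sar = gaps$sar,
      sar_pct = gaps$sar_pct,
      income = income,
      cost_of_need = gaps$need * income,
      cost_of_supply = unname(supply) * income,
      row.names = NULL
    )
  }))
  if (is.null(cadres)) {
    cadres <- data.frame(cadre_id = character(0), year = integer(0),
                         need_fte = numeric(0), need = numeric(0),
                         supply_fte = numeric(0), supply = numeric(0),
                         gap = numeric(0), sar = numeric(0),
                         sar_pct = numeric(0), income = numeric(0),
                         cost_of_need = numeric(0),
                         cost_of_supply = numeric(0))
  }

  structure(
    list(scenario_name = scn$name,
         practice_setting = scn$practice_setting,
         years = years,
         cadres = cadres,
         services = services),
    class = "hwf_projection"
  )
}

#' @export
print.hwf_projection <- function(x, ...) {
  cat("<hwf_projection> ", x$scenario_name, " (",
      min(x$years), "-", max(x$years), ")\n", sep = "")
  for (cid in unique(x$cadres$cadre_id)) {
    d <- x$cadres[x$cadres$cadre_id == cid, ]
    first <- d[1L, ]
    last <- d[nrow(d), ]
    cat(sprintf(
      "  %s: need %s -> %s, supply %s -> %s, gap %s -> %s, SAR %.1f%% -> %.1f%%\n",
      cid, format(first$need, big.mark = ","),
      format(last$need, big.mark = ","),
      format(first$supply, big.mark = ","),
      format(last$supply, big.mark = ","),
      format(first$gap, big.mark = ","), format(last$gap, big.mark = ","),
      first$sar_pct, last$sar_pct))
  }
  invisible(x)
}

## ---- parameter paths and overrides ----------------------------------------

# Split "cadres[midwife].pipeline.dropout_rate" or the dotted equivalent
# "cadres.midwife.pipeline.dropout_rate" into segments.
split_path <- function(path) {
  path <- gsub("\\[([^]]+)\\]", ".\\1", path)
  strsplit(path, ".", fixed = TRUE)[[1L]]
}

# Map a path to an index vector usable with [[<- on the scenario list.
resolve_path <- function(scn, path) {
  seg <- split_path(path)
  if (length(seg) == 0L) stop("empty parameter path", call. = FALSE)
  # flags.* aliases the two top-level switches
  if (seg[1L] == "flags") seg <- seg[-1L]
  node <- scn
  idx <- list()
  for (k in seq_along(seg)) {
    s <- seg[k]
    if (is.list(node) && !is.null(names(node)) && s %in% names(node)) {
      idx[[length(idx) + 1L]] <- s
      node <- node[[s]]
      next
    }
    # sections keyed by id: cadres/services/indicators
    if (is.list(node) && length(node) && k > 1L &&
        seg[k - 1L] %in% c("cadres", "services", "indicators")) {
      field <- c(cadres = "cadre_id", services = "service_id",
                 indicators = "indicator_id")[[seg[k - 1L]]]
      ids <- vapply(node, `[[`, character(1), field)
      pos <- match(s, ids)
      if (!is.na(pos)) {
        idx[[length(idx) + 1L]] <- pos
        node <- node[[pos]]
        next
      }
    }
    # named numeric leaf (work_division, enrolment_by_year, ...)
    if (is.numeric(node) && s %in% names(node)) {
      idx[[length(idx) + 1L]] <- s
      node <- node[[s]]
      next
    }
    stop(sprintf("parameter path '%s' does not exist in scenario '%s'",
                 path, scn$name), call. = FALSE)
  }
  idx
}

#' Override one scenario parameter by path
#'
#' Paths address the scenario tree with dots and optional `[id]` selectors
#' for the id-keyed sections, e.g. `"cadres[midwife].attrition_rate"`,
#' `"services[anc].frequency"`, `"indicators[anc_gap].rate_of_change"`,
#' `"practice_setting"`, `"flags.apply_rate_of_change"`. The path must
#' exist in the base scenario.
#'
#' @param scn an `hwf_scenario`.
#' @param path parameter path (see examples).
#' @param value replacement value.
#' @return the modified, re-validated scenario.
#' @export
scenario_override <- function(scn, path, value) {
  idx <- resolve_path(scn, path)
  validated <- isTRUE(attr(scn, "validated"))
  assign_path <- function(node, idx, value) {
    if (length(idx) == 1L) {
      node[[idx[[1L]]]] <- value
      return(node)
    }
    node[[idx[[1L]]]] <- assign_path(node[[idx[[1L]]]], idx[-1L], value)
    node
  }
  scn2 <- structure(assign_path(unclass(scn), idx, value),
                    class = "hwf_scenario")
  if (validated) scn2 <- validate_scenario(scn2)
  scn2
}

#' Define a scenario variant
#'
#' A named set of parameter overrides applied to a base scenario, the
#' mechanism behind what-if sensitivity analyses (switching the rate of
#' change off, dropping the support adjustment, swapping activity-standard
#' sets).
#'
#' @param name variant label.
#' @param overrides named list, parameter path -> value (paths as in
#'   [scenario_override()]).
#' @return object of class `hwf_variant`.
#' @seealso [apply_variant()], [builtin_variants()]
#' @export
scenario_variant <- function(name, overrides = list()) {
  assert_scalar_chr(name, "name")
  if (!is.list(overrides) ||
      (length(overrides) && is.null(names(overrides)))) {
    stop("`overrides` must be a named list of path -> value", call. = FALSE)
  }
  structure(list(name = name, overrides = overrides), class = "hwf_variant")
}

#' Pre-registered sensitivity variants
#'
#' The three what-if analyses shipped as built-ins:
#' \describe{
#'   \item{`no-rate-change`}{hold every health indicator at its baseline
#'     level (constant level of health);}
#'   \item{`no-support-adjustment`}{plan for direct care only, no SAAF
#'     inflation;}
#'   \item{`tertiary-standards`}{run under the `"tertiary"` practice
#'     setting's activity standards.}
#' }
#'
#' @return named list of [scenario_variant()] objects.
#' @export
builtin_variants <- function() {
  list(
    `no-rate-change` = scenario_variant(
      "no-rate-change", list(apply_rate_of_change = FALSE)),
    `no-support-adjustment` = scenario_variant(
      "no-support-adjustment", list(apply_support_adjustment = FALSE)),
    `tertiary-standards` = scenario_variant(
      "tertiary-standards", list(practice_setting = "tertiary"))
  )
}

#' Apply a variant to a scenario
#'
#' @param scn base `hwf_scenario`.
#' @param variant an [scenario_variant()], or the name of a built-in from
#'   [builtin_variants()].
#' @return the modified scenario, renamed `<base>@<variant>`.
#' @export
apply_variant <- function(scn, variant) {
  if (is.character(variant)) {
    bv <- builtin_variants()
    if (!variant %in% names(bv)) {
      stop(sprintf("unknown built-in variant '%s'", variant), call. = FALSE)
    }
    variant <- bv[[variant]]
  }
  if (!inherits(variant, "hwf_variant")) {
    stop("`variant` must be an hwf_variant or a built-in name",
         call. = FALSE)
  }
  out <- scn
  for (path in names(variant$overrides)) {
    out <- scenario_override(out, path, variant$overrides[[path]])
  }
  out$name <- paste0(scn$name, "@", variant$name)
  out
}

#' Compare two projection results
#'
#' Long-format comparison of need, supply, gap and SAR per cadre-year:
#' absolute difference (`variant - base`) and percent difference relative
#' to base (`NA` where base is zero).
#'
#' @param base,variant `hwf_projection` objects over the same cadres and
#'   years.
#' @return data frame with columns `cadre_id`, `year`, `metric`, `base`,
#'   `variant`, `diff`, `pct_diff`.
#' @export
compare_scenarios <- function(base, variant) {
  for (x in list(base, variant)) {
    if (!inherits(x, "hwf_projection")) {
      stop("both arguments must be hwf_projection results", call. = FALSE)
    }
  }
  if (!identical(base$years, variant$years)) {
    stop("projection horizons differ", call. = FALSE)
  }
  b <- base$cadres[order(base$cadres$cadre_id, base$cadres$year), ]
  v <- variant$cadres[order(variant$cadres$cadre_id, variant$cadres$year), ]
  if (!identical(b$cadre_id, v$cadre_id) || !identical(b$year, v$year)) {
    stop("projections cover different cadres", call. = FALSE)
  }
  metrics <- c(need = "need_fte", supply = "supply_fte", gap = "gap",
               sar = "sar")
  out <- do.call(rbind, lapply(names(metrics), function(m) {
    col <- metrics[[m]]
    bb <- b[[col]]
    vv <- v[[col]]
    data.frame(
      cadre_id = b$cadre_id, year = b$year, metric = m,
      base = bb, variant = vv, diff = vv - bb,
      pct_diff = ifelse(!is.na(bb) & bb != 0, (vv - bb) / bb * 100,
                        NA_real_),
      row.names = NULL
    )
  }))
  out
}

#' Seeded sensitivity sweep
#'
#' Samples `n_samples` parameter vectors by Latin-hypercube design over the
#' given ranges, runs the projection for each, and reports the per
#' cadre-year envelope (minimum and maximum) of need, supply and gap. The
#' base trajectory is included in the envelope, so degenerate ranges
#' reproduce it exactly.
#'
#' @param scn base `hwf_scenario`.
#' @param ranges named list, parameter path -> `c(low, high)` (numeric
#'   paths only; paths as in [scenario_override()]).
#' @param n_samples number of sampled parameter vectors (>= 1).
#' @param seed integer seed; the sweep is reproducible given the seed.
#' @return object of class `hwf_sweep`: list with `base` (the base
#'   `hwf_projection`), `envelope` (data frame `cadre_id`, `year`, `metric`,
#'   `min`, `max`), `samples` (data frame of sampled parameter values, one
#'   row per sample) and `n_samples`.
#' @export
sensitivity_sweep <- function(scn, ranges, n_samples = 16, seed = 1) {
  if (!is.list(ranges) || length(ranges) == 0L || is.null(names(ranges))) {
    stop("`ranges` must be a named list of path -> c(low, high)",
         call. = FALSE)
  }
  for (p in names(ranges)) {
    r <- ranges[[p]]
    if (!is.numeric(r) || length(r) != 2L || r[1L] > r[2L]) {
      stop(sprintf("range for '%s' must be c(low, high) with low <= high",
                   p), call. = FALSE)
    }
    resolve_path(scn, p) # existence check up front
  }
  if (!isTRUE(attr(scn, "validated"))) scn <- validate_scenario(scn)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)

  set.seed(as.integer(seed))
  k <- length(ranges)
  u <- lhs::randomLHS(n_samples, k)
  lows <- vapply(ranges, `[[`, numeric(1), 1L)
  highs <- vapply(ranges, `[[`, numeric(1), 2L)
  samples <- sweep(sweep(u, 2L, highs - lows, `*`), 2L, lows, `+`)
  colnames(samples) <- names(ranges)

  base_res <- run_scenario(scn)
  metrics <- c(need = "need_fte", supply = "supply_fte", gap = "gap")
  extract <- function(res) {
    d <- res$cadres[order(res$cadres$cadre_id, res$cadres$year), ]
    do.call(rbind, lapply(names(metrics), function(m) {
      data.frame(cadre_id = d$cadre_id, year = d$year, metric = m,
                 value = d[[metrics[[m]]]], row.names = NULL)
    }))
  }
  env <- extract(base_res)
  lo <- env$value
  hi <- env$value
  for (i in seq_len(n_samples)) {
    scn_i <- scn
    for (j in seq_len(k)) {
      scn_i <- scenario_override(scn_i, names(ranges)[j], samples[i, j])
    }
    vals <- extract(run_scenario(scn_i))$value
    lo <- pmin(lo, vals)
    hi <- pmax(hi, vals)
  }
  structure(
    list(base = base_res,
         envelope = data.frame(cadre_id = env$cadre_id, year = env$year,
                               metric = env$metric, min = lo, max = hi,
                               row.names = NULL),
         samples = as.data.frame(samples),
         n_samples = n_samples),
    class = "hwf_sweep"
  )
}

#' @export
print.hwf_sweep <- function(x, ...) {
  cat("<hwf_sweep> ", x$n_samples, " samples over ",
      ncol(x$samples), " parameter(s): ",
      paste(colnames(x$samples), collapse = ", "), "\n", sep = "")
  invisible(x)
}
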