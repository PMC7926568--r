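# Scenario configuration I/O and result export.
#
# A scenario lives on disk as one YAML config referencing three CSV tables
# and one cadre YAML (paths resolved relative to the config file):
#
#   config.yaml      name, base_year, horizon_end, practice_setting, flags,
#                    and the file names below
#   population.csv   age_cohort,gender,location,year,count
#   indicators.csv   indicator_id,age_cohort,gender,location,baseline_value,
#                    baseline_year,second_value,second_year,rate_of_change,
#                    rate_method
#   services.csv     one row per service x setting x cadre:
#                    service_id,indicator_id,frequency,setting,
#                    service_standard,cadre_id,work_division
#   cadres.yaml      list of cadre entries (awt, support_activities,
#                    pipeline nested)
#
# Column names are fixed and case-sensitive. Proportion fields accept
# percent notation ("12.5%") and are converted to fractions on read;
# internally everything is a fraction.

blank_to_null <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) ||
      (is.character(x) && !nzchar(trimws(x)))) NULL else x
}

# Selector cells may hold one label, several separated by ";", or
# "all"/blank meaning no restriction.
selector_or_null <- function(x) {
  x <- blank_to_null(x)
  if (is.null(x) || identical(tolower(x), "all")) return(NULL)
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("referenced table not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(required_cols, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Load a scenario from a configuration file
#'
#' Reads the YAML config, the CSV tables it references and the cadre YAML,
#' converts percent-notation proportions to fractions, assembles the
#' scenario and validates it.
#'
#' @param path path to the scenario's `config.yaml` (or a directory
#'   containing one).
#' @return a validated `hwf_scenario`.
#' @seealso [write_scenario()], [validate_scenario()]
#' @export
#' @examples
#' demo <- system.file("extdata", "demo_scenario", package = "hwfplan")
#' scn <- load_scenario(demo)
load_scenario <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "config.yaml")
  if (!file.exists(path)) {
    stop(sprintf("scenario config not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  root <- dirname(path)
  need_field <- function(nm) {
    if (is.null(cfg[[nm]])) {
      stop(sprintf("config %s: missing field '%s'", path, nm),
           call. = FALSE)
    }
    cfg[[nm]]
  }
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(root, p)

  pop_tab <- read_table_checked(
    resolve(need_field("population")),
    c("age_cohort", "gender", "location", "year", "count"))
  population <- data.frame(
    age_cohort = pop_tab$age_cohort, gender = pop_tab$gender,
    location = pop_tab$location,
    year = as.integer(pop_tab$year),
    count = num_or_na(pop_tab$count))

  ind_tab <- read_table_checked(
    resolve(need_field("indicators")),
    c("indicator_id", "age_cohort", "gender", "location",
      "baseline_value", "baseline_year"))
  opt_col <- function(tab, nm, i) {
    if (nm %in% names(tab)) blank_to_null(tab[[nm]][i]) else NULL
  }
  indicators <- lapply(seq_len(nrow(ind_tab)), function(i) {
    rate <- opt_col(ind_tab, "rate_of_change", i)
    sec_v <- opt_col(ind_tab, "second_value", i)
    sec_y <- opt_col(ind_tab, "second_year", i)
    method <- opt_col(ind_tab, "rate_method", i)
    health_indicator(
      ind_tab$indicator_id[i],
      baseline_value = parse_proportion(ind_tab$baseline_value[i]),
      baseline_year = as.integer(ind_tab$baseline_year[i]),
      second_value = if (is.null(sec_v)) NULL else parse_proportion(sec_v),
      second_year = if (is.null(sec_y)) NULL else as.integer(sec_y),
      rate_of_change = if (is.null(rate)) NULL else parse_proportion(rate),
      age_cohort = selector_or_null(ind_tab$age_cohort[i]),
      gender = selector_or_null(ind_tab$gender[i]),
      location = selector_or_null(ind_tab$location[i]),
      rate_method = if (is.null(method)) "geometric" else method)
  })

  svc_tab <- read_table_checked(
    resolve(need_field("services")),
    c("service_id", "indicator_id", "frequency", "setting",
      "service_standard", "cadre_id", "work_division"))
  services <- lapply(unique(svc_tab$service_id), function(sid) {
    rows <- svc_tab[svc_tab$service_id == sid, , drop = FALSE]
    ss_rows <- unique(rows[c("setting", "service_standard")])
    ss_vals <- num_or_na(ss_rows$service_standard)
    settings <- vapply(ss_rows$setting, function(s) {
      s <- blank_to_null(s)
      if (is.null(s)) "" else s
    }, character(1))
    ss <- if (length(ss_vals) == 1L && !nzchar(settings[1L])) {
      ss_vals[1L]
    } else {
      stats::setNames(ss_vals, settings)
    }
    wd_rows <- unique(rows[c("cadre_id", "work_division")])
    wd <- stats::setNames(parse_proportion(wd_rows$work_division),
                          wd_rows$cadre_id)
    service_norm(sid, rows$indicator_id[1L],
                 frequency = num_or_na(rows$frequency[1L]),
                 service_standard = ss, work_division = wd)
  })

  cad_path <- resolve(need_field("cadres"))
  if (!file.exists(cad_path)) {
    stop(sprintf("referenced table not found: %s", cad_path), call. = FALSE)
  }
  cad_cfg <- yaml::read_yaml(cad_path)
  cad_list <- if (!is.null(cad_cfg$cadres)) cad_cfg$cadres else cad_cfg
  cadres <- lapply(cad_list, function(cc) {
    aw <- cc$awt
    if (is.null(aw)) aw <- list()
    support <- lapply(cc$support_activities, function(sa) {
      support_activity(sa$name, parse_proportion(sa$sas))
    })
    pl <- cc$pipeline
    if (is.null(pl)) pl <- list()
    to_map <- function(x) {
      if (is.null(x) || length(x) == 0L) NULL else
        stats::setNames(as.numeric(unlist(x)), names(x))
    }
    cadre_profile(
      cc$cadre_id,
      baseline_stock = as.numeric(cc$baseline_stock),
      attrition_rate = parse_proportion(
        if (is.null(cc$attrition_rate)) 0 else cc$attrition_rate),
      participation_rate = parse_proportion(
        if (is.null(cc$participation_rate)) 1 else cc$participation_rate),
      awt = do.call(awt_components, aw),
      support_activities = support,
      pipeline = education_pipeline(
        enrolment_by_year = to_map(pl$enrolment_by_year),
        dropout_rate = parse_proportion(
          if (is.null(pl$dropout_rate)) 0 else pl$dropout_rate),
        training_duration =
          if (is.null(pl$training_duration)) 0 else pl$training_duration,
        pass_rate = parse_proportion(
          if (is.null(pl$pass_rate)) 1 else pl$pass_rate),
        immigration_by_year = to_map(pl$immigration_by_year)),
      baseline_income =
        if (is.null(cc$baseline_income)) 0 else as.numeric(cc$baseline_income),
      income_inflation = parse_proportion(
        if (is.null(cc$income_inflation)) 0 else cc$income_inflation))
  })

  flags <- if (is.null(cfg$flags)) list() else cfg$flags
  validate_scenario(scenario(
    name = need_field("name"),
    base_year = need_field("base_year"),
    horizon_end = need_field("horizon_end"),
    population = population, indicators = indicators,
    services = services, cadres = cadres,
    practice_setting =
      if (is.null(cfg$practice_setting)) "primary" else cfg$practice_setting,
    apply_rate_of_change =
      if (is.null(flags$apply_rate_of_change)) TRUE else
        flags$apply_rate_of_change,
    apply_support_adjustment =
      if (is.null(flags$apply_support_adjustment)) TRUE else
        flags$apply_support_adjustment))
}

#' Write a scenario to a configuration directory
#'
#' Serialises the scenario to the same file layout [load_scenario()] reads;
#' `load_scenario(write_scenario(scn, dir))` reproduces the scenario.
#'
#' @param scn an `hwf_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  if (!inherits(scn, "hwf_scenario")) {
    stop("`scn` must be an hwf_scenario", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scn$population, file.path(dir, "population.csv"),
                   row.names = FALSE)

  chr_or_blank <- function(x) if (is.null(x)) "" else
    paste(x, collapse = ";")
  ind_tab <- do.call(rbind, lapply(scn$indicators, function(ind) {
    data.frame(
      indicator_id = ind$indicator_id,
      age_cohort = chr_or_blank(ind$age_cohort),
      gender = chr_or_blank(ind$gender),
      location = chr_or_blank(ind$location),
      baseline_value = ind$baseline_value,
      baseline_year = ind$baseline_year,
      second_value = if (is.null(ind$second_value)) "" else ind$second_value,
      second_year = if (is.null(ind$second_year)) "" else ind$second_year,
      rate_of_change = if (is.null(ind$rate_of_change)) "" else
        ind$rate_of_change,
      rate_method = ind$rate_method)
  }))
  utils::write.csv(ind_tab, file.path(dir, "indicators.csv"),
                   row.names = FALSE)

  svc_tab <- do.call(rbind, lapply(scn$services, function(svc) {
    ss <- svc$service_standard
    settings <- if (is.null(names(ss))) "" else names(ss)
    grid <- expand.grid(si = seq_along(ss),
                        ci = seq_along(svc$work_division))
    data.frame(
      service_id = svc$service_id,
      indicator_id = svc$indicator_id,
      frequency = svc$frequency,
      setting = settings[grid$si],
      service_standard = unname(ss)[grid$si],
      cadre_id = names(svc$work_division)[grid$ci],
      work_division = unname(svc$work_division)[grid$ci])
  }))
  utils::write.csv(svc_tab, file.path(dir, "services.csv"),
                   row.names = FALSE)

  cad_list <- lapply(scn$cadres, function(cad) {
    list(
      cadre_id = cad$cadre_id,
      baseline_stock = cad$baseline_stock,
      attrition_rate = cad$attrition_rate,
      participation_rate = cad$participation_rate,
      awt = unclass(cad$awt),
      support_activities = lapply(cad$support_activities, unclass),
      pipeline = list(
        enrolment_by_year = as.list(cad$pipeline$enrolment_by_year),
        dropout_rate = cad$pipeline$dropout_rate,
        training_duration = cad$pipeline$training_duration,
        pass_rate = cad$pipeline$pass_rate,
        immigration_by_year = as.list(cad$pipeline$immigration_by_year)),
      baseline_income = cad$baseline_income,
      income_inflation = cad$income_inflation)
  })
  yaml::write_yaml(list(cadres = cad_list), file.path(dir, "cadres.yaml"),
                   precision = 15)

  yaml::write_yaml(
    list(name = scn$name,
         base_year = scn$base_year,
         horizon_end = scn$horizon_end,
         practice_setting = scn$practice_setting,
         flags = list(apply_rate_of_change = scn$apply_rate_of_change,
                      apply_support_adjustment = scn$apply_support_adjustment),
         population = "population.csv",
         indicators = "indicators.csv",
         services = "services.csv",
         cadres = "cadres.yaml"),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write projection results to CSV and a summary report
#'
#' Writes `need.csv`, `supply.csv`, `gaps.csv`, `costs.csv`, `services.csv`
#' and `summary.md` with a stable column order and documented rounding:
#' FTE, volume and cost values to 2 decimals (half-up), headcounts as whole
#' persons, SAR to 0.1 of a percent. Re-running over the same result
#' produces byte-identical files.
#'
#' @param result an `hwf_projection` from [run_scenario()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(result, out_dir) {
  if (!inherits(result, "hwf_projection")) {
    stop("`result` must be an hwf_projection", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- result$cadres
  r2 <- function(x) round_half_up(x, 2)
  wr <- function(tab, file) {
    utils::write.csv(tab, file.path(out_dir, file), row.names = FALSE)
    file
  }
  files <- c(
    wr(data.frame(cadre_id = d$cadre_id, year = d$year,
                  need_fte = r2(d$need_fte), need = d$need),
       "need.csv"),
    wr(data.frame(cadre_id = d$cadre_id, year = d$year,
                  supply_fte = r2(d$supply_fte), supply = d$supply),
       "supply.csv"),
    wr(data.frame(cadre_id = d$cadre_id, year = d$year,
                  need = d$need, supply = d$supply, gap = d$gap,
                  sar_pct = d$sar_pct),
       "gaps.csv"),
    wr(data.frame(cadre_id = d$cadre_id, year = d$year,
                  income = r2(d$income),
                  cost_of_need = r2(d$cost_of_need),
                  cost_of_supply = r2(d$cost_of_supply)),
       "costs.csv"),
    wr(data.frame(service_id = result$services$service_id,
                  year = result$services$year,
                  volume = r2(result$services$volume)),
       "services.csv")
  )

  lines <- c(
    sprintf("# Projection summary: %s", result$scenario_name),
    "",
    sprintf("- Horizon: %d-%d", min(result$years), max(result$years)),
    sprintf("- Practice setting: %s", result$practice_setting),
    "")
  for (cid in unique(d$cadre_id)) {
    cd <- d[d$cadre_id == cid, ]
    first <- cd[1L, ]
    last <- cd[nrow(cd), ]
    lines <- c(lines, sprintf(
      "- **%s**: need %s -> %s; supply %s -> %s; gap %s -> %s; SAR %.1f%% -> %.1f%%",
      cid,
      format(first$need, big.mark = ",", scientific = FALSE),
      format(last$need, big.mark = ",", scientific = FALSE),
      format(first$supply, big.mark = ",", scientific = FALSE),
      format(last$supply, big.mark = ",", scientific = FALSE),
      format(first$gap, big.mark = ",", scientific = FALSE),
      format(last$gap, big.mark = ",", scientific = FALSE),
      first$sar_pct, last$sar_pct))
  }
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(c(files, "summary.md"))
}
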