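#' Select respiratory-tract-infection (RTI) antibiotics
#'
#' The RTI proxy set is every drug in the BNF families "Penicillins" and
#' "Cephalosporins and other beta-lactams". Amoxicillin is excluded by
#' default: its very large prescription volume across many non-respiratory
#' indications would mask vaccination effects. Family and drug matching is
#' case-insensitive.
#'
#' @param records Canonical record table carrying BNF family labels.
#' @param include_amoxicillin Keep amoxicillin rows (default `FALSE`).
#' @param families The two RTI family labels (override only if the extract
#'   spells them differently).
#' @return The filtered record table.
#' @export
select_rti_records <- function(records, include_amoxicillin = FALSE,
                               families = c("Penicillins",
                                            "Cephalosporins and other beta-lactams")) {
  x <- data.table::as.data.table(records)
  x <- x[tolower(family) %in% tolower(families)]
  if (!include_amoxicillin) x <- x[tolower(drug) != "amoxicillin"]
  x[]
}

#' Read an influenza-vaccination eligibility schedule
#'
#' Season start year -> analysis age group newly eligible for NHS influenza
#' vaccination that season. The package ships a small schedule transcribed
#' from the public history of the English programme at
#' `system.file("extdata", "flu_vaccination_schedule.csv",
#' package = "abxdemog")`; it annotates outputs and is not used in any
#' computation.
#'
#' @param source Path to a CSV with columns `season_start_year`,
#'   `age_group`, or a `data.frame` of that shape.
#' @return A `data.table`.
#' @export
read_vaccination_schedule <- function(source = system.file(
    "extdata", "flu_vaccination_schedule.csv", package = "abxdemog")) {
  x <- if (is.data.frame(source)) data.table::as.data.table(source)
       else data.table::fread(source, encoding = "UTF-8")
  if (!all(c("season_start_year", "age_group") %in% names(x)))
    stop("schedule needs columns season_start_year, age_group", call. = FALSE)
  x[, season_start_year := as.integer(season_start_year)]
  x[]
}

#' Influenza-season relative prescription rates by age group
#'
#' Assembles influenza seasons (October-March; October-December belong to
#' the season starting that year, January-March to the season started the
#' year before; April-September are excluded entirely), sums items per
#' analysis age group and season, and computes per-capita season rates using
#' the mid-year population of the year containing October. Each group's rate
#' is expressed relative to the 15-50 reference group, and the proportional
#' change from the previous season is computed within group
#' (`rate/previous - 1`; `NA` for a group's first season). Vaccination
#' introductions from the schedule are attached as annotations.
#'
#' @param records Record table already filtered with [select_rti_records()]
#'   and de-redacted.
#' @param population Population table ([read_population()]).
#' @param schedule Optional [read_vaccination_schedule()] table.
#' @param reference_group Analysis group used as the rate denominator
#'   (default `"15–50"`).
#' @param groups Named list mapping analysis group label -> canonical bands
#'   (default [flu_age_groups()]).
#' @return A `data.table` with columns `age_group`, `season` (start year),
#'   `items`, `population`, `rate`, `relative_rate`, `prop_change`,
#'   `vaccination_introduced`.
#' @export
season_relative_rates <- function(records, population, schedule = NULL,
                                  reference_group = "15–50",
                                  groups = flu_age_groups()) {
  x <- data.table::as.data.table(records)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  if (!reference_group %in% names(groups))
    stop("reference_group must be one of: ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  p <- parse_period(x$period)
  season <- flu_season_of(p)
  x <- x[!is.na(season)]
  season <- season[!is.na(season)]

  band2group <- data.table::rbindlist(lapply(names(groups), function(g)
    data.table::data.table(age_band = groups[[g]], age_group = g)))
  x <- merge(cbind(x, season = season), band2group, by = "age_band",
             allow.cartesian = FALSE)
  items <- x[, .(items = sum(items)), by = .(age_group, season)]

  pop <- data.table::as.data.table(population)
  pop <- merge(pop[sex %in% c("Female", "Male")], band2group,
               by = "age_band", allow.cartesian = TRUE)
  popg <- pop[, .(population = sum(count)), by = .(age_group, year)]
  out <- merge(items, popg,
               by.x = c("age_group", "season"), by.y = c("age_group", "year"))
  out[, rate := items / population]

  ref <- out[age_group == reference_group, .(season, ref_rate = rate)]
  out <- merge(out, ref, by = "season")
  out[, relative_rate := rate / ref_rate]
  data.table::setorder(out, age_group, season)
  out[, prop_change := {
    prev <- data.table::shift(rate)
    ok <- data.table::shift(season) == season - 1L
    ifelse(ok, rate / prev - 1, NA_real_)
  }, by = age_group]
  out[, ref_rate := NULL]

  out[, vaccination_introduced := FALSE]
  if (!is.null(schedule) && nrow(schedule)) {
    sched <- data.table::as.data.table(schedule)
    out[sched, vaccination_introduced := TRUE,
        on = c(age_group = "age_group", season = "season_start_year")]
  }
  out[]
}
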