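#' Read population denominators
#'
#' ONS-style mid-year estimates: one row per (age band, sex, region, year).
#'
#' @param source Path to a delimited file or a `data.frame` with columns
#'   `age_band`, `sex`, `region`, `year`, `count`.
#' @return A `data.table` with canonical band labels and integer counts.
#' @export
read_population <- function(source) {
  x <- if (is.data.frame(source)) data.table::as.data.table(source)
       else data.table::fread(source, encoding = "UTF-8")
  needed <- c("age_band", "sex", "region", "year", "count")
  if (!all(needed %in% names(x)))
    stop("population table needs columns: ",
         paste(setdiff(needed, names(x)), collapse = ", "), call. = FALSE)
  x <- x[, needed, with = FALSE]
  x[, age_band := parse_age_band(age_band)$label]
  x[, year := as.integer(year)]
  x[, count := as.integer(count)]
  if (any(x$count < 0)) stop("population counts must be >= 0", call. = FALSE)
  if (anyDuplicated(x, by = c("age_band", "sex", "region", "year")))
    stop("duplicate population cells", call. = FALSE)
  x[]
}

#' Prescription rates per 100,000 population
#'
#' Sums item counts within each requested stratum and divides by the matching
#' mid-year population, scaled per 100,000. Denominators are matched by
#' calendar year: every month of a year uses that year's mid-year estimate,
#' and when a stratum collapses over years the denominator is the sum of the
#' annual populations (person-years), so a stratum with no time dimension is
#' read as items per 100,000 person-years. A dimension collapsed out of the
#' strata contributes its whole population (for the years and regions the
#' records span), so e.g. a per-drug rate divides by the total population
#' even when the drug is prescribed only to the elderly. Population must
#' cover every (band, sex, region, year) combination appearing in the
#' records.
#'
#' @param records De-redacted canonical record table (no `NA` items).
#' @param population Population table as from [read_population()].
#' @param strata Character vector of dimensions to keep, from `drug`,
#'   `family`, `age_band`, `sex`, `region`, `period`, `year`.
#' @param zero_fill If `TRUE`, emit explicit zero-item rows for every
#'   combination of the observed stratum levels (cross join) absent from the
#'   records.
#' @param per Scaling constant for the rate (default 1e5; use 1 for
#'   per-person rates).
#' @return A `data.table` with the stratum columns then `items`,
#'   `population`, `rate`. `rate` is `NA` where the denominator is zero.
#' @export
compute_rates <- function(records, population,
                          strata = c("drug", "age_band", "sex", "year"),
                          zero_fill = FALSE, per = 1e5) {
  x <- data.table::as.data.table(records)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  pop <- data.table::as.data.table(population)
  allowed <- c("drug", "family", "age_band", "sex", "region", "period", "year")
  if (!all(strata %in% allowed))
    stop("unknown strata: ", paste(setdiff(strata, allowed), collapse = ", "),
         call. = FALSE)
  x <- data.table::copy(x)
  x[, year := period_year(parse_period(period))]

  # coverage check on the demographic keys the denominator needs
  need <- unique(x[, .(age_band, sex, region, year)])
  miss <- need[!pop, on = c("age_band", "sex", "region", "year")]
  if (nrow(miss))
    stop("population table is missing denominator cell(s), e.g. ",
         paste(utils::capture.output(print(utils::head(miss, 5))),
               collapse = "\n"), call. = FALSE)

  out <- x[, .(items = sum(items)), by = strata]

  # denominator: the FULL population of the years and regions the records
  # span (an absent stratum is zero items over the whole population, not a
  # smaller population), collapsed onto the demographic/time dims kept
  years_cov <- unique(x$year)
  regions_cov <- unique(x$region)
  pop_sub <- pop[pop$year %in% years_cov & pop$region %in% regions_cov]
  pop_by <- intersect(strata, c("age_band", "sex", "region", "year",
                                "period"))
  if ("period" %in% strata) {
    per_map <- unique(x[, .(period, year)])
    den_cells <- merge(per_map, pop_sub, by = "year",
                       allow.cartesian = TRUE)
  } else den_cells <- pop_sub
  den <- if (length(pop_by))
    den_cells[, .(population = sum(count)), by = pop_by]
  else data.table::data.table(population = sum(den_cells$count))

  if (zero_fill && length(strata)) {
    # demographic dims take their levels from the population (so empty cells
    # appear), free dims (drug, family, time) from the records
    lev <- lapply(strata, function(d)
      if (d %in% c("age_band", "sex", "region")) unique(den_cells[[d]])
      else unique(out[[d]]))
    grid <- do.call(data.table::CJ, c(lev, list(unique = TRUE)))
    data.table::setnames(grid, strata)
    out <- merge(grid, out, by = strata, all.x = TRUE)
    out[is.na(items), items := 0L]
  }
  out <- if (length(pop_by)) merge(out, den, by = pop_by, all.x = TRUE)
         else out[, population := den$population]
  out[, rate := ifelse(!is.na(population) & population > 0,
                       items / population * per, NA_real_)]
  data.table::setorderv(out, strata)
  out[]
}

#' Female:male prescribing contrast
#'
#' One row per (drug, age band) with both sexes' rates, the natural log of
#' the female:male rate ratio, and a female-majority flag. When exactly one
#' rate is zero the log ratio is `+Inf`/`-Inf` and the majority follows the
#' nonzero side; when both are zero the row carries `both_zero = TRUE`,
#' `female_majority = NA`, and should be excluded from majority summaries.
#'
#' @param rates Output of [compute_rates()] stratified at least by `drug`,
#'   `age_band`, `sex` (extra strata are carried through).
#' @return A `data.table` with columns `drug`, `age_band` (and any extra
#'   strata), `rate_F`, `rate_M`, `log_ratio`, `female_majority`,
#'   `both_zero`.
#' @export
sex_contrast <- function(rates) {
  x <- data.table::as.data.table(rates)
  if (!all(c("drug", "age_band", "sex", "rate") %in% names(x)))
    stop("rates must be stratified by drug, age_band and sex", call. = FALSE)
  by_cols <- setdiff(names(x), c("sex", "items", "population", "rate"))
  wide <- data.table::dcast(x, paste(paste(by_cols, collapse = " + "),
                                     "~ sex"),
                            value.var = "rate")
  if (!all(c("Female", "Male") %in% names(wide)))
    stop("rates must include both Female and Male strata", call. = FALSE)
  wide <- wide[!is.na(Female) & !is.na(Male)]
  data.table::setnames(wide, c("Female", "Male"), c("rate_F", "rate_M"))
  wide[, both_zero := rate_F == 0 & rate_M == 0]
  wide[, log_ratio := ifelse(both_zero, NA_real_, log(rate_F / rate_M))]
  wide[rate_F > 0 & rate_M == 0, log_ratio := Inf]
  wide[rate_F == 0 & rate_M > 0, log_ratio := -Inf]
  wide[, female_majority := ifelse(both_zero, NA, rate_F > rate_M)]
  wide[]
}
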