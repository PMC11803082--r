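#' Configuration for the synthetic prescription-data generator
#'
#' Describes a synthetic primary-care prescribing dataset with the
#' statistical structure the analysis assumes: 23 age bands x 2 sexes,
#' monthly counts per drug and region, hockey-stick age profiles (high in
#' young children, rising steeply with age), female excess per drug,
#' drug-specific winter seasonality, a COVID-era dip, and small-number
#' suppression of counts below 5. The generator is a test instrument with
#' retained ground truth, not a disclosure-risk emulator of the real FOI
#' extract.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the config.
#' @param start,end First and last months generated, `"YYYY-MM"`.
#' @param drugs Drug table: columns `name`, `family`, `aware_category`,
#'   `base_monthly_rate` (items per 100,000 per month at profile multiplier
#'   1), `seasonal_amplitude` (peak months have mean `(1 + amplitude)` times
#'   baseline), `peak_months` (semicolon-separated month numbers),
#'   `fm_ratio` (female:male rate ratio), `age_profile` (name of a profile
#'   in `age_profiles`). Default: [synthetic_drug_table()].
#' @param age_profiles Named list of length-23 multiplier vectors (band
#'   order of [age_band_table()]). Default: [synthetic_age_profiles()].
#' @param regions Region table: columns `code`, `size_multiplier`
#'   (population scale), `prescribing_multiplier` (uniform rate scale).
#'   Default: one national region `"ENGLAND"`.
#' @param covid_start,covid_end COVID dip window, `"YYYY-MM"` (March 2020 to
#'   June 2022).
#' @param covid_dip Multiplier applied to every mean inside the window.
#' @param suppression_threshold Counts below this are redacted by
#'   [apply_suppression()] (default 5).
#' @param dispersion `Inf` for Poisson counts (default), or a finite
#'   negative-binomial size parameter for overdispersed counts.
#' @param intervention Optional list
#'   `list(bands =, from = "YYYY-MM", multiplier =, drugs = NULL)` applying a
#'   rate multiplier to the given age bands from a month onward (all drugs
#'   when `drugs` is `NULL`) — used to emulate e.g. a vaccination-linked
#'   drop in one age group.
#' @param population_base Length-23 vector of per-sex, per-band population
#'   counts for a size-1 region.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, start = "2015-04", end = "2023-12",
                             drugs = synthetic_drug_table(),
                             age_profiles = synthetic_age_profiles(),
                             regions = data.table::data.table(
                               code = "ENGLAND", size_multiplier = 1,
                               prescribing_multiplier = 1),
                             covid_start = "2020-03", covid_end = "2022-06",
                             covid_dip = 0.7, suppression_threshold = 5L,
                             dispersion = Inf, intervention = NULL,
                             population_base = synthetic_population_base()) {
  drugs <- data.table::as.data.table(drugs)
  regions <- data.table::as.data.table(regions)
  stopifnot(all(c("name", "family", "aware_category", "base_monthly_rate",
                  "seasonal_amplitude", "peak_months", "fm_ratio",
                  "age_profile") %in% names(drugs)),
            all(c("code", "size_multiplier", "prescribing_multiplier") %in%
                  names(regions)),
            length(population_base) == 23L,
            all(drugs$base_monthly_rate > 0), all(drugs$fm_ratio > 0),
            all(drugs$seasonal_amplitude >= 0),
            all(unlist(regions[, .(size_multiplier,
                                   prescribing_multiplier)]) > 0),
            covid_dip > 0)
  if (!all(drugs$age_profile %in% names(age_profiles)))
    stop("unknown age_profile name(s) in drug table", call. = FALSE)
  structure(list(seed = as.integer(seed), start = parse_period(start),
                 end = parse_period(end), drugs = drugs,
                 age_profiles = age_profiles, regions = regions,
                 covid_start = parse_period(covid_start),
                 covid_end = parse_period(covid_end), covid_dip = covid_dip,
                 suppression_threshold = as.integer(suppression_threshold),
                 dispersion = dispersion, intervention = intervention,
                 population_base = population_base),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic prescribing config: ", nrow(x$drugs), " drugs, ",
      nrow(x$regions), " region(s), ", format_period(x$start), " to ",
      format_period(x$end), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname synthetic_config
#' @details `synthetic_drug_table()` is the default 20-drug panel, loosely
#'   modelled on the most prescribed antibiotics in English primary care:
#'   amoxicillin-like high-volume winter-seasonal penicillins, strongly
#'   female-skewed urinary-tract drugs, an acne tetracycline concentrated in
#'   young adults, and a small male-skewed tail.
#' @export
synthetic_drug_table <- function() {
  data.table::rbindlist(list(
    list("Amoxicillin", "Penicillins", "Access", 1000, 0.6, "12;1", 1.40, "hockey"),
    list("Nitrofurantoin", "Urinary-tract infections", "Access", 520, 0.0, "", 4.50, "elderly"),
    list("Flucloxacillin sodium", "Penicillins", "Access", 500, 0.0, "", 1.20, "elderly"),
    list("Doxycycline hyclate", "Tetracyclines", "Access", 430, 0.5, "12;1", 1.50, "elderly"),
    list("Penicillin V", "Penicillins", "Access", 290, 0.7, "12;1", 1.45, "hockey"),
    list("Trimethoprim", "Sulphonamides and trimethoprim", "Access", 270, 0.0, "", 3.00, "elderly"),
    list("Clarithromycin", "Macrolides", "Watch", 270, 0.6, "12;1", 1.70, "elderly"),
    list("Co-amoxiclav", "Penicillins", "Access", 170, 0.3, "12;1", 1.50, "elderly"),
    list("Lymecycline", "Tetracyclines", "Watch", 150, 0.0, "", 1.40, "young_adult"),
    list("Cefalexin", "Cephalosporins and other beta-lactams", "Access", 110, 0.25, "12;1", 4.00, "elderly"),
    list("Azithromycin", "Macrolides", "Watch", 110, 0.3, "12;1", 1.30, "elderly"),
    list("Metronidazole", "Metronidazole", "Access", 80, 0.0, "", 3.50, "young_adult"),
    list("Ciprofloxacin", "Quinolones", "Watch", 70, 0.0, "", 0.92, "elderly"),
    list("Erythromycin", "Macrolides", "Watch", 65, 0.3, "12;1", 1.90, "elderly"),
    list("Oxytetracycline", "Tetracyclines", "Access", 45, 0.0, "", 1.05, "young_adult"),
    list("Pivmecillinam hydrochloride", "Penicillins", "Access", 35, 0.0, "", 3.80, "elderly"),
    list("Erythromycin ethylsuccinate", "Macrolides", "Watch", 30, 0.5, "12;1", 1.00, "hockey"),
    list("Co-trimoxazole", "Sulphonamides and trimethoprim", "Access", 27, 0.0, "", 0.80, "elderly"),
    list("Methenamine hippurate", "Urinary-tract infections", "Unclassified", 20, 0.0, "", 4.00, "elderly"),
    list("Rifaximin", "Other antibacterials", "Unclassified", 11, 0.0, "", 0.70, "elderly")
  ))[, stats::setNames(.SD, c("name", "family", "aware_category",
                              "base_monthly_rate", "seasonal_amplitude",
                              "peak_months", "fm_ratio", "age_profile"))]
}

#' @rdname synthetic_config
#' @details `synthetic_age_profiles()` returns the default multiplier
#'   shapes: `hockey` (childhood peak, steep old-age rise), `elderly`
#'   (monotone old-age rise), `young_adult` (adolescent/young-adult peak),
#'   `flat`.
#' @export
synthetic_age_profiles <- function() {
  list(
    hockey = c(2.5, 2.0, 0.8, 0.6, 0.7, 0.8, 0.8, 0.8, 0.8, 0.9, 1.0, 1.1,
               1.2, 1.4, 1.6, 1.9, 2.2, 2.6, 3.0, 3.2, 3.2, 3.0, 2.8),
    elderly = c(0.30, 0.25, 0.20, 0.25, 0.40, 0.50, 0.55, 0.60, 0.65, 0.70,
                0.80, 0.90, 1.00, 1.20, 1.50, 1.90, 2.40, 3.00, 3.40, 3.50,
                3.40, 3.20, 3.00),
    young_adult = c(0.20, 0.30, 0.50, 1.50, 2.50, 2.20, 1.80, 1.40, 1.10,
                    0.90, 0.80, 0.70, 0.60, 0.50, 0.50, 0.40, 0.40, 0.30,
                    0.30, 0.25, 0.20, 0.20, 0.20),
    flat = rep(1, 23)
  )
}

#' @rdname synthetic_config
#' @details `synthetic_population_base()` is an England-like per-sex age
#'   pyramid (counts per band for a size-1 region; both sexes equal so that
#'   all female:male prescribing contrasts come from the drug `fm_ratio`).
#' @export
synthetic_population_base <- function() {
  c(650e3, 1.30e6, 1.70e6, 1.70e6, 1.60e6, 1.70e6, 1.90e6, 1.90e6, 1.80e6,
    1.70e6, 1.80e6, 1.90e6, 1.80e6, 1.50e6, 1.30e6, 1.20e6, 0.90e6, 0.60e6,
    3.5e5, 1.5e5, 4.0e4, 8.0e3, 1.0e3)
}

#' Generate population denominators from a synthetic config
#'
#' Mid-year-style estimates per (band, sex, region, year): the base pyramid
#' scaled by each region's size multiplier, constant over years (real
#' denominators drift by well under the sampling noise of the counts).
#' Deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return A population `data.table` as accepted by [read_population()].
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  bands <- age_band_table()$label
  years <- period_year(config$start):period_year(config$end)
  grid <- data.table::CJ(region = config$regions$code, age_band = bands,
                         sex = c("Female", "Male"), year = years,
                         sorted = FALSE)
  grid[, count := as.integer(round(
    config$population_base[match(age_band, bands)] *
      config$regions$size_multiplier[match(region, config$regions$code)]))]
  data.table::setcolorder(grid, c("age_band", "sex", "region", "year",
                                  "count"))
  grid[]
}

#' Generate synthetic prescription counts with retained ground truth
#'
#' Draws one count per (drug, age band, sex, region, month) from a Poisson
#' (or negative-binomial) distribution whose mean is the product of the
#' configured factors:
#' `base_rate x age multiplier x sex factor x seasonal multiplier x region
#' prescribing multiplier x COVID dip x intervention multiplier x
#' population / 100,000`. The female/male factors are `2r/(1+r)` and
#' `2/(1+r)` for configured ratio `r`, so the two sexes' rates average to the
#' base rate. Zero draws are emitted as absent rows (matching how the real
#' extracts omit empty cells).
#'
#' @param config A [synthetic_config()].
#' @param population Output of [generate_population()] on the same config.
#' @return A list: `records` (canonical record table, true counts, no
#'   redaction) and `truth` (class `synthetic_truth`: the per-cell expected
#'   counts and the config).
#' @export
generate_prescriptions <- function(config, population = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(population)) population <- generate_population(config)
  pop <- data.table::as.data.table(population)
  bands <- age_band_table()$label
  periods <- config$start:config$end

  cells <- data.table::CJ(drug = config$drugs$name, region = config$regions$code,
                          age_band = bands, sex = c("Female", "Male"),
                          p = periods, sorted = FALSE)
  cells[, `:=`(year = period_year(p), month = period_month(p))]
  cells <- merge(cells, pop[, .(age_band, sex, region, year, count)],
                 by = c("age_band", "sex", "region", "year"))

  di <- match(cells$drug, config$drugs$name)
  cells[, family := config$drugs$family[di]]
  prof <- vapply(seq_len(nrow(config$drugs)), function(i)
    config$age_profiles[[config$drugs$age_profile[i]]],
    numeric(23L))  # 23 bands x n_drugs
  age_mult <- prof[cbind(match(cells$age_band, bands), di)]
  r <- config$drugs$fm_ratio[di]
  sex_mult <- ifelse(cells$sex == "Female", 2 * r / (1 + r), 2 / (1 + r))
  peak_mat <- vapply(strsplit(config$drugs$peak_months, ";", fixed = TRUE),
                     function(s) 1:12 %in% as.integer(s[nzchar(s)]),
                     logical(12L))  # 12 months x n_drugs
  season_mult <- 1 + config$drugs$seasonal_amplitude[di] *
    peak_mat[cbind(cells$month, di)]
  region_mult <- config$regions$prescribing_multiplier[
    match(cells$region, config$regions$code)]
  covid_mult <- ifelse(cells$p >= config$covid_start &
                         cells$p <= config$covid_end, config$covid_dip, 1)
  int_mult <- rep(1, nrow(cells))
  if (!is.null(config$intervention)) {
    iv <- config$intervention
    hit <- cells$age_band %in% iv$bands & cells$p >= parse_period(iv$from)
    if (!is.null(iv$drugs)) hit <- hit & cells$drug %in% iv$drugs
    int_mult[hit] <- iv$multiplier
  }
  mu <- config$drugs$base_monthly_rate[di] / 1e5 *
    age_mult * sex_mult * season_mult * region_mult * covid_mult * int_mult *
    cells$count

  set.seed(config$seed)
  items <- if (is.finite(config$dispersion))
    stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
  else stats::rpois(length(mu), mu)

  truth_tab <- data.table::data.table(
    drug = cells$drug, family = cells$family,
    age_band = cells$age_band, sex = cells$sex, region = cells$region,
    period = format_period(cells$p), expected_items = mu)
  records <- data.table::data.table(
    period = format_period(cells$p), drug = cells$drug,
    family = cells$family, age_band = cells$age_band, sex = cells$sex,
    region = cells$region, items = as.integer(items))[items > 0L]
  data.table::setorder(records, period, drug, region, age_band, sex)
  list(records = records[],
       truth = structure(list(expected_items = truth_tab, config = config),
                         class = "synthetic_truth"))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$expected_items), "cells, expected",
      format(round(sum(x$expected_items$expected_items)), big.mark = ","),
      "items\n")
  invisible(x)
}

#' Small-number suppression
#'
#' Redacts every record whose count is below the threshold (default 5),
#' mimicking the privacy suppression applied to the source extracts. Zero
#' cells are already absent rows and are never emitted as redacted.
#'
#' @param records Record table with numeric items.
#' @param threshold Counts `< threshold` become redacted (`NA`).
#' @return The record table with small counts redacted.
#' @export
apply_suppression <- function(records, threshold = 5L) {
  x <- data.table::copy(data.table::as.data.table(records))
  if (anyNA(x$items))
    stop("records already contain redacted items", call. = FALSE)
  x[items < threshold, items := NA_integer_]
  x[]
}

#' Expected totals from synthetic ground truth
#'
#' Sums the generator's per-cell expected counts over any grouping, e.g. to
#' compare a pipeline estimate with what the config implies.
#'
#' @param truth A `synthetic_truth` object.
#' @param by Character vector of grouping columns (subset of `drug`,
#'   `family`, `age_band`, `sex`, `region`, `period`); empty for the grand
#'   total.
#' @return A `data.table` with the grouping columns and `expected_items`.
#' @export
truth_expected_totals <- function(truth, by = character(0)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  grp <- by  # plain character vector; avoids data.table's by-NSE guessing
  if (length(grp))
    truth$expected_items[, .(expected_items = sum(expected_items)), by = grp]
  else
    truth$expected_items[, .(expected_items = sum(expected_items))]
}
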