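#' Per-drug summary table (most-prescribed antibiotics)
#'
#' Ranks drugs by total items over the complete calendar years and summarises
#' each: total and mean annual items, percentage of items prescribed to
#' females, the calendar month with the most items when summing across the
#' whole dataset (ties broken by earliest month), yearly totals, and — when a
#' population table is supplied — the top three age bands per sex by
#' prescription rate in the reference year.
#'
#' `mean_annual` is the rounded total divided by the number of complete
#' years. Rounding is half-to-even by default, matching how published summary
#' tables print these values; half-away-from-zero is available.
#'
#' @param records De-redacted canonical record table.
#' @param calendar A [study_calendar()]; `complete_years` defines totals.
#' @param top_n Number of drugs to keep (default 20). If it exceeds the
#'   number of drugs available, all are summarised with a warning.
#' @param population Optional population table for the top-band-by-rate
#'   columns.
#' @param band_year Reference year for the top-band rates (default 2023).
#' @param rounding `"half_even"` (default) or `"half_away"`.
#' @return A `data.table`, one row per drug in descending total order:
#'   `drug`, `total_items`, `mean_annual`, `pct_female`, `top_month`, one
#'   `items_<year>` column per complete year, and (with population)
#'   `top_bands_female`, `top_bands_male` (semicolon-separated, descending
#'   rate).
#' @export
summarize_drugs <- function(records, calendar = study_calendar(), top_n = 20L,
                            population = NULL, band_year = 2023L,
                            rounding = c("half_even", "half_away")) {
  rounding <- match.arg(rounding)
  x <- data.table::as.data.table(records)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  x <- data.table::copy(x)
  p <- parse_period(x$period)
  x[, `:=`(year = period_year(p), month = period_month(p))]
  cy <- calendar$complete_years

  yearly <- x[year %in% cy, .(items = sum(items)), by = .(drug, year)]
  tot <- yearly[, .(total_items = sum(items)), by = drug]
  n_drugs <- nrow(tot)
  if (top_n > n_drugs) {
    warning("top_n = ", top_n, " exceeds the ", n_drugs,
            " drugs available; summarising all", call. = FALSE)
    top_n <- n_drugs
  }
  data.table::setorder(tot, -total_items, drug)
  top <- tot[seq_len(top_n)]

  fem <- x[year %in% cy & drug %in% top$drug,
           .(fem_items = sum(items[sex == "Female"]), all_items = sum(items)),
           by = drug]
  fem[, pct_female := 100 * fem_items / all_items]

  # top month over the WHOLE dataset (partial years included)
  bym <- x[drug %in% top$drug, .(items = sum(items)), by = .(drug, month)]
  data.table::setorder(bym, drug, -items, month)
  topm <- bym[, .(top_month = month[1L]), by = drug]

  out <- merge(top, fem[, .(drug, pct_female)], by = "drug")
  out <- merge(out, topm, by = "drug")
  out[, mean_annual := round_count(total_items / length(cy), rounding)]

  wide <- data.table::dcast(yearly[drug %in% top$drug], drug ~ year,
                            value.var = "items", fill = 0L)
  data.table::setnames(wide, as.character(cy), paste0("items_", cy),
                       skip_absent = TRUE)
  out <- merge(out, wide, by = "drug")

  if (!is.null(population)) {
    r <- compute_rates(x[drug %in% top$drug & year == band_year],
                       population, strata = c("drug", "age_band", "sex"))
    data.table::setorder(r, drug, sex, -rate, age_band)
    tb <- r[, .(bands = paste(utils::head(age_band, 3L), collapse = ";")),
            by = .(drug, sex)]
    tbw <- data.table::dcast(tb, drug ~ sex, value.var = "bands")
    data.table::setnames(tbw, c("Female", "Male"),
                         c("top_bands_female", "top_bands_male"),
                         skip_absent = TRUE)
    out <- merge(out, tbw, by = "drug", all.x = TRUE)
  }
  data.table::setorder(out, -total_items, drug)
  cols <- c("drug", "total_items", "mean_annual", "pct_female", "top_month")
  data.table::setcolorder(out, c(cols, setdiff(names(out), cols)))
  out[]
}

round_count <- function(x, rounding = "half_even") {
  if (rounding == "half_even") round(x)
  else sign(x) * floor(abs(x) + 0.5)
}

#' Headline counts from a drug-summary table
#'
#' The whole-cohort statements derivable from a top-N summary table: how many
#' drugs had fewer items in 2023 than in 2016, how many are female-majority,
#' the distribution of top months, and how many fell by at least 10% between
#' 2019 and 2023.
#'
#' Female majority at the printed-percentage level uses `pct_female >= 50`
#' (a drug printed at exactly 50% counts as female-majority, as published
#' summary tables mark it); with `female_rule = "strict"` the raw-level
#' `> 50` is used instead.
#'
#' @param summaries A [summarize_drugs()] table (or the packaged reference
#'   fixture, [load_table1()]); must carry `pct_female`, `top_month` and
#'   `items_2016`, `items_2019`, `items_2023`.
#' @param female_rule `"printed"` (default, `>= 50`) or `"strict"` (`> 50`).
#' @return An object of class `headline_counts`: list with `n_top`,
#'   `n_decreasing_2016_2023`, `n_female_majority`, `month_distribution`
#'   (named integer vector, names = month numbers),
#'   `n_reduction_ge_10pct_2019_2023`.
#' @export
headline_counts <- function(summaries, female_rule = c("printed", "strict")) {
  female_rule <- match.arg(female_rule)
  x <- data.table::as.data.table(summaries)
  needed <- c("pct_female", "top_month", "items_2016", "items_2019",
              "items_2023")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("summaries lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- x[is.na(items_2016) | is.na(items_2019) | is.na(items_2023), drug]
  if (length(bad))
    stop("missing yearly totals for drug(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  md <- table(factor(x$top_month, levels = 1:12))
  structure(list(
    n_top = nrow(x),
    n_decreasing_2016_2023 = sum(x$items_2023 < x$items_2016),
    n_female_majority = if (female_rule == "printed") sum(x$pct_female >= 50)
                        else sum(x$pct_female > 50),
    month_distribution = stats::setNames(as.integer(md), names(md)),
    n_reduction_ge_10pct_2019_2023 =
      sum((x$items_2019 - x$items_2023) / x$items_2019 >= 0.10)
  ), class = "headline_counts")
}

#' @export
print.headline_counts <- function(x, ...) {
  cat("Headline counts (top ", x$n_top, " drugs)\n", sep = "")
  cat("  fewer items in 2023 than 2016:  ", x$n_decreasing_2016_2023, "/",
      x$n_top, "\n", sep = "")
  cat("  female-majority:                ", x$n_female_majority, "/",
      x$n_top, "\n", sep = "")
  cat("  >=10% reduction 2019->2023:     ",
      x$n_reduction_ge_10pct_2019_2023, "/", x$n_top, "\n", sep = "")
  md <- x$month_distribution[x$month_distribution > 0]
  cat("  top months: ",
      paste(sprintf("%s=%d", month.abb[as.integer(names(md))], md),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Packaged top-20 reference summary
#'
#' A transcription of the published summary table for the 20 most prescribed
#' antibiotics in English primary care (complete years 2016-2023): totals,
#' printed mean annual items, percentage to females, top month, totals for
#' 2016/2019/2023 and top age bands per sex in 2023. Ships with the package
#' and backs the reproduction tests and the demo.
#'
#' @return A `data.table` in the same column layout as [summarize_drugs()].
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_top20.csv", package = "abxdemog")
  x <- data.table::fread(path, encoding = "UTF-8")
  data.table::setorder(x, -total_items)
  x[]
}
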