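#' Redaction-imputation sensitivity scan
#'
#' Suppressed cells hold a true count in 1-4; the main analysis substitutes
#' 1. This scan re-runs the female-majority summary across alternative
#' substitutions and scopes and reports, for each combination, the fraction
#' of drugs that are female-majority (rate in females strictly above rate in
#' males) in at least 50%, 75% and 90% of their age bands. Bands where both
#' sexes have zero items are excluded from a drug's band denominator —
#' counting undefined comparisons would bias against female majority. The
#' baseline row (value 1, scope `all`) is always included.
#'
#' @param records Raw canonical record table, redacted cells still `NA`.
#' @param population Population table ([read_population()]).
#' @param values Imputation values to scan (default `c(1, 4)`).
#' @param scopes Scopes to scan (default all three).
#' @param year Optional calendar year to restrict to (e.g. 2023); `NULL`
#'   pools all years.
#' @param thresholds Band-majority fractions reported (fixed columns for
#'   0.50/0.75/0.90).
#' @return A `data.table`, one row per (value, scope): `value`, `scope`,
#'   `n_drugs`, `frac_female_majority_50`, `frac_female_majority_75`,
#'   `frac_female_majority_90`.
#' @export
sensitivity_scan <- function(records, population, values = c(1L, 4L),
                             scopes = c("all", "males_only", "children_only"),
                             year = NULL, thresholds = c(0.5, 0.75, 0.9)) {
  x <- data.table::as.data.table(records)
  if (!is.null(year)) {
    x <- x[period_year(parse_period(period)) == year]
    if (!nrow(x)) stop("no records in year ", year, call. = FALSE)
  }
  combos <- data.table::CJ(value = as.integer(values), scope = scopes,
                           unique = TRUE)
  base <- data.table::data.table(value = 1L, scope = "all")
  combos <- unique(rbind(base, combos))

  rows <- lapply(seq_len(nrow(combos)), function(i) {
    v <- combos$value[i]; sc <- combos$scope[i]
    imp <- impute_redacted(x, value = v, scope = sc)
    rt <- compute_rates(imp, population,
                        strata = c("drug", "age_band", "sex"),
                        zero_fill = TRUE)
    rt <- rt[!is.na(rate)]
    ct <- sex_contrast(rt)
    ct <- ct[!(both_zero)]
    per_drug <- ct[, .(frac_bands = mean(female_majority)), by = drug]
    data.table::data.table(
      value = v, scope = sc, n_drugs = nrow(per_drug),
      frac_female_majority_50 = mean(per_drug$frac_bands >= thresholds[1]),
      frac_female_majority_75 = mean(per_drug$frac_bands >= thresholds[2]),
      frac_female_majority_90 = mean(per_drug$frac_bands >= thresholds[3]))
  })
  data.table::rbindlist(rows)
}
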