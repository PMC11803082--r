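#' Updated Comparison Metric (UCM) age-sex prescribing weights
#'
#' Computes STAR-PU-style weights at the full 23-band resolution: the weight
#' of each (age band, sex) cell is its per-capita prescribing rate in the
#' reference year divided by the rate in the baseline cell, females aged
#' 66-70 by default (a subset of the classic STAR-PU 65-74 female baseline).
#' A weight of X reads: an average individual in that cell receives X times
#' the antibiotics of the baseline group. Weights may be computed over all
#' prescriptions ("overall") or restricted to one BNF drug family
#' ("UCM-family"). Weights are clamped to `[floor, cap]`
#' (default `[0.01, 100]`), and child bands (up to `16-20`) with no items at
#' all receive the substitute value 0.01 — in sparse families children are
#' the only cells that can be empty.
#'
#' Weights are computed on the pooled (national) data and then applied to
#' regional populations with [apply_ucm()]; this mirrors STAR-PU practice.
#'
#' @param records De-redacted canonical record table.
#' @param population Population table ([read_population()]) covering `year`.
#' @param year Reference calendar year (default 2023).
#' @param baseline Length-2 character vector `c(age_band, sex)` of the
#'   baseline cell; its weight is exactly 1.
#' @param family `NULL` for the overall UCM, or a BNF family name for a
#'   family-specific weighting.
#' @param floor,cap Clamp bounds for the weights.
#' @param child_substitute Weight assigned to zero-item child bands.
#' @param child_max_age Bands with lower bound `<= child_max_age` count as
#'   child bands for the substitute rule (default 16, i.e. bands `0-1`
#'   through `16-20`).
#' @param clamp_zero If `TRUE`, a zero-item non-child cell gets the floor
#'   weight instead of raising an error.
#' @return An object of class `ucm_weights`: the weight table plus the
#'   parameters used.
#' @export
compute_ucm_weights <- function(records, population, year = 2023L,
                                baseline = c("66–70", "Female"),
                                family = NULL, floor = 0.01, cap = 100,
                                child_substitute = 0.01, child_max_age = 16,
                                clamp_zero = FALSE) {
  x <- data.table::as.data.table(records)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  if (!is.null(family)) {
    sel <- x$family == family  # select outside [] so the argument isn't masked
    x <- x[sel]
  }
  if (!nrow(x)) stop("no records", if (!is.null(family))
    paste0(" for family ", sQuote(family)), call. = FALSE)
  x <- x[period_year(parse_period(period)) == year]
  if (!nrow(x)) stop("no records in year ", year, call. = FALSE)

  base_band <- parse_age_band(baseline[1])$label
  items <- x[sex %in% c("Female", "Male"),
             .(items = sum(items)), by = .(age_band, sex)]
  pop <- data.table::as.data.table(population)
  sel_pop <- pop$year == year & pop$sex %in% c("Female", "Male")
  pop <- pop[sel_pop, .(population = sum(count)), by = .(age_band, sex)]
  if (!nrow(pop)) stop("population table has no rows for year ", year,
                       call. = FALSE)

  cells <- merge(pop, items, by = c("age_band", "sex"), all.x = TRUE)
  cells[is.na(items), items := 0L]
  cells[, rate := items / population]
  base <- cells[age_band == base_band & sex == baseline[2]]
  if (nrow(base) != 1L || base$items == 0L || base$population == 0L)
    stop("baseline cell (", baseline[1], ", ", baseline[2],
         ") has no items or no population; weighting undefined",
         call. = FALSE)

  child <- child_bands_lower(child_max_age)
  cells[, weight := rate / base$rate]
  zero_cells <- cells$items == 0L
  cells[zero_cells & age_band %in% child, weight := child_substitute]
  bad <- zero_cells & !cells$age_band %in% child
  if (any(bad) && !clamp_zero)
    stop("zero items in non-child cell(s): ",
         paste(cells[bad, paste0(age_band, "/", sex)], collapse = ", "),
         "; set clamp_zero = TRUE to assign the floor weight", call. = FALSE)
  cells[bad, weight := floor]
  cells[, weight := pmin(pmax(weight, floor), cap)]

  w <- cells[, .(age_band, sex, weight)]
  ord <- age_band_table()$label
  w[, age_band := factor(age_band, levels = ord)]
  data.table::setorder(w, age_band, sex)
  w[, age_band := as.character(age_band)]
  structure(list(weights = w[],
                 baseline = c(age_band = base_band, sex = baseline[2]),
                 family = if (is.null(family)) NA_character_ else family,
                 year = as.integer(year), floor = floor, cap = cap,
                 child_substitute = child_substitute),
            class = "ucm_weights")
}

# bands whose lower bound is <= max_age (the "children up to 16" rule)
child_bands_lower <- function(max_age) {
  bands <- age_band_table()
  bands$label[bands$lower <= max_age]
}

#' @export
print.ucm_weights <- function(x, ...) {
  cat("UCM weights (",
      if (is.na(x$family)) "overall" else paste0("family: ", x$family),
      ", year ", x$year, ")\n", sep = "")
  cat("  baseline: ", x$baseline[["sex"]], " ", x$baseline[["age_band"]],
      "; clamp [", x$floor, ", ", x$cap, "]\n", sep = "")
  print(x$weights, nrows = 12)
  invisible(x)
}

#' @export
summary.ucm_weights <- function(object, ...) {
  w <- object$weights
  cat("UCM weight summary (",
      if (is.na(object$family)) "overall" else object$family, ")\n", sep = "")
  cat("  range:", paste(signif(range(w$weight), 3), collapse = " to "), "\n")
  top <- w[order(-weight)][1:3]
  cat("  highest:", paste(sprintf("%s %s (%.2f)", top$sex, top$age_band,
                                  top$weight), collapse = ", "), "\n")
  invisible(w)
}

#' @export
format.ucm_weights <- function(x, ...) {
  w <- data.table::copy(x$weights)
  w[, family := if (is.na(x$family)) "overall" else x$family]
  w[]
}

#' Apply UCM weights to regional populations
#'
#' The weighted population of a region is the sum over (band, sex) cells of
#' weight x population; the region's metric is its total items per weighted
#' person. Two regions with identical age/sex rate structure get equal
#' metrics regardless of size.
#'
#' @param weights A `ucm_weights` object.
#' @param population_by_region Population table with a `region` column, for
#'   the weights' reference year.
#' @param items_by_region Named numeric vector or two-column
#'   `data.frame`/`data.table` (`region`, `items`) of total items per region.
#' @return A `data.table` with columns `region`, `weighted_population`,
#'   `items`, `metric` (unranked; see [rank_regions()]).
#' @export
apply_ucm <- function(weights, population_by_region, items_by_region) {
  stopifnot(inherits(weights, "ucm_weights"))
  pop <- data.table::as.data.table(population_by_region)
  if ("year" %in% names(pop)) pop <- pop[pop$year == weights$year]
  pop <- pop[sex %in% c("Female", "Male"),
             .(count = sum(count)), by = .(region, age_band, sex)]
  if (is.data.frame(items_by_region)) {
    it <- data.table::as.data.table(items_by_region)[, .(region, items)]
  } else {
    it <- data.table::data.table(region = names(items_by_region),
                                 items = as.numeric(items_by_region))
  }
  missing_pop <- setdiff(it$region, unique(pop$region))
  if (length(missing_pop))
    stop("region(s) in items but absent from population: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  w <- merge(pop, weights$weights, by = c("age_band", "sex"))
  if (nrow(w) < nrow(pop))
    stop("weights are missing (band, sex) cells present in the population",
         call. = FALSE)
  wp <- w[, .(weighted_population = sum(count * weight)), by = region]
  out <- merge(wp, it, by = "region")
  out[, metric := items / weighted_population]
  out[]
}

#' Rank regions on a UCM metric
#'
#' Descending sort by metric (rank 1 = highest prescriber), ties broken by
#' ascending region code for deterministic output. With 42 regions (the
#' English ICBs) the published grouping applies: ranks 1-10, 11-20, 21-30 and
#' 31-42 form groups 1-4; other region counts get proportional cut points at
#' `ceiling(n * c(10, 20, 30) / 42)`.
#'
#' @param metrics Output of [apply_ucm()].
#' @return The same table with `rank` and `quartile_group` columns, sorted by
#'   rank.
#' @export
rank_regions <- function(metrics) {
  x <- data.table::copy(data.table::as.data.table(metrics))
  if (!nrow(x)) stop("no regions to rank", call. = FALSE)
  data.table::setorder(x, -metric, region)
  x[, rank := seq_len(.N)]
  n <- nrow(x)
  cuts <- ceiling(n * c(10, 20, 30) / 42)
  x[, quartile_group := 1L + (rank > cuts[1]) + (rank > cuts[2]) +
      (rank > cuts[3])]
  x[]
}
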