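#' Load an AWaRe category map
#'
#' Reads a drug -> category table (categories `Access`, `Watch`, `Reserve`;
#' anything a dataset contains that the table does not resolves to
#' `Unclassified`, explicitly) plus an optional overrides table of manual
#' matches for names that differ between the prescribing data and the
#' reference (e.g. salt suffixes). The package ships a curated reference
#' covering common English primary-care antibiotics at
#' `system.file("extdata", "aware_map.csv", package = "abxdemog")`.
#'
#' @param map Path to a CSV with columns `drug`, `category`, or a
#'   `data.frame` of the same shape. Defaults to the packaged table.
#' @param overrides Optional path/`data.frame` with columns `source_name`,
#'   `reference_name` mapping dataset spellings onto reference spellings.
#' @return An object of class `aware_map`.
#' @export
read_aware_map <- function(map = system.file("extdata", "aware_map.csv",
                                             package = "abxdemog"),
                           overrides = NULL) {
  m <- if (is.data.frame(map)) data.table::as.data.table(map)
       else data.table::fread(map, encoding = "UTF-8")
  if (!all(c("drug", "category") %in% names(m)))
    stop("AWaRe map needs columns drug, category", call. = FALSE)
  ok <- c("Access", "Watch", "Reserve", "Unclassified")
  if (!all(m$category %in% ok))
    stop("unknown AWaRe categories: ",
         paste(setdiff(unique(m$category), ok), collapse = ", "),
         call. = FALSE)
  ov <- NULL
  if (!is.null(overrides)) {
    ov <- if (is.data.frame(overrides)) data.table::as.data.table(overrides)
          else data.table::fread(overrides, encoding = "UTF-8")
    if (!all(c("source_name", "reference_name") %in% names(ov)))
      stop("overrides need columns source_name, reference_name",
           call. = FALSE)
    key <- norm_drug_name(ov$source_name)
    dup <- duplicated(key) &
      !duplicated(paste(key, norm_drug_name(ov$reference_name)))
    if (any(dup))
      stop("conflicting overrides for: ",
           paste(unique(ov$source_name[dup]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(entries = m[, .(drug, category)], overrides = ov),
            class = "aware_map")
}

#' @export
print.aware_map <- function(x, ...) {
  cat("AWaRe map:", nrow(x$entries), "drugs (",
      paste(names(table(x$entries$category)),
            table(x$entries$category), collapse = ", "), ")\n")
  if (!is.null(x$overrides))
    cat("  manual matches:", nrow(x$overrides), "\n")
  invisible(x)
}

norm_drug_name <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Resolve drugs to AWaRe categories
#'
#' Exact-name match against the reference first (case-insensitive, after
#' whitespace normalization), then via the manual-match override table, else
#' `Unclassified`.
#'
#' @param drugs Character vector of drug names.
#' @param map An [read_aware_map()] object.
#' @return Named character vector: drug -> category.
#' @export
resolve_categories <- function(drugs, map) {
  stopifnot(inherits(map, "aware_map"))
  key <- norm_drug_name(map$entries$drug)
  q <- norm_drug_name(drugs)
  cat_ <- map$entries$category[match(q, key)]
  if (!is.null(map$overrides)) {
    miss <- is.na(cat_)
    ref <- map$overrides$reference_name[
      match(q[miss], norm_drug_name(map$overrides$source_name))]
    cat_[miss] <- map$entries$category[match(norm_drug_name(ref), key)]
  }
  cat_[is.na(cat_)] <- "Unclassified"
  stats::setNames(cat_, drugs)
}

#' AWaRe category shares and Access targets by stratum
#'
#' Item-weighted share of each AWaRe category within each stratum, with
#' boolean flags for the 60% (former WHO), 70% (UN General Assembly) and 80%
#' (ambitious oral-use) Access targets. Unclassified drugs stay in the
#' denominator: the targets are fractions of total consumption, and dropping
#' unmatched drugs would inflate the Access share.
#'
#' @param records De-redacted canonical record table.
#' @param map An [read_aware_map()] object.
#' @param strata Dimensions to stratify by (default `age_band`, `sex`,
#'   `year`); use `character(0)` for one pooled row.
#' @param drop_unclassified If `TRUE`, unmatched drugs are excluded from the
#'   denominator instead (not the default, see above).
#' @return A `data.table`: stratum columns, `n_items`, one `share_*` column
#'   per category present, `share_Access`, and `meets_60`, `meets_70`,
#'   `meets_80`.
#' @export
aware_breakdown <- function(records, map,
                            strata = c("age_band", "sex", "year"),
                            drop_unclassified = FALSE) {
  x <- data.table::as.data.table(records)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  x <- data.table::copy(x)
  x[, year := period_year(parse_period(period))]
  lk <- resolve_categories(unique(x$drug), map)
  x[, category := unname(lk[drug])]
  if (drop_unclassified) x <- x[category != "Unclassified"]

  shares <- x[, .(cat_items = sum(items)), by = c(strata, "category")]
  if (length(strata)) {
    tot <- x[, .(n_items = sum(items)), by = strata]
    shares <- merge(shares, tot, by = strata)
  } else {
    shares[, n_items := sum(x$items)]
  }
  shares[, share := cat_items / n_items]
  form <- if (length(strata))
    paste(paste(c(strata, "n_items"), collapse = " + "), "~ category")
  else "n_items ~ category"
  wide <- data.table::dcast(shares, form, value.var = "share", fill = 0)
  cats <- intersect(c("Access", "Watch", "Reserve", "Unclassified"),
                    names(wide))
  data.table::setnames(wide, cats, paste0("share_", cats))
  if (!"share_Access" %in% names(wide)) wide[, share_Access := 0]
  wide[, `:=`(meets_60 = share_Access >= 0.60,
              meets_70 = share_Access >= 0.70,
              meets_80 = share_Access >= 0.80)]
  if (length(strata)) data.table::setorderv(wide, strata)
  wide[]
}
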