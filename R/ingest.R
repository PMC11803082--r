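#' Read a disaggregated prescription extract
#'
#' Parses a delimited text extract (comma or tab separated, UTF-8) into the
#' canonical record table: one row per (month, drug, family, age band, sex,
#' region) cell with an item count. Cells suppressed at source (fewer than
#' five items, marked `"*"` by default) are read as redacted and carried as
#' `NA` in the `items` column until [impute_redacted()] assigns them a value.
#'
#' Malformed rows (unparseable period, zero / negative / non-integer item
#' counts, band labels outside the 23-band scheme) are never silently
#' dropped: they are collected into a rejects table attached as
#' `attr(x, "rejects")`, with one reason per row, so that FOI-style extracts
#' remain auditable. Missing or unparseable demographic *categories*
#' (`"Unknown"`, empty) are not rejects: they become the `Unknown` level and
#' are handled by [apply_exclusions()].
#'
#' @param source Path to a delimited file, or a `data.frame` already in
#'   memory.
#' @param col_map Named character vector mapping canonical column names
#'   (`period`, `drug`, `family`, `age_band`, `sex`, `region`, `items`) to
#'   the header names used in `source`.
#' @param redaction_marker String marking suppressed counts (default `"*"`).
#' @return A `data.table` with columns `period` (`"YYYY-MM"`), `drug`,
#'   `family`, `age_band` (canonical label or `"Unknown"`), `sex`
#'   (`Female`/`Male`/`Indeterminate`/`Unknown`), `region`, `items` (integer,
#'   `NA` = redacted). Input row order is preserved. Rejected rows are in
#'   `attr(, "rejects")`.
#' @seealso [write_records()] for the inverse; the pair round-trips all
#'   non-rejected rows losslessly.
#' @export
read_prescriptions <- function(source,
                               col_map = c(period = "period", drug = "drug",
                                           family = "family",
                                           age_band = "age_band", sex = "sex",
                                           region = "region", items = "items"),
                               redaction_marker = "*") {
  needed <- c("period", "drug", "family", "age_band", "sex", "region", "items")
  if (!all(needed %in% names(col_map)))
    stop("col_map must name columns: ",
         paste(setdiff(needed, names(col_map)), collapse = ", "), call. = FALSE)
  raw <- if (is.data.frame(source)) data.table::as.data.table(source)
         else data.table::fread(source, colClasses = "character",
                                na.strings = NULL, encoding = "UTF-8")
  missing_cols <- setdiff(unname(col_map[needed]), names(raw))
  if (length(missing_cols))
    stop("input is missing mandatory column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)

  x <- raw[, unname(col_map[needed]), with = FALSE]
  data.table::setnames(x, needed)
  for (j in needed) data.table::set(x, j = j, value = as.character(x[[j]]))
  n <- nrow(x)
  reason <- rep(NA_character_, n)

  # period
  pm <- regexec("^\\s*(\\d{4})[-/](\\d{1,2})\\s*$", x$period)
  ok_period <- vapply(regmatches(x$period, pm), length, 1L) == 3L
  mo <- suppressWarnings(as.integer(sub("^\\s*\\d{4}[-/](\\d{1,2})\\s*$", "\\1",
                                        x$period)))
  ok_period <- ok_period & !is.na(mo) & mo >= 1L & mo <= 12L
  reason[!ok_period] <- "malformed period"

  # items: integer >= 1, or the redaction marker
  it <- trimws(x$items)
  redacted <- it == redaction_marker
  items_num <- suppressWarnings(as.numeric(it))
  ok_items <- redacted |
    (!is.na(items_num) & items_num >= 1 & items_num == floor(items_num))
  reason[is.na(reason) & !ok_items] <-
    ifelse(!is.na(items_num[is.na(reason) & !ok_items]) &
             items_num[is.na(reason) & !ok_items] < 1,
           "item count below 1", "non-integer item count")

  # age band: canonical scheme, or the Unknown category
  band_in <- trimws(x$age_band)
  band_canon <- canonical_band(band_in)
  band_unknown <- band_in %in% c("", "Unknown", "unknown", "UNKNOWN", "NA")
  ok_band <- !is.na(band_canon) | band_unknown
  reason[is.na(reason) & !ok_band] <- "unknown age band label"

  sex_norm <- normalize_sex(x$sex)

  keep <- is.na(reason)
  rejects <- raw[!keep]
  if (nrow(rejects)) rejects[, reject_reason := reason[!keep]]

  out <- data.table::data.table(
    period = sprintf("%04d-%02d",
                     as.integer(substr(trimws(x$period[keep]), 1L, 4L)),
                     mo[keep]),
    drug = trimws(x$drug[keep]),
    family = trimws(x$family[keep]),
    age_band = ifelse(band_unknown[keep], "Unknown", band_canon[keep]),
    sex = sex_norm[keep],
    region = trimws(x$region[keep]),
    items = ifelse(redacted[keep], NA_integer_,
                   as.integer(items_num[keep]))
  )
  data.table::setattr(out, "rejects", rejects)
  out[]
}

normalize_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("Unknown", length(x))
  out[x %in% c("female", "f")] <- "Female"
  out[x %in% c("male", "m")] <- "Male"
  out[x %in% c("indeterminate", "i")] <- "Indeterminate"
  out
}

#' Write a canonical record table as delimited text
#'
#' Fixed column order (period, drug, family, age_band, sex, region, items);
#' redacted cells are written as the marker, so write-then-read is lossless.
#'
#' @param records Canonical record table.
#' @param path Output file path.
#' @param redaction_marker Marker for redacted (`NA`) items.
#' @export
write_records <- function(records, path, redaction_marker = "*") {
  x <- data.table::as.data.table(records)[
    , c("period", "drug", "family", "age_band", "sex", "region", "items"),
    with = FALSE]
  x[, items := ifelse(is.na(items), redaction_marker, as.character(items))]
  data.table::fwrite(x, path)
  invisible(path)
}

#' Apply the study's exclusion rules
#'
#' Removes (i) records with unknown age band or unknown sex, (ii) records for
#' patients of Indeterminate sex, and (iii) all records of drugs prescribed
#' fewer than `rare_threshold` items per year on average over the complete
#' calendar years (redacted cells counted at `impute_value`). Demographic
#' exclusions are applied before the rare-drug rule. Everything removed is
#' accounted for in the returned report.
#'
#' @param records Canonical record table (may contain redacted cells).
#' @param rare_threshold Mean items per complete year below which a drug is
#'   dropped (default 10).
#' @param calendar A [study_calendar()]; its `complete_years` define the
#'   rare-drug averaging window.
#' @param impute_value Value at which redacted cells are counted when
#'   averaging (default 1).
#' @return A list: `records` (filtered table) and `report`, an
#'   `exclusion_report` with the counts, the unknown-demographics item
#'   fraction, and the drugs dropped as rare.
#' @export
apply_exclusions <- function(records, rare_threshold = 10,
                             calendar = study_calendar(), impute_value = 1L) {
  x <- data.table::as.data.table(records)
  items_acc <- ifelse(is.na(x$items), as.integer(impute_value), x$items)
  total_items <- sum(items_acc)

  unknown <- x$age_band == "Unknown" | x$sex == "Unknown"
  indet <- !unknown & x$sex == "Indeterminate"
  report <- structure(list(
    n_unknown_demographics = sum(unknown),
    pct_unknown = if (total_items > 0) sum(items_acc[unknown]) / total_items
                  else 0,
    n_indeterminate = sum(indet),
    drugs_dropped_rare = character(0),
    threshold_rare = rare_threshold
  ), class = "exclusion_report")

  x <- x[!unknown & !indet]
  if (nrow(x)) {
    yr <- period_year(parse_period(x$period))
    acc <- ifelse(is.na(x$items), as.integer(impute_value), x$items)
    in_cy <- yr %in% calendar$complete_years
    tot <- tapply(acc[in_cy], x$drug[in_cy], sum)
    mean_by_drug <- tot / length(calendar$complete_years)
    rare <- names(mean_by_drug)[mean_by_drug < rare_threshold]
    # drugs absent from complete years altogether have mean 0
    rare <- union(rare, setdiff(unique(x$drug), names(mean_by_drug)))
    report$drugs_dropped_rare <- sort(rare)
    x <- x[!drug %in% rare]
  }
  list(records = x[], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  unknown age/sex records: %d (%.2f%% of items)\n",
              x$n_unknown_demographics, 100 * x$pct_unknown))
  cat("  indeterminate-sex records:", x$n_indeterminate, "\n")
  cat(sprintf("  rare drugs dropped (< %g items/year): %d\n",
              x$threshold_rare, length(x$drugs_dropped_rare)))
  if (length(x$drugs_dropped_rare))
    cat("   ", paste(x$drugs_dropped_rare, collapse = ", "), "\n")
  invisible(x)
}

#' Impute redacted item counts
#'
#' Suppressed cells hold a true count in 1-4. The main analysis assigns them
#' 1; sensitivity analyses re-assign 4 within a scope (everyone, males only,
#' or children only, i.e. under-20s), with cells outside the scope keeping
#' the default.
#'
#' @param records Canonical record table with `NA` items for redacted cells.
#' @param value Integer in 1..4 assigned to redacted cells inside `scope`.
#' @param scope One of `"all"`, `"males_only"`, `"children_only"`.
#' @param default Value for redacted cells outside the scope (default 1).
#' @return The record table with no `NA` items.
#' @export
impute_redacted <- function(records, value = 1L,
                            scope = c("all", "males_only", "children_only"),
                            default = 1L) {
  scope <- match.arg(scope)
  value <- as.integer(value)
  if (is.na(value) || value < 1L || value > 4L)
    stop("imputation value must be an integer in 1..4", call. = FALSE)
  x <- data.table::copy(data.table::as.data.table(records))
  in_scope <- switch(scope,
    all = rep(TRUE, nrow(x)),
    males_only = x$sex == "Male",
    children_only = x$age_band %in% child_bands(20))
  x[is.na(items), items := ifelse(in_scope[is.na(x$items)],
                                  value, as.integer(default))]
  x[]
}

#' Keep only listed regions
#'
#' The source extracts mix English ICBs with some Welsh practices and a
#' national aggregate (region code `"ENGLAND"`); analyses restrict to a
#' keep-list.
#'
#' @param records Canonical record table.
#' @param keep Character vector of region codes to retain.
#' @export
filter_regions <- function(records, keep) {
  data.table::as.data.table(records)[region %in% keep]
}

#' Collapse old-age bands for reporting
#'
#' Optionally re-bands everything from a lower bound upwards (default 86)
#' into a single open band, as summary tables sometimes present. This is a
#' presentation choice, not part of the analysis scheme.
#'
#' @param records Canonical record table.
#' @param min_lower Collapse bands whose lower bound is `>= min_lower`.
#' @param label Label of the collapsed band.
#' @export
collapse_age_bands <- function(records, min_lower = 86, label = "86+") {
  bands <- age_band_table()
  tall <- bands$label[bands$lower >= min_lower]
  x <- data.table::copy(data.table::as.data.table(records))
  x[age_band %in% tall, age_band := label]
  x[]
}
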