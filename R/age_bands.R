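#' Canonical 23-band age scheme
#'
#' The NHSBSA extracts disaggregate patient age into 23 bands: \code{"0-1"},
#' \code{"2-5"}, then 5-year bands \code{"6-10"} up to \code{"101-105"}, and a
#' terminal open band \code{"105+"}. Together the bands partition the
#' non-negative integers. Labels are stored with an en dash, matching the
#' source data; [parse_age_band()] accepts ASCII hyphens too.
#'
#' @return A `data.table` with columns `label`, `lower`, `upper`
#'   (`upper = Inf` for the open band), one row per band in ascending age
#'   order.
#' @export
#' @examples
#' age_band_table()
age_band_table <- function() {
  # the terminal open band starts at 106: "101–105" already covers age 105,
  # so "105+" is read as "older than 105" to keep the bands disjoint
  lower <- c(0L, 2L, seq(6L, 101L, by = 5L), 106L)
  upper <- c(1L, 5L, seq(10L, 105L, by = 5L), Inf)
  label <- c("0–1", "2–5",
             paste0(seq(6L, 101L, by = 5L), "–", seq(10L, 105L, by = 5L)),
             "105+")
  data.table::data.table(label = label, lower = as.numeric(lower),
                         upper = as.numeric(upper))
}

# dash/whitespace dialects seen in extracts: en dash, em dash, hyphen, minus
normalize_band_label <- function(label) {
  x <- gsub("[‒–—−-]", "–", trimws(label))
  gsub("[[:space:]]+", "", x)
}

#' Parse an age-band label into its numeric bounds
#'
#' Accepts hyphen/en-dash and whitespace variants of the canonical 23-band
#' labels; any other label is an error (silent coercion of unexpected bands
#' would corrupt downstream denominators).
#'
#' @param label Character vector of band labels.
#' @return A `data.table` with columns `label` (canonical form), `lower`,
#'   `upper`, one row per input element.
#' @export
#' @examples
#' parse_age_band(c("0-1", "66-70", "105+"))
parse_age_band <- function(label) {
  if (length(label) == 0L || any(!nzchar(trimws(label))))
    stop("age band label must be non-empty", call. = FALSE)
  bands <- age_band_table()
  idx <- match(normalize_band_label(label), bands$label)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown age band label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  bands[idx]
}

#' @rdname parse_age_band
#' @details `canonical_band()` returns only the canonical label (or `NA` for
#'   labels outside the scheme), which is convenient for vectorised cleaning
#'   where unknown labels should be handled by the caller.
#' @export
canonical_band <- function(label) {
  bands <- age_band_table()
  bands$label[match(normalize_band_label(label), bands$label)]
}

#' Age bands counted as children
#'
#' Two child scopes recur in the analysis: redaction-imputation
#' "children only" means under-20s (bands `0-1` through `16-20`, the band
#' containing age 19), and the UCM zero-cell substitute applies to bands up to
#' age 16 (also `0-1` through `16-20`, the band containing 16, since band
#' edges do not align with 16 exactly).
#'
#' @param max_upper Keep bands whose upper bound is `<= max_upper`
#'   (default 20).
#' @return Character vector of band labels.
#' @export
child_bands <- function(max_upper = 20) {
  bands <- age_band_table()
  bands$label[bands$upper <= max_upper]
}

#' Map analysis age groups to canonical bands
#'
#' The influenza-vaccination analysis uses coarser groups aligned to vaccine
#' eligibility: `0-1`, `2-5`, `5-10`, `11-15`, `15-50`, `50-65`, `65+`. Group
#' edges quoted in eligibility schedules do not align with the 23-band scheme;
#' each group is built from whole canonical bands (`5-10` maps to band `6-10`,
#' `15-50` to `16-20` .. `46-50`, `50-65` to `51-55` .. `61-65`, `65+` to
#' `66-70` and above), so ages 2-5 are never double counted.
#'
#' @return Named list: analysis group label -> character vector of canonical
#'   band labels.
#' @export
flu_age_groups <- function() {
  bands <- age_band_table()
  list(
    "0–1"   = "0–1",
    "2–5"   = "2–5",
    "5–10"  = "6–10",
    "11–15" = "11–15",
    "15–50" = bands$label[bands$lower >= 16 & bands$upper <= 50],
    "50–65" = bands$label[bands$lower >= 51 & bands$upper <= 65],
    "65+"        = bands$label[bands$lower >= 66]
  )
}
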