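#' Study calendar: COVID window, complete years, influenza season
#'
#' Bundles the date windows the analysis conditions on. Defaults follow the
#' English primary-care extract: data run April 2015 to December 2023; the
#' COVID-19 disruption window is March 2020 to June 2022 inclusive; complete
#' calendar years are 2016-2023; the influenza season runs 1 October to
#' 30 March (at monthly resolution the whole of March is included).
#'
#' @param covid_start,covid_end First and last months of the COVID window,
#'   `"YYYY-MM"`.
#' @param data_start,data_end First and last months with data, `"YYYY-MM"`.
#' @param complete_years Integer vector of calendar years fully covered.
#' @param flu_season_months Integer months belonging to the influenza season
#'   (October-December count towards the season starting that year,
#'   January-March towards the season started the previous year).
#' @return An object of class `study_calendar`.
#' @export
study_calendar <- function(covid_start = "2020-03", covid_end = "2022-06",
                           data_start = "2015-04", data_end = "2023-12",
                           complete_years = 2016:2023,
                           flu_season_months = c(10L, 11L, 12L, 1L, 2L, 3L)) {
  cs <- parse_period(covid_start); ce <- parse_period(covid_end)
  if (cs > ce) stop("covid_start must not be after covid_end", call. = FALSE)
  structure(list(covid_start = cs, covid_end = ce,
                 data_start = parse_period(data_start),
                 data_end = parse_period(data_end),
                 complete_years = as.integer(complete_years),
                 flu_season_months = as.integer(flu_season_months)),
            class = "study_calendar")
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("Study calendar\n")
  cat("  data:          ", format_period(x$data_start), "to",
      format_period(x$data_end), "\n")
  cat("  COVID window:  ", format_period(x$covid_start), "to",
      format_period(x$covid_end), "\n")
  cat("  complete years:", paste(range(x$complete_years), collapse = "-"), "\n")
  invisible(x)
}

# periods are held internally as integer month indices (year*12 + month - 1)
# so window comparisons are plain integer comparisons
parse_period <- function(x) {
  if (is.numeric(x) && all(x == as.integer(x))) return(as.integer(x))
  m <- regmatches(x, regexec("^\\s*(\\d{4})[-/](\\d{1,2})\\s*$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed period(s): ", paste(sQuote(x[bad]), collapse = ", "),
         call. = FALSE)
  yr <- as.integer(vapply(m, `[`, "", 2L))
  mo <- as.integer(vapply(m, `[`, "", 3L))
  if (any(mo < 1L | mo > 12L))
    stop("month out of range in period(s): ",
         paste(sQuote(x[mo < 1L | mo > 12L]), collapse = ", "), call. = FALSE)
  yr * 12L + mo - 1L
}

format_period <- function(p) sprintf("%d-%02d", p %/% 12L, p %% 12L + 1L)

period_year <- function(p) p %/% 12L
period_month <- function(p) p %% 12L + 1L

in_covid_window <- function(p, calendar) {
  p >= calendar$covid_start & p <= calendar$covid_end
}

# influenza season containing period p: Oct-Dec -> that year, Jan-Mar -> the
# previous year's season; Apr-Sep -> NA (outside any season)
flu_season_of <- function(p) {
  m <- period_month(p); y <- period_year(p)
  out <- rep(NA_integer_, length(p))
  out[m >= 10L] <- y[m >= 10L]
  out[m <= 3L] <- y[m <= 3L] - 1L
  out
}
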