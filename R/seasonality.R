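#' Pre-COVID monthly profile of a drug
#'
#' National item totals for one drug are summed per calendar month (over all
#' ages, sexes and regions in the table), restricted to the pre-COVID window
#' (data start up to the month before the COVID window opens), then averaged
#' within each of the 12 calendar months across the years observed. Months
#' falling inside the COVID window never contribute. The profile's overall
#' mean is the mean of the 12 month means, so incomplete years do not weight
#' some months more than others.
#'
#' @param records De-redacted canonical record table.
#' @param drug Drug name (one of `records$drug`).
#' @param calendar A [study_calendar()].
#' @param overall One of `"mean_of_month_means"` (default) or
#'   `"mean_of_raw_months"`; the two differ only when years are incomplete.
#' @return An object of class `monthly_profile`: list with `drug`,
#'   `month_means` (length-12 numeric, January first), `overall_mean`,
#'   `years_used`.
#' @export
monthly_profile <- function(records, drug, calendar = study_calendar(),
                            overall = c("mean_of_month_means",
                                        "mean_of_raw_months")) {
  overall <- match.arg(overall)
  x <- data.table::as.data.table(records)
  sel <- x$drug == drug  # select outside [] so the argument isn't masked
  x <- x[sel]
  if (!nrow(x)) stop("drug not present in records: ", sQuote(drug),
                     call. = FALSE)
  if (anyNA(x$items))
    stop("records contain redacted items; run impute_redacted() first",
         call. = FALSE)
  p <- parse_period(x$period)
  pre <- p >= calendar$data_start & p < calendar$covid_start
  x <- x[pre]; p <- p[pre]
  monthly <- x[, .(total = sum(items)),
               by = .(year = period_year(p), month = period_month(p))]
  if (length(unique(monthly$month)) < 12L)
    stop("profile undefined: only ", length(unique(monthly$month)),
         " distinct calendar months observed pre-COVID for ", sQuote(drug),
         call. = FALSE)
  mm <- monthly[, .(m = mean(total)), by = month]
  month_means <- rep(NA_real_, 12L)
  month_means[mm$month] <- mm$m
  overall_mean <- if (overall == "mean_of_month_means") mean(month_means)
                  else mean(monthly$total)
  structure(list(drug = drug, month_means = month_means,
                 overall_mean = overall_mean,
                 years_used = sort(unique(monthly$year))),
            class = "monthly_profile")
}

#' @export
print.monthly_profile <- function(x, ...) {
  cat("Monthly profile:", x$drug, "\n")
  cat("  years:", paste(range(x$years_used), collapse = "-"),
      " overall mean:", format(x$overall_mean, big.mark = ","), "\n")
  print(stats::setNames(round(x$month_means, 1), month.abb))
  invisible(x)
}

#' Rule-based seasonality verdict
#'
#' A drug is classed seasonal when at least `min_months` calendar months have
#' a mean at least `threshold_factor` times the overall mean — by default at
#' least 2 months 20% above average, with the boundary inclusive (a month at
#' exactly 1.2x the mean counts as a peak).
#'
#' @param profile A [monthly_profile()].
#' @param threshold_factor Multiplier on the overall mean defining a peak
#'   month (default 1.2; must exceed 1).
#' @param min_months Minimum number of peak months for a seasonal verdict
#'   (default 2).
#' @return An object of class `seasonality_verdict`: list with `drug`,
#'   `seasonal`, `peak_months` (integer month numbers, 1 = January),
#'   `threshold_factor`, `min_months`, `overall_mean`.
#' @export
classify_seasonal <- function(profile, threshold_factor = 1.2,
                              min_months = 2L) {
  stopifnot(inherits(profile, "monthly_profile"))
  if (threshold_factor <= 1) stop("threshold_factor must exceed 1",
                                  call. = FALSE)
  if (min_months < 1L) stop("min_months must be >= 1", call. = FALSE)
  peaks <- which(profile$month_means >=
                   threshold_factor * profile$overall_mean)
  structure(list(drug = profile$drug,
                 seasonal = length(peaks) >= min_months,
                 peak_months = peaks,
                 threshold_factor = threshold_factor,
                 min_months = as.integer(min_months),
                 overall_mean = profile$overall_mean),
            class = "seasonality_verdict")
}

#' @export
print.seasonality_verdict <- function(x, ...) {
  cat(x$drug, "->", if (x$seasonal) "seasonal" else "not seasonal")
  if (length(x$peak_months))
    cat(" (peaks:", paste(month.abb[x$peak_months], collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Classify every drug in a record table
#'
#' Convenience wrapper: [monthly_profile()] + [classify_seasonal()] per drug,
#' returned as one table. Drugs whose pre-COVID series covers fewer than 12
#' distinct calendar months are skipped with a warning.
#'
#' @inheritParams monthly_profile
#' @inheritParams classify_seasonal
#' @return A `data.table` with columns `drug`, `seasonal`, `peak_months`
#'   (comma-separated month numbers), `overall_mean`.
#' @export
classify_all_seasonal <- function(records, calendar = study_calendar(),
                                  threshold_factor = 1.2, min_months = 2L) {
  drugs <- sort(unique(records$drug))
  rows <- lapply(drugs, function(d) {
    prof <- tryCatch(monthly_profile(records, d, calendar),
                     error = function(e) NULL)
    if (is.null(prof)) return(NULL)
    v <- classify_seasonal(prof, threshold_factor, min_months)
    data.table::data.table(drug = d, seasonal = v$seasonal,
                           peak_months = paste(v$peak_months, collapse = ","),
                           overall_mean = v$overall_mean)
  })
  skipped <- drugs[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    warning("skipped drug(s) with <12 observed calendar months: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  data.table::rbindlist(rows)
}
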