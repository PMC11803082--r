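library(data.table)

# one canonical record, with overridable fields
rec_row <- function(period = "2023-01", drug = "Amoxicillin",
                    family = "Penicillins", age_band = "2–5",
                    sex = "Female", region = "ENGLAND", items = 10L) {
  data.table(period = period, drug = drug, family = family,
             age_band = age_band, sex = sex, region = region,
             items = as.integer(items))
}

# record table from vectors (recycled against the longest)
make_records <- function(...) {
  defaults <- list(period = "2023-01", drug = "Amoxicillin",
                   family = "Penicillins", age_band = "2–5", sex = "Female",
                   region = "ENGLAND", items = 10L)
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  dt <- do.call(data.table, defaults)
  dt[, items := as.integer(items)]
  dt[]
}

# flat population: every (band, sex) cell = n persons, for given years/regions
flat_population <- function(n = 100000L, years = 2023L, regions = "ENGLAND") {
  CJ(age_band = abxdemog::age_band_table()$label,
     sex = c("Female", "Male"), region = regions, year = years,
     sorted = FALSE)[, count := as.integer(n)][]
}

# small fast synthetic config: few drugs, short span, one region
quick_config <- function(seed = 1L, drugs = synthetic_drug_table()[1:4],
                         start = "2023-01", end = "2023-12", ...) {
  synthetic_config(seed = seed, drugs = drugs, start = start, end = end, ...)
}

period_year_of <- function(period) as.integer(substr(period, 1, 4))
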