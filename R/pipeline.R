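#' Run one pipeline stage from a config
#'
#' Single entry point wiring the analysis stages into reproducible runs. A
#' run is a pure function of (inputs, config, seed): outputs are written as
#' CSV/JSON into the output directory together with a manifest (inputs,
#' parameters, row counts, package version) and an echo of the resolved
#' config. The companion shell wrapper is installed at
#' `system.file("cli", "abxdemog.R", package = "abxdemog")`.
#'
#' Config fields (all optional unless a stage needs them): `prescriptions`,
#' `population`, `aware_map`, `aware_overrides`, `vaccination_schedule`
#' (input paths); `output_dir`; `seed`; `imputation_value`,
#' `imputation_scope`; `strata`; `year`; `top_n`; `regions_keep`;
#' `rare_threshold`; `ucm_family`.
#'
#' @param subcommand One of `simulate`, `ingest`, `rates`, `seasonality`,
#'   `ucm`, `aware`, `flu`, `sensitivity`, `summary`.
#' @param config Path to a YAML or JSON config file, or a named list.
#' @param output_dir Overrides `config$output_dir`.
#' @param seed Overrides `config$seed`.
#' @return (Invisibly) a named list of the paths written.
#' @export
run_pipeline <- function(subcommand, config = list(), output_dir = NULL,
                         seed = NULL) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "ingest", "rates", "seasonality",
                            "ucm", "aware", "flu", "sensitivity", "summary"))
  cfg <- load_run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$output_dir))
    validation_stop("config must set output_dir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  out <- switch(subcommand,
    simulate = stage_simulate(cfg),
    ingest = stage_ingest(cfg),
    rates = stage_rates(cfg),
    seasonality = stage_seasonality(cfg),
    ucm = stage_ucm(cfg),
    aware = stage_aware(cfg),
    flu = stage_flu(cfg),
    sensitivity = stage_sensitivity(cfg),
    summary = stage_summary(cfg))

  cfg_echo <- file.path(cfg$output_dir, paste0(subcommand, "_config.json"))
  jsonlite::write_json(cfg[order(names(cfg))], cfg_echo, auto_unbox = TRUE,
                       null = "null")
  manifest <- file.path(cfg$output_dir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(list(
    subcommand = subcommand, package = "abxdemog",
    version = as.character(utils::packageVersion("abxdemog")),
    seed = cfg$seed, outputs = out$files, row_counts = out$rows,
    timestamp = format(Sys.time(), tz = "UTC")),
    manifest, auto_unbox = TRUE)
  invisible(c(out$files, config = cfg_echo, manifest = manifest))
}

validation_stop <- function(...) {
  stop(structure(class = c("abxdemog_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) validation_stop("config file not found: ",
                                              config)
    cfg <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
           else jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) cfg <- config
  else validation_stop("config must be a file path or a list")
  for (f in c("prescriptions", "population", "aware_map", "aware_overrides",
              "vaccination_schedule"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      validation_stop("input file for ", sQuote(f), " not found: ", cfg[[f]])
  cfg
}

need_input <- function(cfg, field) {
  if (is.null(cfg[[field]]))
    validation_stop("subcommand requires config field ", sQuote(field))
  cfg[[field]]
}

load_records <- function(cfg, dered = TRUE) {
  rec <- read_prescriptions(need_input(cfg, "prescriptions"))
  if (!is.null(cfg$regions_keep)) rec <- filter_regions(rec, cfg$regions_keep)
  if (dered)
    rec <- impute_redacted(rec,
                           value = cfg$imputation_value %||% 1L,
                           scope = cfg$imputation_scope %||% "all")
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

out_file <- function(cfg, name) file.path(cfg$output_dir, name)

stage_simulate <- function(cfg) {
  sc <- synthetic_config(seed = cfg$seed)
  pop <- generate_population(sc)
  gen <- generate_prescriptions(sc, pop)
  supp <- apply_suppression(gen$records, sc$suppression_threshold)
  f1 <- out_file(cfg, "prescriptions.csv"); write_records(supp, f1)
  f2 <- out_file(cfg, "population.csv"); data.table::fwrite(pop, f2)
  f3 <- out_file(cfg, "truth_totals_by_drug.json")
  tt <- truth_expected_totals(gen$truth, by = "drug")
  jsonlite::write_json(stats::setNames(as.list(tt$expected_items), tt$drug),
                       f3, auto_unbox = TRUE, digits = NA)
  list(files = c(prescriptions = f1, population = f2, truth = f3),
       rows = c(prescriptions = nrow(supp), population = nrow(pop)))
}

stage_ingest <- function(cfg) {
  rec <- read_prescriptions(need_input(cfg, "prescriptions"))
  rejects <- attr(rec, "rejects")
  if (!is.null(cfg$regions_keep)) rec <- filter_regions(rec, cfg$regions_keep)
  ex <- apply_exclusions(rec, rare_threshold = cfg$rare_threshold %||% 10)
  f1 <- out_file(cfg, "records.csv"); write_records(ex$records, f1)
  f2 <- out_file(cfg, "exclusion_report.json")
  jsonlite::write_json(unclass(ex$report), f2, auto_unbox = TRUE, digits = NA)
  f3 <- out_file(cfg, "rejects.csv")
  data.table::fwrite(if (is.null(rejects)) data.table::data.table()
                     else rejects, f3)
  list(files = c(records = f1, exclusion_report = f2, rejects = f3),
       rows = c(records = nrow(ex$records),
                rejects = if (is.null(rejects)) 0L else nrow(rejects)))
}

stage_rates <- function(cfg) {
  rec <- load_records(cfg)
  pop <- read_population(need_input(cfg, "population"))
  strata <- cfg$strata %||% c("drug", "age_band", "sex", "year")
  r <- compute_rates(rec, pop, strata = strata)
  f <- out_file(cfg, "rates.csv"); data.table::fwrite(r, f)
  list(files = c(rates = f), rows = c(rates = nrow(r)))
}

stage_seasonality <- function(cfg) {
  rec <- load_records(cfg)
  v <- classify_all_seasonal(rec)
  f <- out_file(cfg, "seasonality.csv"); data.table::fwrite(v, f)
  list(files = c(seasonality = f), rows = c(seasonality = nrow(v)))
}

stage_ucm <- function(cfg) {
  rec <- load_records(cfg)
  pop <- read_population(need_input(cfg, "population"))
  year <- cfg$year %||% 2023L
  w <- compute_ucm_weights(rec, pop, year = year,
                           family = cfg$ucm_family %||% NULL)
  yr_rec <- rec[period_year(parse_period(period)) == year]
  if (!is.null(cfg$ucm_family)) yr_rec <- yr_rec[family == cfg$ucm_family]
  items <- yr_rec[, .(items = sum(items)), by = region]
  metrics <- rank_regions(apply_ucm(w, pop, items))
  f1 <- out_file(cfg, "ucm_weights.csv")
  data.table::fwrite(format(w), f1)
  f2 <- out_file(cfg, "ucm_metrics.csv"); data.table::fwrite(metrics, f2)
  list(files = c(weights = f1, metrics = f2),
       rows = c(weights = nrow(w$weights), metrics = nrow(metrics)))
}

stage_aware <- function(cfg) {
  rec <- load_records(cfg)
  map <- read_aware_map(cfg$aware_map %||%
                          system.file("extdata", "aware_map.csv",
                                      package = "abxdemog"),
                        overrides = cfg$aware_overrides %||% NULL)
  b <- aware_breakdown(rec, map,
                       strata = cfg$strata %||% c("age_band", "sex", "year"))
  f <- out_file(cfg, "aware.csv"); data.table::fwrite(b, f)
  list(files = c(aware = f), rows = c(aware = nrow(b)))
}

stage_flu <- function(cfg) {
  rec <- load_records(cfg)
  pop <- read_population(need_input(cfg, "population"))
  sched <- if (!is.null(cfg$vaccination_schedule))
    read_vaccination_schedule(cfg$vaccination_schedule)
  else read_vaccination_schedule()
  s <- season_relative_rates(select_rti_records(rec), pop, sched)
  f <- out_file(cfg, "flu.csv"); data.table::fwrite(s, f)
  list(files = c(flu = f), rows = c(flu = nrow(s)))
}

stage_sensitivity <- function(cfg) {
  rec <- load_records(cfg, dered = FALSE)
  pop <- read_population(need_input(cfg, "population"))
  s <- sensitivity_scan(rec, pop, year = cfg$year %||% NULL)
  f <- out_file(cfg, "sensitivity.csv"); data.table::fwrite(s, f)
  list(files = c(sensitivity = f), rows = c(sensitivity = nrow(s)))
}

stage_summary <- function(cfg) {
  rec <- load_records(cfg)
  pop <- if (!is.null(cfg$population))
    read_population(cfg$population) else NULL
  sm <- summarize_drugs(rec, top_n = cfg$top_n %||% 20L, population = pop)
  hc <- headline_counts(sm)
  f1 <- out_file(cfg, "summary.csv"); data.table::fwrite(sm, f1)
  f2 <- out_file(cfg, "headline.json")
  jsonlite::write_json(list(
    n_top = hc$n_top,
    n_decreasing_2016_2023 = hc$n_decreasing_2016_2023,
    n_female_majority = hc$n_female_majority,
    month_distribution = as.list(hc$month_distribution),
    n_reduction_ge_10pct_2019_2023 = hc$n_reduction_ge_10pct_2019_2023),
    f2, auto_unbox = TRUE)
  list(files = c(summary = f1, headline = f2), rows = c(summary = nrow(sm)))
}
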