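test_that("RTI selection keeps the two beta-lactam families minus amoxicillin", {
  rec <- make_records(
    drug = c("Amoxicillin", "Penicillin V", "Doxycycline hyclate",
             "Cefalexin"),
    family = c("Penicillins", "Penicillins", "Tetracyclines",
               "Cephalosporins and other beta-lactams"))
  expect_setequal(select_rti_records(rec)$drug,
                  c("Penicillin V", "Cefalexin"))
  expect_setequal(select_rti_records(rec, include_amoxicillin = TRUE)$drug,
                  c("Amoxicillin", "Penicillin V", "Cefalexin"))
  expect_equal(nrow(select_rti_records(rec[0])), 0L)
})

test_that("every Oct-Mar month is in exactly one season, Apr-Sep in none", {
  p <- abxdemog:::parse_period(sprintf("2019-%02d", 1:12))
  s <- abxdemog:::flu_season_of(p)
  expect_equal(s[10:12], rep(2019L, 3))   # Oct-Dec -> season 2019/20
  expect_equal(s[1:3], rep(2018L, 3))     # Jan-Mar -> season 2018/19
  expect_true(all(is.na(s[4:9])))
})

test_that("relative rates and season-on-season changes follow definitions", {
  # two seasons, two groups; reference 15-50 held flat
  ref_bands <- flu_age_groups()[["15–50"]]
  mk <- function(period, band, items)
    make_records(period = period, age_band = band, items = items,
                 drug = "Penicillin V")
  rec <- rbind(
    mk(c("2017-10", "2018-01"), "0–1", c(120L, 80L)),     # season 2017
    mk(c("2018-10", "2019-01"), "0–1", c(90L, 60L)),      # season 2018
    mk(c("2017-11", "2018-02"), ref_bands[1], c(500L, 500L)),
    mk(c("2018-11", "2019-02"), ref_bands[1], c(500L, 500L)))
  pop <- flat_population(10000L, years = 2017:2019)
  s <- season_relative_rates(rec, pop)

  r0 <- s[age_group == "0–1"]
  # group rate 200/20000 vs reference 1000/(7 bands x 2 sexes x 10000)
  expect_equal(r0[season == 2017]$rate, 200 / 20000)
  ref <- s[age_group == "15–50"]
  expect_equal(ref$relative_rate, c(1, 1))   # reference is exactly 1
  expect_equal(r0[season == 2017]$relative_rate,
               (200 / 20000) / (1000 / 140000))
  # items 200 -> 150 on a fixed population: prop change -0.25
  expect_equal(r0[season == 2018]$prop_change, -0.25)
  expect_true(is.na(r0[season == 2017]$prop_change))  # no previous season
})

test_that("proportional change is invariant to uniform population scaling", {
  rec <- rbind(
    make_records(period = c("2017-10", "2018-10"), age_band = "2–5",
                 items = c(400L, 300L), drug = "Penicillin V"),
    make_records(period = c("2017-10", "2018-10"), age_band = "16–20",
                 items = c(100L, 100L), drug = "Penicillin V"))
  pop1 <- flat_population(50000L, years = 2017:2018)
  pop2 <- data.table::copy(pop1)[, count := count * 7L]
  s1 <- season_relative_rates(rec, pop1)
  s2 <- season_relative_rates(rec, pop2)
  expect_equal(s1[age_group == "2–5"]$prop_change,
               s2[age_group == "2–5"]$prop_change)
})

test_that("vaccination introductions annotate the matching group-season", {
  sched <- data.frame(season_start_year = 2018L, age_group = "2–5")
  rec <- make_records(period = c("2017-10", "2018-10", "2017-11", "2018-11"),
                      age_band = c("2–5", "2–5", "16–20", "16–20"),
                      items = 100L, drug = "Penicillin V")
  s <- season_relative_rates(rec, flat_population(1000L, 2017:2018),
                             schedule = read_vaccination_schedule(sched))
  expect_true(s[age_group == "2–5" & season == 2018]$vaccination_introduced)
  expect_false(any(s[age_group != "2–5"]$vaccination_introduced))
})

test_that("an injected RTI rate drop in one group is recovered at its season", {
  drugs <- synthetic_drug_table()[name %in% c("Penicillin V", "Cefalexin")]
  drugs[, `:=`(seasonal_amplitude = 0, peak_months = "",
               base_monthly_rate = 600, age_profile = "flat", fm_ratio = 1)]
  cfg <- synthetic_config(
    seed = 31, start = "2016-07", end = "2019-03", drugs = drugs,
    covid_dip = 1,
    intervention = list(bands = "6–10", from = "2018-10", multiplier = 0.9))
  pop <- generate_population(cfg)
  gen <- generate_prescriptions(cfg, pop)
  s <- season_relative_rates(select_rti_records(gen$records), pop)
  drop_grp <- s[age_group == "5–10" & season == 2018]
  expect_lt(abs(drop_grp$prop_change - (-0.10)), 0.01)
  others <- s[age_group != "5–10" & season == 2018]
  expect_true(all(abs(others$prop_change) < 0.02))
})
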