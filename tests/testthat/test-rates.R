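test_that("rate is items per 100,000 matched-year population", {
  rec <- rec_row(items = 50L, period = "2023-06")
  pop <- flat_population(100000L)
  r <- compute_rates(rec, pop, strata = c("drug", "age_band", "sex"))
  expect_equal(r$rate, 50)
  expect_equal(r$population, 100000L)
  # per-person scaling
  r1 <- compute_rates(rec, pop, strata = "drug", per = 1)
  expect_equal(r1$rate, 50 / (100000 * 46))  # all 23 bands x 2 sexes pooled
})

test_that("collapsing sub-strata adds items and denominators", {
  rec <- make_records(age_band = c("21–25", "26–30"), items = c(30L, 20L),
                      period = "2023-01")
  # a two-band world: the collapse must sum both items and denominators
  pop <- flat_population(50000L)[age_band %in% c("21–25", "26–30")]
  fine <- compute_rates(rec, pop, strata = c("age_band", "sex"))
  coarse <- compute_rates(rec, pop, strata = "sex")
  expect_equal(sum(fine$items), coarse$items)
  # brute-force oracle: (30 + 20) / (50k + 50k) x 1e5 = 50
  expect_equal(coarse[sex == "Female"]$rate, 50)
})

test_that("missing denominator cells are reported, zero strata fillable", {
  rec <- rec_row(period = "2023-01")
  pop <- flat_population(1000L, years = 2022L)  # wrong year
  expect_error(compute_rates(rec, pop, strata = "drug"), "missing denominator")
  rec2 <- make_records(sex = c("Female", "Female"), items = c(5L, 5L),
                       age_band = c("0–1", "2–5"))
  z <- compute_rates(rec2, flat_population(1000L),
                     strata = c("age_band", "sex"), zero_fill = TRUE)
  expect_true(all(z[sex == "Male"]$items == 0L))
  expect_equal(z[sex == "Male" & age_band == "0–1"]$rate, 0)
})

test_that("rates are invariant to splitting records and scale with population", {
  set.seed(7)
  rec <- make_records(items = 100L, period = "2021-09")
  pop <- flat_population(40000L, years = 2021L)
  r0 <- compute_rates(rec, pop, strata = "drug")
  split <- rbind(rec_row(items = 60L, period = "2021-09"),
                 rec_row(items = 40L, period = "2021-09"))
  expect_equal(compute_rates(split, pop, strata = "drug")$rate, r0$rate)
  pop2 <- data.table::copy(pop)[, count := count * 2L]
  expect_equal(compute_rates(rec, pop2, strata = "drug")$rate, r0$rate / 2)
})

test_that("sex contrast computes log ratios, ties and zero-rate flags", {
  pop <- flat_population(100000L)
  rec <- make_records(sex = c("Female", "Male"), items = c(200L, 100L))
  ct <- sex_contrast(compute_rates(rec, pop,
                                   strata = c("drug", "age_band", "sex")))
  expect_equal(ct$log_ratio, log(2), tolerance = 1e-12)
  expect_true(ct$female_majority)

  tie <- make_records(sex = c("Female", "Male"), items = c(75L, 75L))
  ct2 <- sex_contrast(compute_rates(tie, pop,
                                    strata = c("drug", "age_band", "sex")))
  expect_equal(ct2$log_ratio, 0)
  expect_false(ct2$female_majority)  # a tie is not a majority

  onezero <- make_records(sex = c("Female", "Male"), items = c(10L, 5L),
                          age_band = c("0–1", "0–1"),
                          drug = c("A", "A"))
  rz <- compute_rates(rbind(onezero, rec), pop,
                      strata = c("drug", "age_band", "sex"), zero_fill = TRUE)
  ctz <- sex_contrast(rz)
  # zero-filled cells: A has no female items in band 2-5 etc.
  both0 <- ctz[both_zero == TRUE]
  expect_true(all(is.na(both0$female_majority)))
  inf_rows <- ctz[is.infinite(log_ratio)]
  expect_true(all(inf_rows$female_majority == (inf_rows$log_ratio > 0)))
})

test_that("a generator F:M ratio of 2 is recovered in every band's log ratio", {
  drugs <- synthetic_drug_table()[1:2]
  drugs[, `:=`(fm_ratio = 2, seasonal_amplitude = 0, peak_months = "",
               age_profile = "flat", base_monthly_rate = 400)]
  cfg <- quick_config(seed = 11, drugs = drugs)
  gen <- generate_prescriptions(cfg)
  pop <- generate_population(cfg)
  r <- compute_rates(gen$records, pop, strata = c("drug", "age_band", "sex"))
  ct <- sex_contrast(r)[is.finite(log_ratio)]
  expect_gt(nrow(ct), 40)
  expect_equal(mean(ct$log_ratio), log(2), tolerance = 0.02)
  # the tiniest bands (105+ has ~1000 people) are noisy; a wide per-band
  # bound still rules out any systematic distortion
  expect_true(all(abs(ct$log_ratio - log(2)) < 0.7))
})
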