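# minimal two-cell world: baseline females 66-70 at rate 0.10 items/person,
# males 86-90 at 0.20 -> weight 2
two_cell_fixture <- function() {
  pop <- data.table::data.table(
    age_band = c("66–70", "86–90"), sex = c("Female", "Male"),
    region = "ENGLAND", year = 2023L, count = c(1000L, 500L))
  rec <- make_records(period = "2023-05",
                      age_band = c("66–70", "86–90"),
                      sex = c("Female", "Male"), items = c(100L, 100L))
  list(rec = rec, pop = pop)
}

test_that("weights are per-capita rates relative to the 66-70 female baseline", {
  f <- two_cell_fixture()
  w <- compute_ucm_weights(f$rec, f$pop)
  expect_equal(w$weights[age_band == "66–70" & sex == "Female"]$weight, 1)
  expect_equal(w$weights[age_band == "86–90" & sex == "Male"]$weight, 2)
})

test_that("empty child cells take the 0.01 substitute; other empties error", {
  f <- two_cell_fixture()
  pop <- rbind(f$pop, data.table::data.table(
    age_band = c("2–5", "31–35"), sex = "Male", region = "ENGLAND",
    year = 2023L, count = 1000L))
  expect_error(compute_ucm_weights(f$rec, pop), "31–35/Male")
  w <- compute_ucm_weights(f$rec, pop, clamp_zero = TRUE)
  expect_equal(w$weights[age_band == "2–5" & sex == "Male"]$weight, 0.01)
  expect_equal(w$weights[age_band == "31–35" & sex == "Male"]$weight, 0.01)

  # a zero baseline leaves the metric undefined
  badrec <- f$rec[age_band != "66–70"]
  expect_error(compute_ucm_weights(badrec, f$pop), "baseline")
})

test_that("weights are clamped to the configured limits", {
  f <- two_cell_fixture()
  f$rec[age_band == "86–90", items := 100000L]   # rate ratio 1000 -> cap
  w <- compute_ucm_weights(f$rec, f$pop)
  expect_equal(w$weights[age_band == "86–90"]$weight, 100)
  w2 <- compute_ucm_weights(f$rec, f$pop, cap = 50)
  expect_equal(w2$weights[age_band == "86–90"]$weight, 50)
})

test_that("regional metric is items per weighted person", {
  f <- two_cell_fixture()
  w <- compute_ucm_weights(f$rec, f$pop)   # weights 1 and 2
  reg_pop <- data.table::data.table(
    age_band = c("66–70", "86–90"), sex = c("Female", "Male"),
    region = "QA1", year = 2023L, count = c(1000L, 500L))
  m <- apply_ucm(w, reg_pop, c(QA1 = 400))
  expect_equal(m$weighted_population, 2000)   # 1000x1 + 500x2
  expect_equal(m$metric, 0.2)
  expect_error(apply_ucm(w, reg_pop, c(QZ9 = 10)), "absent from population")
})

test_that("two regions with the same rate structure get equal metrics", {
  f <- two_cell_fixture()
  w <- compute_ucm_weights(f$rec, f$pop)
  reg_pop <- data.table::rbindlist(list(
    data.table::data.table(age_band = c("66–70", "86–90"),
                           sex = c("Female", "Male"), region = "A",
                           year = 2023L, count = c(1000L, 500L)),
    data.table::data.table(age_band = c("66–70", "86–90"),
                           sex = c("Female", "Male"), region = "B",
                           year = 2023L, count = c(3000L, 1500L))))
  m <- apply_ucm(w, reg_pop, c(A = 400, B = 1200))  # same per-cell rates
  expect_equal(m[region == "A"]$metric, m[region == "B"]$metric)
  # scale invariance: x10 on both items and populations changes nothing
  reg10 <- data.table::copy(reg_pop)[, count := count * 10L]
  m10 <- apply_ucm(w, reg10, c(A = 4000, B = 12000))
  expect_equal(m10$metric, m$metric)
})

test_that("ranking sorts descending with code tie-break and 10/10/10/12 groups", {
  m <- data.table::data.table(region = c("A", "B", "C"),
                              weighted_population = 1,
                              items = c(0.3, 0.1, 0.2), metric = c(0.3, 0.1, 0.2))
  r <- rank_regions(m)
  expect_equal(r$region, c("A", "C", "B"))
  expect_equal(r$rank, 1:3)

  tied <- data.table::data.table(region = c("QX", "QA"),
                                 weighted_population = 1, items = 1,
                                 metric = c(0.5, 0.5))
  expect_equal(rank_regions(tied)$region, c("QA", "QX"))

  m42 <- data.table::data.table(region = sprintf("Q%02d", 1:42),
                                weighted_population = 1, items = 1,
                                metric = 42:1)
  g <- rank_regions(m42)[, .N, by = quartile_group]
  expect_equal(g$N, c(10L, 10L, 10L, 12L))
})

test_that("configured per-cell relative rates are recovered from counts", {
  profiles <- synthetic_age_profiles()
  drugs <- synthetic_drug_table()[1]
  drugs[, `:=`(base_monthly_rate = 2000, seasonal_amplitude = 0,
               peak_months = "", fm_ratio = 1.5, age_profile = "elderly")]
  cfg <- quick_config(seed = 5, drugs = drugs,
                      population_base = rep(2e6, 23))
  pop <- generate_population(cfg)
  gen <- generate_prescriptions(cfg, pop)
  w <- compute_ucm_weights(gen$records, pop, year = 2023)

  # expected weight = (age multiplier x sex factor) / baseline cell's product
  prof <- profiles$elderly
  bands <- age_band_table()$label
  sexf <- c(Female = 2 * 1.5 / 2.5, Male = 2 / 2.5)
  base <- prof[bands == "66–70"] * sexf["Female"]
  expected <- unname(w$weights[, prof[match(age_band, bands)] *
                                 sexf[sex] / base])
  expect_equal(w$weights$weight, expected, tolerance = 0.02)
})
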