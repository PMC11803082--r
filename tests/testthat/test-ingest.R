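test_that("reading parses counts, redaction markers, and rejects bad rows", {
  raw <- data.frame(
    period = c("2023-01", "2023-02", "2023-03", "2023-13", "2023-04"),
    drug = "Amoxicillin", family = "Penicillins", age_band = "2–5",
    sex = "Female", region = "QRL",
    items = c("120", "*", "0", "5", "2.5"))
  rec <- read_prescriptions(raw)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$items[1], 120L)
  expect_true(is.na(rec$items[2]))           # "*" carried as redacted
  rej <- attr(rec, "rejects")
  expect_equal(nrow(rej), 3L)
  expect_setequal(rej$reject_reason,
                  c("item count below 1", "malformed period",
                    "non-integer item count"))
})

test_that("missing mandatory columns are a configuration error", {
  raw <- data.frame(period = "2023-01", drug = "X", items = "1")
  expect_error(read_prescriptions(raw), "missing mandatory column")
})

test_that("write-then-read round-trips every non-rejected row losslessly", {
  rec <- make_records(period = c("2023-01", "2023-02", "2023-03"),
                      items = c(7L, NA, 12L),
                      age_band = c("0–1", "66–70", "105+"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_prescriptions(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "rejects")), 0L)
})

test_that("unknown demographics and indeterminate sex are excluded and counted", {
  # 1000 one-item records, 33 of unknown sex: mirrors a 3.3% exclusion rate
  rec <- make_records(period = "2023-05", items = 1L,
                      sex = c(rep("Female", 967), rep("Unknown", 33)),
                      drug = "Trimethoprim")
  ex <- apply_exclusions(rec, rare_threshold = 0)
  expect_equal(nrow(ex$records), 967L)
  expect_equal(ex$report$n_unknown_demographics, 33L)
  expect_equal(ex$report$pct_unknown, 0.033)

  rec2 <- rbind(rec_row(sex = "Indeterminate"), rec_row(sex = "Male"))
  ex2 <- apply_exclusions(rec2, rare_threshold = 0)
  expect_equal(ex2$records$sex, "Male")
  expect_equal(ex2$report$n_indeterminate, 1L)
})

test_that("rare drugs are dropped on mean items per complete year", {
  # 5 items in each complete year: mean 5 < threshold 10 -> dropped
  rare <- make_records(period = paste0(2016:2023, "-06"), items = 5L,
                       drug = "Raredrug")
  common <- make_records(period = paste0(2016:2023, "-06"), items = 500L)
  ex <- apply_exclusions(rbind(rare, common), rare_threshold = 10)
  expect_equal(ex$report$drugs_dropped_rare, "Raredrug")
  expect_false("Raredrug" %in% ex$records$drug)
  expect_true("Amoxicillin" %in% ex$records$drug)
})

test_that("clean input passes through unchanged and exclusion is idempotent", {
  rec <- make_records(period = "2019-01", items = c(200L, 300L),
                      sex = c("Female", "Male"))
  ex1 <- apply_exclusions(rec)
  expect_equal(as.data.frame(ex1$records), as.data.frame(rec))
  ex2 <- apply_exclusions(ex1$records)
  expect_equal(as.data.frame(ex2$records), as.data.frame(ex1$records))
  # empty input: zeroed report, no error
  ex0 <- apply_exclusions(rec[0])
  expect_equal(nrow(ex0$records), 0L)
  expect_equal(ex0$report$n_unknown_demographics, 0L)
})

test_that("imputation respects value, scope and the out-of-scope default", {
  red <- rec_row(items = NA)
  expect_equal(impute_redacted(red, value = 1, scope = "all")$items, 1L)
  expect_equal(impute_redacted(red, value = 4, scope = "all")$items, 4L)
  # female record under males_only scope takes the default 1
  expect_equal(impute_redacted(red, value = 4, scope = "males_only")$items, 1L)
  expect_equal(impute_redacted(rec_row(sex = "Male", items = NA),
                               value = 4, scope = "males_only")$items, 4L)
  # children_only: band 16-20 (contains 19) in scope, 21-25 not
  expect_equal(impute_redacted(rec_row(age_band = "16–20", items = NA),
                               value = 3, scope = "children_only")$items, 3L)
  expect_equal(impute_redacted(rec_row(age_band = "21–25", items = NA),
                               value = 3, scope = "children_only")$items, 1L)
  # numeric items never touched; invalid values rejected
  expect_equal(impute_redacted(rec_row(items = 7L), value = 4)$items, 7L)
  expect_error(impute_redacted(red, value = 5), "1..4")
  expect_error(impute_redacted(red, value = 0), "1..4")
})

test_that("total items rises by 3 per redacted cell from value 1 to 4", {
  set.seed(42)
  for (i in 1:5) {
    n <- 50L
    items <- sample(c(NA, 1:200), n, replace = TRUE)
    rec <- make_records(period = "2022-03", items = items,
                        drug = sample(letters[1:5], n, replace = TRUE))
    k <- sum(is.na(items))
    t1 <- sum(impute_redacted(rec, 1)$items)
    t4 <- sum(impute_redacted(rec, 4)$items)
    expect_equal(t4 - t1, 3L * k)
  }
})

test_that("region filter and old-age collapsing behave as stated", {
  rec <- make_records(region = c("ENGLAND", "QRL", "7A1"))
  expect_equal(filter_regions(rec, c("ENGLAND", "QRL"))$region,
               c("ENGLAND", "QRL"))
  rec2 <- make_records(age_band = c("81–85", "86–90", "105+"))
  out <- collapse_age_bands(rec2)
  expect_equal(out$age_band, c("81–85", "86+", "86+"))
})
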