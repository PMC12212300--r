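test_that("a valid survey CSV loads row for row with its weights", {
  w <- toy_women(3, weight = c(1.5, 2, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(w, path)
  got <- read_microdata(path, "survey")
  expect_equal(nrow(got), 3)
  expect_equal(got$weight, c(1.5, 2, 0.7))
})

test_that("census data with an outcome column is a schema error", {
  w <- toy_women(2)  # survey schema carries outcomes
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(w, path)
  expect_error(read_microdata(path, "census"),
               class = "ethnosae_schema_error")
})

test_that("nonpositive weights and unknown categories are rejected by row", {
  expect_error(validate_microdata(toy_women(1, weight = 0), "survey"),
               class = "ethnosae_validation_error")
  expect_error(validate_microdata(toy_women(1, age_group = "50-54"),
                                  "survey"),
               regexp = "age_group", class = "ethnosae_validation_error")
  expect_error(validate_microdata(toy_women(1, education = "doctorate"),
                                  "survey"),
               regexp = "doctorate")
})

test_that("outcome-consistency invariants are enforced and relaxable", {
  bad_modern <- toy_women(1, y_use_any = 0L, y_use_modern = 1L)
  expect_error(validate_microdata(bad_modern, "survey"),
               regexp = "modern")
  overlap <- toy_women(1, y_use_any = 1L, y_use_modern = 0L, y_unmet = 1L)
  expect_error(validate_microdata(overlap, "survey"),
               regexp = "mutually exclusive")
  expect_silent(validate_microdata(overlap, "survey",
                                   allow_unmet_overlap = TRUE))
})

test_that("missing values error by default and drop listwise on request", {
  w <- toy_women(3)
  w$working[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(w, path)
  expect_error(read_microdata(path, "survey"),
               class = "ethnosae_validation_error")
  expect_message(got <- read_microdata(path, "survey", na_action = "drop"),
                 "dropped 1")
  expect_equal(nrow(got), 2)
})

test_that("eligibility filter keeps exactly in-union women aged 13-49", {
  w <- toy_women(10)
  w$in_union <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)
  expect_equal(nrow(filter_eligible(w)), 4)
  expect_equal(nrow(filter_eligible(w, in_union_flag = rep(0L, 10))), 0)
})

test_that("eligibility filter agrees with a row-by-row predicate oracle", {
  w <- random_women(200, seed = 9)
  w$in_union <- sample(0:1, 200, replace = TRUE)
  got <- filter_eligible(w)
  oracle_keep <- vapply(seq_len(nrow(w)), function(i) {
    w$in_union[i] == 1 &&
      w$age_group[i] %in% c("13-14", "15-19", "20-24", "25-29",
                            "30-34", "35-39", "40-44", "45-49")
  }, logical(1))
  expect_identical(got$id, w$id[oracle_keep])
})

test_that("microdata round-trip is exact for categories, 1e-12 for weights", {
  w <- validate_microdata(random_women(50, seed = 3), "survey")
  path <- withr::local_tempfile(fileext = ".csv")
  write_microdata(w, path)
  back <- read_microdata(path, "survey")
  for (col in c("ethnic_group", "urbanicity", "age_group", "education")) {
    expect_identical(as.character(back[[col]]), as.character(w[[col]]))
  }
  expect_equal(back$weight, w$weight, tolerance = 1e-12)
  expect_identical(back$y_use_any, w$y_use_any)
})
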