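test_that("read_cohort parses a small CSV, typing columns by declared kind", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex,death", "61,M,0", "70,F,1", "55,M,0", "n/a,F,1"), f)
  ch <- read_cohort(f, outcome = "death")
  expect_equal(nrow(ch$data), 4)
  expect_equal(unname(ch$kinds[c("age", "sex")]), c("continuous", "categorical"))
  expect_true(is.na(ch$data$age[4]))  # unparseable numeric cell -> missing
  expect_equal(ch$data$death, c(0L, 1L, 0L, 1L))
})

test_that("non-binary or missing outcomes are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,death", "61,0", "70,2"), f)
  expect_error(read_cohort(f, outcome = "death"), "0/1")
  expect_error(read_cohort(f, outcome = "mort"), "not present")
  expect_error(cohort(data.frame(a = 1, y = NA), "y"), "0/1")
})

test_that("flag_outliers blanks out-of-range cells and nothing else", {
  ch <- cohort(data.frame(heart_rate = c(400, 80, 10), age = c(50, 60, 70),
                          y = c(0, 1, 0)), "y")
  out <- flag_outliers(ch, list(heart_rate = c(20, 300)))
  expect_equal(out$data$heart_rate, c(NA, 80, NA))  # both 400 and 10 out of range
  expect_identical(out$data$age, ch$data$age)
  expect_identical(flag_outliers(ch, list()), ch)  # empty ranges: identity
  expect_error(flag_outliers(ch, list(bmi = c(10, 60))), "unknown")
  ch2 <- cohort(data.frame(sex = c("M", "F"), y = c(0, 1)), "y")
  expect_error(flag_outliers(ch2, list(sex = c(0, 1))), "continuous")
})

test_that("split_cohort gives exact sizes, reproducibility and a partition", {
  ch <- cohort(data.frame(x = rnorm(100), y = rep(c(0, 1), 50)), "y")
  s1 <- split_cohort(ch, c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(vapply(s1, function(p) nrow(p$data), numeric(1)),
               c(train = 70, validation = 10, test = 20))
  s2 <- split_cohort(ch, c(0.7, 0.1, 0.2), seed = 1)
  expect_identical(s1, s2)

  # every row of a larger cohort lands in exactly one partition
  ch <- cohort(data.frame(x = rnorm(1000), id = 1:1000,
                          y = rep(c(0, 1), 500)), "y")
  s <- split_cohort(ch, c(0.7, 0.1, 0.2), seed = 42)
  ids <- sort(unname(unlist(lapply(s, function(p) p$data$id))))
  expect_equal(ids, 1:1000)

  expect_error(split_cohort(cohort(data.frame(x = 1:3, y = c(0, 1, 0)), "y"),
                            c(0.7, 0.1, 0.2), seed = 1), "empty")
  expect_error(split_cohort(ch, c(0.5, 0.5, 0.5)), "summing")
})

test_that("stratified split preserves class balance in each partition", {
  ch <- cohort(data.frame(x = rnorm(1000), y = rep(c(0, 1), c(900, 100))), "y")
  s <- split_cohort(ch, seed = 3, stratify = TRUE)
  rates <- vapply(s, function(p) mean(p$data$y), numeric(1))
  expect_true(all(abs(rates - 0.1) < 1e-9))
})

test_that("imputation uses training medians only and clears all missingness", {
  train <- cohort(data.frame(lab = c(1, 2, 3, NA), sex = c("M", NA, "F", "M"),
                             y = c(0, 1, 0, 1)), "y")
  test <- cohort(data.frame(lab = c(NA, 100), sex = c("F", NA),
                            y = c(0, 1)), "y")
  imp <- impute_from_training(train, list(test))
  expect_equal(imp$train$data$lab[4], 2)          # median of {1,2,3}
  expect_equal(imp$others[[1]]$data$lab[1], 2)    # training median, not test's
  expect_equal(imp$train$data$sex[2], "Unknown")
  expect_equal(imp$others[[1]]$data$sex[2], "Unknown")
  expect_false(anyNA(imp$train$data) || anyNA(imp$others[[1]]$data))

  # even count: mean of the two central order statistics
  tr2 <- cohort(data.frame(lab = c(1, 2, 10, 20, NA), y = c(0, 1, 0, 1, 0)), "y")
  expect_equal(impute_from_training(tr2)$train$data$lab[5], 6)

  # no missing values: identity
  tr3 <- cohort(data.frame(lab = 1:4, y = c(0, 1, 0, 1)), "y")
  expect_identical(impute_from_training(tr3)$train, tr3)

  tr4 <- cohort(data.frame(lab = c(NA_real_, NA), y = c(0, 1)), "y")
  expect_error(impute_from_training(tr4), "no observed training values")
})

test_that("imputation values are a function of the training partition alone", {
  set.seed(9)
  train <- cohort(data.frame(lab = c(rnorm(50), NA), y = rep(c(0, 1), len = 51)), "y")
  test_a <- cohort(data.frame(lab = c(NA, rnorm(10)), y = rep(c(0, 1), len = 11)), "y")
  test_b <- test_a
  test_b$data$lab[-1] <- test_b$data$lab[-1] + 1000  # perturb observed test values
  fill_a <- impute_from_training(train, list(test_a))$others[[1]]$data$lab[1]
  fill_b <- impute_from_training(train, list(test_b))$others[[1]]$data$lab[1]
  expect_identical(fill_a, fill_b)
})

test_that("outlier flagging then imputation leaves zero missing cells", {
  set.seed(4)
  n <- 200
  dat <- data.frame(hr = c(rnorm(n - 2, 80, 10), 400, -5),
                    sex = sample(c("M", "F"), n, TRUE),
                    y = rep(c(0, 1), n / 2))
  dat$hr[1:5] <- NA
  ch <- flag_outliers(cohort(dat, "y"), list(hr = c(20, 300)))
  parts <- split_cohort(ch, seed = 2)
  imp <- impute_from_training(parts$train, parts[c("validation", "test")])
  for (p in c(list(imp$train), imp$others)) expect_false(anyNA(p$data))
})

test_that("plausibility ranges round-trip through YAML and JSON configs", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("heart_rate: [20, 300]", "temperature: [30, 43]"), fy)
  r <- read_ranges(fy)
  expect_equal(r$heart_rate, c(20, 300))
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"heart_rate": [20, 300]}', fj)
  expect_equal(read_ranges(fj)$heart_rate, c(20, 300))
  fbad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("heart_rate: [300, 20]", fbad)
  expect_error(read_ranges(fbad), "low < high")
})
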