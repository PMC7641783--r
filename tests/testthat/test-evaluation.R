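test_that("roc_auc matches hand values and rejects degenerate labels", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both outcome classes")
  expect_error(roc_auc(c(1, 2, 3), c(0, 1)), "equal length")
})

test_that("rank-based AUC equals brute-force pair counting on random instances", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(1:10, n, replace = TRUE)  # heavy ties on purpose
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))[sample(n)]
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(82)
  for (i in 1:25) {
    n <- 200
    scores <- rnorm(n)
    labels <- rbinom(n, 1, plogis(scores))
    if (length(unique(labels)) < 2) next
    a <- roc_auc(scores, labels)
    expect_equal(roc_auc(exp(scores), labels), a)
    expect_equal(roc_auc(scores * 3.7 + 11, labels), a)
    expect_equal(roc_auc(rank(scores), labels), a)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  scores <- round(rnorm(300), 1)
  labels <- rbinom(300, 1, plogis(scores))
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("optimal threshold minimises distance to the upper-left corner", {
  # enumerated: t=2 gives (sens 1, spec .5); t=4 gives (sens .5, spec 1);
  # both at distance .5 -> tie broken to the lowest threshold
  expect_equal(optimal_threshold(c(1, 2, 3, 4), c(0, 1, 0, 1)), 2)
  # perfect separation: lowest achievable zero-distance threshold
  expect_equal(optimal_threshold(c(1, 2, 10, 11), c(0, 0, 1, 1)), 10)
  expect_equal(optimal_threshold(rep(5, 4), c(0, 1, 0, 1)), 5)
})

test_that("target-sensitivity/specificity thresholds take the conservative extreme", {
  s <- c(10, 20, 30, 40); l <- c(0, 0, 1, 1)
  row_sens <- threshold_for_target(s, l, "sensitivity", 0.95)
  expect_equal(row_sens$threshold, 30)
  expect_equal(row_sens$sensitivity, 1.0)
  row_spec <- threshold_for_target(s, l, "specificity", 0.95)
  expect_equal(row_spec$threshold, 30)
  expect_equal(row_spec$specificity, 1.0)
  # top score is a control: specificity 1 needs the all-negative threshold
  s2 <- c(1, 2, 2, 3); l2 <- c(0, 1, 0, 0)
  expect_equal(threshold_for_target(s2, l2, "specificity", 1)$threshold, 4)
  expect_error(threshold_for_target(s2, l2, "sensitivity", 2), "level")
})

test_that("confusion metrics handle undefined ratios as NA, never zero", {
  s <- c(10, 20, 30, 40); l <- c(0, 0, 1, 1)
  m <- confusion_metrics(s, l, 25)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  hi <- confusion_metrics(s, l, 99)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_true(is.na(hi$ppv))
  lo <- confusion_metrics(s, l, -5)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_true(is.na(lo$npv))
})

test_that("sens*P + (1-spec)*N equals predicted positives at any threshold", {
  set.seed(84)
  for (i in 1:30) {
    n <- 80
    s <- sample(0:20, n, replace = TRUE)
    l <- c(0, 1, rbinom(n - 2, 1, 0.3))[sample(n)]
    t <- sample(0:21, 1)
    m <- confusion_metrics(s, l, t)
    P <- sum(l == 1); N <- sum(l == 0)
    expect_equal(m$sensitivity * P + (1 - m$specificity) * N, sum(s >= t))
  }
})

test_that("bootstrap CIs are reproducible and degenerate for constant metrics", {
  set.seed(85)
  s <- rnorm(150); l <- rbinom(150, 1, plogis(s))
  ci1 <- bootstrap_ci(roc_auc, s, l, reps = 200, seed = 5)
  ci2 <- bootstrap_ci(roc_auc, s, l, reps = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])

  sep <- c(rep(0, 40), rep(10, 40))
  lab <- rep(c(0, 1), each = 40)
  expect_equal(bootstrap_ci(roc_auc, sep, lab, reps = 200, seed = 1), c(1, 1))
  expect_error(bootstrap_ci(roc_auc, s, l, reps = 10), "at least 100")
})

test_that("bootstrap AUC interval covers the point estimate on noisy data", {
  set.seed(86)
  n <- 500
  s <- rnorm(n)
  l <- rbinom(n, 1, plogis(1.3 * s - 1))  # true AUC around 0.75
  a <- roc_auc(s, l)
  ci <- bootstrap_ci(roc_auc, s, l, reps = 400, seed = 2)
  expect_gt(a, ci[1])
  expect_lt(a, ci[2])
})

test_that("calibration bins conserve counts and flag empty bins", {
  s <- c(1, 2, 3, 9); l <- c(0, 1, 0, 1)
  one <- calibration_bins(s, l, c(0, 10))
  expect_equal(one$n, 4)
  expect_equal(one$rate, 0.5)

  bins <- calibration_bins(s, l, c(0, 5, 7, 10))
  expect_equal(sum(bins$n), 4)
  expect_equal(bins$n, c(3, 0, 1))
  expect_true(is.na(bins$rate[2]))
  # last interval closed so the maximum score is kept
  expect_equal(calibration_bins(c(0, 10), c(0, 1), c(0, 5, 10))$n, c(1, 1))
  expect_error(calibration_bins(s, l, c(5, 1)), "strictly increasing")
  expect_error(calibration_bins(s, l, c(2, 10)), "span")
})

test_that("evaluate_scores assembles a consistent report", {
  set.seed(87)
  n <- 800
  s <- round(20 + 10 * rnorm(n))
  l <- rbinom(n, 1, plogis((s - 25) / 6))
  rep1 <- evaluate_scores(s, l, reps = 200, seed = 9)
  expect_s3_class(rep1, "eval_report")
  expect_true(rep1$auc >= rep1$auc_ci[1] && rep1$auc <= rep1$auc_ci[2])
  expect_equal(sum(rep1$calibration$n), n)
  expect_equal(nrow(rep1$thresholds), 3)
  expect_true(all(rep1$thresholds$sensitivity >= 0 &
                    rep1$thresholds$sensitivity <= 1, na.rm = TRUE))
  opt <- rep1$thresholds[rep1$thresholds$rule == "optimal", ]
  expect_equal(opt$threshold, optimal_threshold(s, l))
  rep2 <- evaluate_scores(s, l, reps = 200, seed = 9)
  expect_identical(rep1, rep2)
})
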