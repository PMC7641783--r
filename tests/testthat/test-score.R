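test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -2.5, 1.49)),
               c(1, 2, 3, -1, -3, 1))
})

test_that("a 2x2 table recovers its closed-form log odds ratio", {
  df <- make_two_by_two()  # OR = (400/100)/(100/400) = 16
  ch <- cohort(df, "y")
  tc <- apply_transform(ch, make_transform_spec(ch, "exposure"))
  fit <- fit_weights(tc)
  expect_lt(abs(fit$coef$exposure[["yes"]] - log(16)), 0.05)
  expect_true(fit$converged)
  expect_false(fit$separation)

  # agrees with an unpenalised glm fit (independent route)
  glm_fit <- glm(y ~ exposure, data = df, family = binomial)
  expect_lt(abs(fit$coef$exposure[["yes"]] - coef(glm_fit)[["exposureyes"]]),
            1e-3)
  expect_lt(abs(fit$intercept - coef(glm_fit)[[1]]), 1e-3)
})

test_that("an uninformative predictor gets a near-zero coefficient", {
  set.seed(71)
  n <- 4000
  df <- data.frame(g = sample(c("p", "q"), n, TRUE), y = rbinom(n, 1, 0.3))
  ch <- cohort(df, "y")
  tc <- apply_transform(ch, make_transform_spec(ch, "g"))
  fit <- fit_weights(tc)
  expect_lt(abs(unlist(fit$coef$g)), 0.1)
})

test_that("a zero-event category stays finite and flags separation", {
  df <- data.frame(
    g = rep(c("low", "mid", "high"), c(200, 200, 100)),
    y = c(rbinom(200, 1, 0.3), rbinom(200, 1, 0.5), rep(0, 100))
  )
  ch <- cohort(df, "y")
  tc <- apply_transform(ch, make_transform_spec(ch, "g"))
  fit <- fit_weights(tc)
  expect_true(all(is.finite(unlist(fit$coef))))
  expect_true(fit$separation)
})

test_that("releveling picks the argmin category and refitting is a fixed point", {
  set.seed(72)
  n <- 6000
  g <- sample(c("A", "B", "C"), n, TRUE)
  risk <- c(A = 0.3, B = 0.18, C = 0.45)[g]   # B is the lowest-risk category
  df <- data.frame(g = g, y = rbinom(n, 1, risk))
  ch <- cohort(df, "y")
  tc <- apply_transform(ch, make_transform_spec(ch, "g"))
  fit1 <- fit_weights(tc)
  fit2 <- relevel_references(fit1, tc)
  expect_equal(unname(fit2$references["g"]), "B")
  expect_true(all(unlist(fit2$coef$g) >= 0))

  # already releveled: a second pass reproduces the coefficients
  fit3 <- relevel_references(fit2, tc)
  expect_equal(unname(fit3$references["g"]), "B")
  expect_equal(fit3$coef$g[names(fit2$coef$g)], fit2$coef$g, tolerance = 1e-8)
})

test_that("points are coefficients divided by the lowest and rounded", {
  fit <- make_weight_fit(list(A = c(A2 = 0.5, A3 = 1.0), B = c(B2 = 0.25)))
  tab <- derive_points(fit)
  expect_equal(tab$points$A[["A2"]], 2)
  expect_equal(tab$points$A[["A3"]], 4)
  expect_equal(tab$points$B[["B2"]], 1)
  expect_equal(tab$points$A[["A_ref"]], 0)
  expect_equal(tab$beta_lowest, 0.25)
  expect_equal(tab$min_total, 0)
  expect_equal(tab$max_total, 5)

  # round(0.37/0.25) = round(1.48) = 1
  tab2 <- derive_points(make_weight_fit(list(A = c(A2 = 0.37), B = c(B2 = 0.25))))
  expect_equal(tab2$points$A[["A2"]], 1)

  # equal coefficients all map to one point
  tab3 <- derive_points(make_weight_fit(list(A = c(A2 = 0.8), B = c(B2 = 0.8))))
  expect_equal(unname(c(tab3$points$A[["A2"]], tab3$points$B[["B2"]])), c(1, 1))

  expect_error(derive_points(make_weight_fit(list(A = c(A2 = 1e-9)))),
               "score would be identically zero")
  expect_error(derive_points(make_weight_fit(list(A = c(A2 = -0.2)))),
               "nonnegative")
})

test_that("ceiling normalisation rescales points and respects its bounds", {
  fit <- make_weight_fit(list(A = c(A2 = 2, A3 = 10), B = c(B2 = 1, B3 = 9)))
  tab <- derive_points(fit)   # points 2,10,1,9; max_total 19
  expect_equal(tab$max_total, 19)
  half <- normalize_to_ceiling(tab, 200)  # factor ~10.5
  expect_equal(half$points$A[["A_ref"]], 0)
  expect_lte(half$max_total, 200 + length(half$points))

  same <- normalize_to_ceiling(tab, tab$max_total)
  expect_equal(same$points, tab$points)

  # single variable with 10 points and ceiling 1: 10 * 1/10 = 1
  single <- as_score_table(list(A = c(ref = 0, cat2 = 10)))
  expect_equal(normalize_to_ceiling(single, 1)$points$A[["cat2"]], 1)
  expect_error(normalize_to_ceiling(tab, 1), "number of variables")
})

test_that("published nine-variable table reproduces its worked examples", {
  tab <- reference_score_table()
  episode <- data.frame(age = 50, heart_rate = 80, resp_rate = 18, sbp = 120,
                        temperature = 37.0, spo2 = 97, platelet = 200,
                        bun = 20, lactate = 1.5)
  # single-variable lookup: age 50 falls in 48-78 -> 14 points
  age_only <- as_score_table(list(age = tab$points$age),
                             cutoffs = list(age = c(30, 48, 78, 85)))
  expect_equal(score_episodes(age_only, episode["age"]), 14)
  expect_equal(score_episodes(tab, episode), 30)

  # an episode in every zero-point category scores zero
  zero <- data.frame(age = 20, heart_rate = 65, resp_rate = 14, sbp = 110,
                     temperature = 37.0, spo2 = 97, platelet = 200,
                     bun = 5, lactate = 0.5)
  expect_equal(score_episodes(tab, zero), 0)
})

test_that("compute_score falls back for unknown categories and errors otherwise", {
  tab <- as_score_table(list(g = c(ref = 0, hi = 5, Other = 2)))
  df <- data.frame(g = c("hi", "zzz", "ref"))
  expect_equal(compute_score(df, tab), c(5, 2, 0))
  tab2 <- as_score_table(list(g = c(ref = 0, hi = 5)),
                         references = c(g = "ref"))
  expect_equal(compute_score(data.frame(g = "zzz"), tab2), 0)
  expect_error(compute_score(data.frame(h = "x"), tab), "lack score variable")
})

test_that("score tables round-trip through JSON with their embedded spec", {
  set.seed(73)
  n <- 1500
  df <- data.frame(x = rnorm(n), g = sample(c("a", "b"), n, TRUE),
                   y = rbinom(n, 1, 0.2))
  df$y <- rbinom(n, 1, plogis(-2 + df$x + (df$g == "b")))
  ch <- cohort(df, "y")
  spec <- make_transform_spec(ch)
  tc <- apply_transform(ch, spec)
  tab <- derive_points(relevel_references(fit_weights(tc), tc), spec = spec)
  f <- withr::local_tempfile(fileext = ".json")
  write_score_table(tab, f)
  tab2 <- read_score_table(f)
  expect_equal(tab2$points, tab$points)
  expect_equal(tab2$max_total, tab$max_total)
  expect_equal(score_episodes(tab2, df), score_episodes(tab, df))
})

test_that("totals stay within [min_total, max_total] for random episodes", {
  set.seed(74)
  tab <- reference_score_table()
  n <- 10000
  eps <- data.frame(
    age = runif(n, 0, 110), heart_rate = runif(n, 30, 200),
    resp_rate = runif(n, 4, 50), sbp = runif(n, 50, 250),
    temperature = runif(n, 33, 42), spo2 = runif(n, 50, 100),
    platelet = runif(n, 5, 900), bun = runif(n, 1, 150),
    lactate = runif(n, 0.2, 20)
  )
  s <- score_episodes(tab, eps)
  expect_true(all(s >= tab$min_total & s <= tab$max_total))
  expect_true(all(s == round(s)))
  pts <- unlist(tab$points)
  expect_true(all(pts >= 0 & pts == round(pts)))
})
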