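# brute-force AUC oracle: mean over all case-control pairs of
# 1[case > control] + 0.5 * 1[tie]; independent of the rank-based route
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    total <- total + sum(a > controls) + 0.5 * sum(a == controls)
  }
  total / (length(cases) * length(controls))
}

# published nine-variable inpatient-mortality point table, as a score_table
# with cutoffs so it can score raw episodes
reference_score_table <- function() {
  path <- system.file("extdata", "icu_mortality_score.csv",
                      package = "pointscore")
  df <- read.csv(path, stringsAsFactors = FALSE)
  pts <- lapply(split(df, df$variable), function(d) {
    setNames(d$points, d$interval)
  })
  # preserve file (bin) order within variable
  pts <- lapply(unique(df$variable), function(v) {
    d <- df[df$variable == v, ]
    setNames(d$points, d$interval)
  })
  names(pts) <- unique(df$variable)
  cutoffs <- list(
    age = c(30, 48, 78, 85),
    heart_rate = c(62, 72, 98, 112),
    resp_rate = c(12, 16, 22),
    sbp = c(90, 100, 130, 150),
    temperature = c(36, 36.5, 37.5, 38),
    spo2 = c(85, 90, 95),
    platelet = c(80, 150, 300, 450),
    bun = c(7.5, 12, 35, 70),
    lactate = c(1, 2.5, 4)
  )
  as_score_table(pts, cutoffs = cutoffs)
}

# small deterministic 2x2 cohort: binary exposure with exact event counts
make_two_by_two <- function(n_exposed = 500, n_unexposed = 500,
                            events_exposed = 400, events_unexposed = 100) {
  data.frame(
    exposure = rep(c("yes", "no"), c(n_exposed, n_unexposed)),
    y = c(rep(c(1, 0), c(events_exposed, n_exposed - events_exposed)),
          rep(c(1, 0), c(events_unexposed, n_unexposed - events_unexposed))),
    stringsAsFactors = FALSE
  )
}

# categorized cohort straight from a data.frame of factors + 0/1 outcome
as_categorized <- function(df, outcome) {
  vars <- setdiff(names(df), outcome)
  ch <- cohort(df, outcome = outcome,
               kinds = setNames(rep("categorical", length(vars)), vars))
  for (v in vars) {
    ch$data[[v]] <- if (is.factor(df[[v]])) df[[v]] else factor(df[[v]])
  }
  class(ch) <- c("categorized_cohort", "cohort")
  ch
}

# hand-built releveled weight fit for derive_points unit tests
make_weight_fit <- function(coefs, references = NULL) {
  vars <- names(coefs)
  if (is.null(references)) {
    references <- setNames(paste0(vars, "_ref"), vars)
  }
  levels <- lapply(vars, function(v) c(references[[v]], names(coefs[[v]])))
  names(levels) <- vars
  structure(
    list(intercept = -2, coef = coefs, references = references,
         levels = levels, variables = vars, lambda = 1e-4,
         converged = TRUE, separation = FALSE, clamped = character(0)),
    class = "weight_fit"
  )
}

# transform spec built from a synthetic truth record (true categorization)
truth_transform_spec <- function(truth) {
  vars <- names(truth$points)[!vapply(truth$points, is.null, logical(1))]
  rules <- list()
  for (v in vars) {
    if (!is.null(truth$cutoffs[[v]])) {
      rules[[v]] <- list(type = "continuous", cutoffs = truth$cutoffs[[v]])
    } else {
      lev <- truth$levels[[v]]
      rules[[v]] <- list(type = "categorical",
                         map = setNames(lev, lev), levels = lev)
    }
  }
  structure(list(variables = rules, grid = quantile_grid()),
            class = "transform_spec")
}

# named true point vector of one variable, labelled like the pipeline labels
truth_points_named <- function(truth, v) {
  p <- truth$points[[v]]
  names(p) <- if (!is.null(truth$cutoffs[[v]])) {
    bin_labels(truth$cutoffs[[v]])
  } else {
    truth$levels[[v]]
  }
  p
}
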