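#' Derive a point-based clinical risk score
#'
#' End-to-end derivation of an integer point-based risk score from a cohort
#' table with a binary outcome: plausibility screening, random 70/10/20
#' train/validation/test split, training-median imputation, random-forest
#' Gini-importance variable ranking, parsimony-driven choice of the number of
#' variables, quantile discretisation, releveled category-level logistic
#' weighting, coefficient-to-integer-point conversion, optional cutoff
#' fine-tuning and ceiling normalisation, and ROC evaluation with bootstrap
#' confidence intervals on the held-out test set. The test partition is
#' touched only in the final evaluation.
#'
#' @param formula \code{outcome ~ .} or \code{outcome ~ v1 + v2 + ...};
#'   the left-hand side names the binary 0/1 outcome column.
#' @param data data.frame holding the outcome and candidate predictors.
#' @param kinds optional named character vector declaring predictors
#'   \code{"continuous"}/\code{"categorical"} (otherwise inferred).
#' @param ranges optional named list of plausibility ranges
#'   (\code{variable -> c(low, high)}); out-of-range values become missing
#'   before imputation.
#' @param split (train, validation, test) fractions, default
#'   \code{c(0.7, 0.1, 0.2)}.
#' @param stratify outcome-stratified split (default FALSE, plain random).
#' @param seed single integer governing every stochastic stage (split,
#'   forest, bootstrap) through fixed per-stage offsets.
#' @param ntree trees in the ranking forest (default 100).
#' @param grid a [quantile_grid()].
#' @param lambda ridge penalty for the category-level logistic fits.
#' @param m number of variables; NULL (default) selects it automatically
#'   from the parsimony curve.
#' @param m_values candidate model sizes for the parsimony curve; default
#'   \code{1:min(20, p)}.
#' @param delta minimum meaningful validation-AUC gain for automatic
#'   selection (default 0.005).
#' @param cutoff_overrides optional named list of fine-tuned cutoff vectors
#'   applied before the final score derivation.
#' @param score_ceiling optional total-score ceiling; the derived points are
#'   rescaled with [normalize_to_ceiling()].
#' @param boot bootstrap replicates for the evaluation CIs (default 1000).
#' @return an object of class \code{pointscore} with, among others,
#'   \code{$ranking}, \code{$curve}, \code{$m}, \code{$transform},
#'   \code{$score_table} and \code{$evaluation}. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{predict} and \code{plot}.
#' @examples
#' spec <- default_ehr_spec(n = 1500, seed = 7)
#' dat <- generate_cohort(spec)$cohort$data
#' names(dat)[names(dat) == "..outcome.."] <- "death"
#' fit <- pointscore(death ~ ., data = dat, m = 3, boot = 200, seed = 7)
#' fit
#' @export
pointscore <- function(formula, data, kinds = NULL, ranges = NULL,
                       split = c(0.7, 0.1, 0.2), stratify = FALSE, seed = 1,
                       ntree = 100, grid = quantile_grid(), lambda = 1e-4,
                       m = NULL, m_values = NULL, delta = 0.005,
                       cutoff_overrides = NULL, score_ceiling = NULL,
                       boot = 1000) {
  cl <- match.call()
  outcome <- all.vars(formula[[2]])
  if (length(outcome) != 1) stop("formula needs a single outcome", call. = FALSE)
  rhs <- attr(stats::terms(formula, data = data), "term.labels")
  preds <- if (length(rhs)) rhs else setdiff(names(data), outcome)
  ch <- cohort(data[c(outcome, preds)], outcome = outcome, kinds = kinds)
  if (!is.null(ranges)) ch <- flag_outliers(ch, ranges)

  parts <- split_cohort(ch, fractions = split, seed = stage_seed(seed, 2L),
                        stratify = stratify)
  imp <- impute_from_training(parts$train, list(parts$validation, parts$test))
  train <- imp$train
  validation <- imp$others[[1]]
  test <- imp$others[[2]]

  ranking <- rank_variables(train, ntree = ntree, seed = seed)
  curve <- parsimony_curve(train, validation, ranking,
                           m_values = m_values, grid = grid, lambda = lambda)
  m_sel <- select_m(curve, delta = delta, m = m)
  vars <- ranking$variable[seq_len(m_sel)]

  spec <- make_transform_spec(train, vars, grid)
  if (!is.null(cutoff_overrides)) spec <- fine_tune_cutoffs(spec, cutoff_overrides)
  train_cat <- apply_transform(train, spec)
  fit1 <- fit_weights(train_cat, lambda = lambda)
  fit2 <- relevel_references(fit1, train_cat)
  table <- derive_points(fit2, spec = spec)
  if (!is.null(score_ceiling)) table <- normalize_to_ceiling(table, score_ceiling)

  # map from total score to event probability, fitted on the training scores
  train_scores <- compute_score(train_cat, table)
  risk_fit <- stats::glm.fit(
    x = cbind(1, train_scores),
    y = train$data[[outcome]],
    family = stats::binomial()
  )
  risk_coef <- stats::setNames(risk_fit$coefficients, c("intercept", "score"))

  test_scores <- compute_score(apply_transform(test, spec), table)
  evaluation <- evaluate_scores(test_scores, test$data[[outcome]],
                                reps = boot, seed = seed)

  structure(
    list(
      call = cl,
      outcome = outcome,
      kinds = ch$kinds,
      n = c(train = nrow(train$data), validation = nrow(validation$data),
            test = nrow(test$data)),
      medians = imp$medians,
      ranking = ranking,
      curve = curve,
      m = m_sel,
      variables = vars,
      transform = spec,
      fit_first_pass = fit1,
      fit = fit2,
      score_table = table,
      risk_coef = risk_coef,
      test_scores = test_scores,
      evaluation = evaluation,
      seed = seed
    ),
    class = "pointscore"
  )
}

#' @export
print.pointscore <- function(x, ...) {
  cat(sprintf(
    "Point-based risk score for '%s' (m = %d of %d candidates; seed %d)\n",
    x$outcome, x$m, nrow(x$ranking), x$seed))
  cat(sprintf("Partitions: train %d / validation %d / test %d\n\n",
              x$n["train"], x$n["validation"], x$n["test"]))
  print(x$score_table)
  cat(sprintf("\nTest AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$evaluation$auc, x$evaluation$auc_ci[1], x$evaluation$auc_ci[2]))
  invisible(x)
}

#' @export
summary.pointscore <- function(object, ...) {
  structure(list(fit = object), class = "summary.pointscore")
}

#' @export
print.summary.pointscore <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nParsimony curve (validation AUC by model size):\n")
  print.data.frame(f$curve, row.names = FALSE, digits = 4)
  cat("\n")
  print(f$evaluation)
  invisible(x)
}

#' @export
coef.pointscore <- function(object, ...) {
  df <- as.data.frame(object$score_table)
  stats::setNames(df$points, paste(df$variable, df$interval, sep = "="))
}

#' Predict from a fitted point score
#'
#' @param object a [pointscore()] fit.
#' @param newdata data.frame of raw predictor values; missing cells are
#'   filled with the stored training medians (continuous) or "Unknown"
#'   (categorical).
#' @param type \code{"score"} for the integer total score,
#'   \code{"response"} for the event probability implied by the training
#'   score-to-risk logistic calibration, or \code{"category"} for the
#'   per-variable category labels.
#' @param ... unused.
#' @return numeric vector (or data.frame for \code{type = "category"}).
#' @export
predict.pointscore <- function(object, newdata,
                               type = c("score", "response", "category"), ...) {
  type <- match.arg(type)
  vars <- names(object$score_table$points)
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) {
    stop("newdata lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- newdata[vars]
  for (v in vars) {
    if (object$kinds[[v]] == "continuous") {
      col <- suppressWarnings(as.numeric(df[[v]]))
      col[is.na(col)] <- object$medians[[v]]
      df[[v]] <- col
    } else {
      col <- as.character(df[[v]])
      col[is.na(col)] <- "Unknown"
      df[[v]] <- col
    }
  }
  if (type == "category") {
    tmp <- df
    tmp$..y.. <- 0L
    return(apply_transform(cohort(tmp, "..y.."), object$transform)$data[vars])
  }
  s <- score_episodes(object$score_table, df)
  if (type == "score") return(s)
  stats::plogis(object$risk_coef["intercept"] + object$risk_coef["score"] * s)
}

#' Plot a fitted point score
#'
#' @param x a [pointscore()] fit.
#' @param which \code{"parsimony"} (validation AUC versus model size),
#'   \code{"calibration"} (observed test event rate by score interval) or
#'   \code{"distribution"} (test score histogram by interval).
#' @param ... passed to the underlying plot call.
#' @export
plot.pointscore <- function(x, which = c("parsimony", "calibration",
                                         "distribution"), ...) {
  which <- match.arg(which)
  if (which == "parsimony") {
    plot(x$curve, ...)
    graphics::abline(v = x$m, lty = 2)
  } else {
    cal <- x$evaluation$calibration
    if (which == "calibration") {
      graphics::barplot(100 * cal$rate, names.arg = cal$interval, las = 2,
                        ylab = "Observed event rate (%)",
                        xlab = "Score interval", ...)
    } else {
      graphics::barplot(cal$n, names.arg = cal$interval, las = 2,
                        ylab = "Episodes", xlab = "Score interval", ...)
    }
  }
  invisible(x)
}

#' Persist the artifacts of a score derivation run
#'
#' Writes the ranking, parsimony curve, transform spec, score table (JSON
#' and Markdown), evaluation report and a run log to a directory. The score
#' table JSON embeds the transform spec, so it is the complete deployable
#' object; with the same data and seed the file is byte-identical across
#' runs.
#'
#' @param object a [pointscore()] fit.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_pointscore_artifacts <- function(object, dir) {
  stopifnot(inherits(object, "pointscore"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ranking = file.path(dir, "ranking.json"),
    parsimony = file.path(dir, "parsimony.csv"),
    transform = file.path(dir, "transform_spec.json"),
    score_json = file.path(dir, "score_table.json"),
    score_md = file.path(dir, "score_table.md"),
    eval_csv = file.path(dir, "eval_report.csv"),
    eval_md = file.path(dir, "eval_report.md"),
    calibration = file.path(dir, "calibration.csv"),
    log = file.path(dir, "run_log.txt")
  )
  write_json_stable(
    lapply(seq_len(nrow(object$ranking)), function(i) {
      list(variable = object$ranking$variable[i],
           importance = object$ranking$importance[i])
    }),
    paths["ranking"]
  )
  utils::write.csv(object$curve, paths["parsimony"], row.names = FALSE)
  write_transform_spec(object$transform, paths["transform"])
  write_score_table(object$score_table, paths["score_json"])

  df <- as.data.frame(object$score_table)
  md <- c("| Variable | Interval | Points |", "|---|---|---|",
          sprintf("| %s | %s | %d |", df$variable, df$interval,
                  as.integer(df$points)),
          "",
          sprintf("Total score range: %d to %d",
                  as.integer(object$score_table$min_total),
                  as.integer(object$score_table$max_total)))
  writeLines(md, paths["score_md"])

  ev <- object$evaluation
  utils::write.csv(ev$thresholds, paths["eval_csv"], row.names = FALSE)
  utils::write.csv(ev$calibration, paths["calibration"], row.names = FALSE)
  md2 <- c(
    sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d bootstrap replicates",
            ev$auc, ev$auc_ci[1], ev$auc_ci[2], ev$reps),
    sprintf("Rule: %s", ev$positivity_rule), "",
    "| Rule | Threshold | Sensitivity | Specificity | PPV | NPV |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %.1f%% (%.1f-%.1f) | %.1f%% (%.1f-%.1f) | %.1f%% (%.1f-%.1f) | %.1f%% (%.1f-%.1f) |",
            ev$thresholds$rule, fmt_num(ev$thresholds$threshold),
            100 * ev$thresholds$sensitivity, 100 * ev$thresholds$sens_low,
            100 * ev$thresholds$sens_high,
            100 * ev$thresholds$specificity, 100 * ev$thresholds$spec_low,
            100 * ev$thresholds$spec_high,
            100 * ev$thresholds$ppv, 100 * ev$thresholds$ppv_low,
            100 * ev$thresholds$ppv_high,
            100 * ev$thresholds$npv, 100 * ev$thresholds$npv_low,
            100 * ev$thresholds$npv_high)
  )
  writeLines(md2, paths["eval_md"])

  writeLines(c(
    sprintf("pointscore %s on R %s.%s", utils::packageVersion("pointscore"),
            R.version$major, R.version$minor),
    sprintf("seed: %d", object$seed),
    sprintf("partitions: train %d, validation %d, test %d",
            object$n["train"], object$n["validation"], object$n["test"]),
    sprintf("selected m: %d", object$m),
    sprintf("variables: %s", paste(object$variables, collapse = ", "))
  ), paths["log"])
  invisible(paths)
}
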