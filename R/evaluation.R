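#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen case scores
#' higher than a randomly chosen control, counting ties as one half. Equal to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  check_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be 0/1 and nothing missing", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

# sensitivity/specificity at every candidate threshold under the rule
# "positive iff score >= threshold"
operating_points <- function(scores, labels, thresholds) {
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / P,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & labels == 0) / N,
                 numeric(1))
  data.frame(threshold = thresholds, sensitivity = sens, specificity = spec)
}

#' Confusion-matrix metrics at a threshold
#'
#' Classification rule: positive iff score >= threshold. Ratios with a zero
#' denominator (e.g. PPV when nothing is predicted positive) are reported as
#' NA, never as 0.
#'
#' @inheritParams roc_auc
#' @param threshold score cutoff.
#' @return one-row data.frame: threshold, sensitivity, specificity, ppv, npv.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_labels(scores, labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1)
  fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1)
  tn <- sum(!pos & labels == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(
    threshold = threshold,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Threshold nearest the upper-left ROC corner
#'
#' Over all achievable operating points, minimises the Euclidean distance
#' sqrt((1-sens)^2 + (1-spec)^2) to the (sens = 1, spec = 1) corner; ties go
#' to the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return the optimal score threshold.
#' @export
optimal_threshold <- function(scores, labels) {
  check_labels(scores, labels)
  cand <- sort(unique(scores))
  op <- operating_points(scores, labels, cand)
  d <- sqrt((1 - op$sensitivity)^2 + (1 - op$specificity)^2)
  min(cand[d <= min(d) + 1e-12])
}

#' Threshold reaching a target sensitivity or specificity
#'
#' Exact targets are generally unattainable on integer scores, so the
#' conservative extreme is used: for sensitivity the largest threshold whose
#' sensitivity still reaches the level, for specificity the smallest
#' threshold whose specificity reaches it.
#'
#' @inheritParams roc_auc
#' @param target \code{"sensitivity"} or \code{"specificity"}.
#' @param level target proportion in (0, 1].
#' @return one-row [confusion_metrics()] data.frame at the chosen threshold.
#' @export
threshold_for_target <- function(scores, labels,
                                 target = c("sensitivity", "specificity"),
                                 level = 0.95) {
  target <- match.arg(target)
  check_labels(scores, labels)
  if (level <= 0 || level > 1) stop("level must be in (0, 1]", call. = FALSE)
  cand <- sort(unique(scores))
  if (target == "specificity") cand <- c(cand, max(cand) + 1)  # all-negative rule
  op <- operating_points(scores, labels, cand)
  ok <- if (target == "sensitivity") op$sensitivity >= level else
    op$specificity >= level
  if (!any(ok)) {
    stop("target ", target, " of ", level, " is unattainable", call. = FALSE)
  }
  t <- if (target == "sensitivity") max(cand[ok]) else min(cand[ok])
  confusion_metrics(scores, labels, t)
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Resamples episodes with replacement; replicates lacking an outcome class
#' are redrawn. The interval is the 2.5/97.5 percentile of the replicate
#' metrics.
#'
#' @param metric function(scores, labels) -> scalar.
#' @inheritParams roc_auc
#' @param reps number of bootstrap replicates (>= 100).
#' @param seed integer seed; fixed seed gives a reproducible interval.
#' @param conf confidence level (default 0.95).
#' @return c(low, high).
#' @export
bootstrap_ci <- function(metric, scores, labels, reps = 1000, seed = 1,
                         conf = 0.95) {
  check_labels(scores, labels)
  if (reps < 100) stop("reps must be at least 100", call. = FALSE)
  n <- length(scores)
  vals <- with_seed(seed, vapply(seq_len(reps), function(i) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    as.numeric(metric(scores[idx], labels[idx]))
  }, numeric(1)))
  if (mean(is.na(vals)) > 0.5) {
    stop("metric undefined on more than half of the bootstrap replicates",
         call. = FALSE)
  }
  a <- (1 - conf) / 2
  stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7)
}

#' Observed event rate by score interval
#'
#' Bins scores into the left-closed intervals defined by \code{edges} (the
#' last interval also includes its right edge so the edges cover the data)
#' and reports per-bin counts and observed event rates. Empty bins get count
#' 0 and an NA rate.
#'
#' @inheritParams roc_auc
#' @param edges strictly increasing interval edges spanning all scores.
#' @return data.frame: interval, low, high, n, events, rate. Counts sum to
#'   \code{length(scores)}.
#' @export
calibration_bins <- function(scores, labels, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing with at least two values",
         call. = FALSE)
  }
  if (any(scores < edges[1]) || any(scores > edges[length(edges)])) {
    stop("edges must span the score range", call. = FALSE)
  }
  idx <- findInterval(scores, edges, rightmost.closed = TRUE)
  k <- length(edges) - 1L
  n <- tabulate(idx, nbins = k)
  ev <- vapply(seq_len(k), function(i) sum(labels[idx == i]), numeric(1))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  data.frame(
    interval = paste0("[", fmt_num(lo), ",", fmt_num(hi),
                      c(rep(")", k - 1L), "]")),
    low = lo, high = hi, n = n, events = ev,
    rate = ifelse(n > 0, ev / n, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Full predictive-performance report for a score
#'
#' Computes the test AUC with a bootstrap CI, confusion metrics (with
#' bootstrap CIs) at the upper-left-corner optimal threshold and at the
#' thresholds reaching roughly 95 percent sensitivity and specificity, and a
#' binned calibration table. One bootstrap pass is shared by all metrics so
#' the CIs are mutually consistent.
#'
#' @inheritParams roc_auc
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param sens_level,spec_level target levels for the extra threshold rows.
#' @param bin_width calibration bin width; default spans the observed range
#'   in about 10 equal bins.
#' @return an object of class \code{eval_report}.
#' @export
evaluate_scores <- function(scores, labels, reps = 1000, seed = 1,
                            sens_level = 0.95, spec_level = 0.95,
                            bin_width = NULL) {
  check_labels(scores, labels)
  auc <- roc_auc(scores, labels)
  rows <- list(
    optimal = confusion_metrics(scores, labels, optimal_threshold(scores, labels)),
    sens95 = tryCatch(
      threshold_for_target(scores, labels, "sensitivity", sens_level),
      error = function(e) NULL),
    spec95 = tryCatch(
      threshold_for_target(scores, labels, "specificity", spec_level),
      error = function(e) NULL)
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]

  # one shared bootstrap pass: AUC plus every threshold row's four metrics
  n <- length(scores)
  boot <- with_seed(stage_seed(seed, 3L), {
    replicate(reps, {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      s <- scores[idx]; l <- labels[idx]
      out <- c(auc = roc_auc(s, l))
      for (nm in names(rows)) {
        cm <- confusion_metrics(s, l, rows[[nm]]$threshold)
        out <- c(out, stats::setNames(
          as.numeric(cm[c("sensitivity", "specificity", "ppv", "npv")]),
          paste(nm, c("sensitivity", "specificity", "ppv", "npv"), sep = ".")
        ))
      }
      out
    })
  })
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)

  threshold_table <- do.call(rbind, lapply(names(rows), function(nm) {
    cm <- rows[[nm]]
    data.frame(
      rule = switch(nm, optimal = "optimal",
                    sens95 = sprintf("sensitivity ~%.0f%%", 100 * sens_level),
                    spec95 = sprintf("specificity ~%.0f%%", 100 * spec_level)),
      threshold = cm$threshold,
      sensitivity = cm$sensitivity,
      sens_low = ci[1, paste0(nm, ".sensitivity")],
      sens_high = ci[2, paste0(nm, ".sensitivity")],
      specificity = cm$specificity,
      spec_low = ci[1, paste0(nm, ".specificity")],
      spec_high = ci[2, paste0(nm, ".specificity")],
      ppv = cm$ppv,
      ppv_low = ci[1, paste0(nm, ".ppv")],
      ppv_high = ci[2, paste0(nm, ".ppv")],
      npv = cm$npv,
      npv_low = ci[1, paste0(nm, ".npv")],
      npv_high = ci[2, paste0(nm, ".npv")],
      stringsAsFactors = FALSE
    )
  }))

  rng <- range(scores)
  w <- bin_width %||% max(1, round_half_up((rng[2] - rng[1]) / 10))
  edges <- seq(floor(rng[1] / w) * w, rng[2] + w, by = w)
  calib <- calibration_bins(scores, labels, edges)

  structure(
    list(
      auc = auc, auc_ci = c(ci[1, "auc"], ci[2, "auc"]),
      thresholds = threshold_table,
      calibration = calib,
      n = n, events = sum(labels), reps = reps,
      positivity_rule = "positive iff score >= threshold"
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Predictive performance (n = %d, events = %d)\n", x$n, x$events))
  cat(sprintf("AUC: %.3f (95%% CI %.3f-%.3f; %d bootstrap replicates)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$reps))
  cat("Rule:", x$positivity_rule, "\n\n")
  t <- x$thresholds
  for (i in seq_len(nrow(t))) {
    cat(sprintf("%-20s threshold %s\n", t$rule[i], fmt_num(t$threshold[i])))
    cat(sprintf("  sensitivity %.1f%% (%.1f-%.1f)  specificity %.1f%% (%.1f-%.1f)\n",
                100 * t$sensitivity[i], 100 * t$sens_low[i], 100 * t$sens_high[i],
                100 * t$specificity[i], 100 * t$spec_low[i], 100 * t$spec_high[i]))
    cat(sprintf("  PPV %.1f%% (%.1f-%.1f)  NPV %.1f%% (%.1f-%.1f)\n",
                100 * t$ppv[i], 100 * t$ppv_low[i], 100 * t$ppv_high[i],
                100 * t$npv[i], 100 * t$npv_low[i], 100 * t$npv_high[i]))
  }
  cat("\nCalibration (observed event rate by score interval):\n")
  print(x$calibration[, c("interval", "n", "events", "rate")], row.names = FALSE)
  invisible(x)
}
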