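#' Validation performance versus model size (parsimony curve)
#'
#' For each candidate number of variables m, takes the top-m ranked
#' variables, derives cutoffs and an integer score table on the training set,
#' scores the validation set with the integer score, and records the
#' validation AUC. The deployed object is the integer score, so the curve is
#' computed on it rather than on the underlying logistic predictor. A model
#' size whose fit fails is recorded as a gap (NA) rather than aborting the
#' curve.
#'
#' @param train,validation imputed [cohort()] partitions.
#' @param ranking a [rank_variables()] result.
#' @param m_values candidate model sizes; default \code{1:min(20, p)}.
#' @param grid a [quantile_grid()].
#' @param lambda ridge penalty passed to [fit_weights()].
#' @return data.frame of class \code{parsimony_curve} with columns \code{m}
#'   and \code{auc}.
#' @export
parsimony_curve <- function(train, validation, ranking,
                            m_values = NULL, grid = quantile_grid(),
                            lambda = 1e-4) {
  stopifnot(inherits(train, "cohort"), inherits(validation, "cohort"),
            inherits(ranking, "variable_ranking"))
  p <- nrow(ranking)
  m_values <- sort(unique(as.integer(m_values %||% seq_len(min(20L, p)))))
  if (any(m_values < 1L) || any(m_values > p)) {
    stop("m_values must lie in 1..", p, call. = FALSE)
  }
  y_val <- validation$data[[validation$outcome]]
  auc <- vapply(m_values, function(m) {
    tryCatch({
      vars <- ranking$variable[seq_len(m)]
      spec <- make_transform_spec(train, vars, grid)
      tc <- apply_transform(train, spec)
      fit2 <- relevel_references(fit_weights(tc, lambda = lambda), tc)
      tab <- derive_points(fit2, spec = spec)
      roc_auc(compute_score(apply_transform(validation, spec), tab), y_val)
    }, error = function(e) {
      warning("m = ", m, " failed: ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  out <- data.frame(m = m_values, auc = auc)
  class(out) <- c("parsimony_curve", "data.frame")
  out
}

#' @export
plot.parsimony_curve <- function(x, ...) {
  graphics::plot(x$m, x$auc, type = "b", pch = 19,
                 xlab = "Number of variables (m)", ylab = "Validation AUC",
                 main = "Parsimony plot", ...)
  invisible(x)
}

#' Choose the number of variables from a parsimony curve
#'
#' In automatic mode, returns the smallest m whose AUC gain to every larger
#' evaluated m is below \code{delta} — the point where adding variables no
#' longer improves performance meaningfully. Supplying \code{m} selects it
#' manually (the intended human-in-the-loop usage) after checking it was
#' evaluated.
#'
#' @param curve a [parsimony_curve()].
#' @param delta minimum meaningful AUC gain (default 0.005).
#' @param m optional manual choice.
#' @return the selected integer m.
#' @export
select_m <- function(curve, delta = 0.005, m = NULL) {
  stopifnot(inherits(curve, "parsimony_curve"), nrow(curve) >= 1)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  keep <- !is.na(curve$auc)
  if (!any(keep)) stop("parsimony curve has no successful fits", call. = FALSE)
  curve <- curve[keep, , drop = FALSE]
  if (!is.null(m)) {
    m <- as.integer(m)
    if (!m %in% curve$m) {
      stop("manual m = ", m, " was not evaluated on the curve", call. = FALSE)
    }
    return(m)
  }
  for (i in seq_len(nrow(curve))) {
    larger <- curve$auc[curve$m > curve$m[i]]
    if (all(larger - curve$auc[i] < delta)) return(curve$m[i])
  }
  curve$m[nrow(curve)]
}
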