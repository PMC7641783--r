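#' Gini impurity of a node
#'
#' For class fractions p_1..p_R the Gini index is 1 - sum(p_r^2); in binary
#' classification it lies in [0, 0.5] and is 0 for a pure node.
#'
#' @param p numeric vector of nonnegative class fractions summing to 1.
#' @param tol tolerance for the sum-to-one check.
#' @return nonnegative scalar.
#' @examples
#' gini_index(c(0.9, 0.1))  # 0.18
#' @export
gini_index <- function(p, tol = 1e-8) {
  p <- as.numeric(p)
  if (any(p < -tol)) stop("class fractions must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("class fractions must sum to 1", call. = FALSE)
  }
  1 - sum(p^2)
}

# Integer-code a categorical column by training outcome rate: levels are
# ordered by event rate (ties broken by level name) and mapped to their rank.
# Keeps the forest's split search binary and makes the encoding deterministic.
encode_by_outcome_rate <- function(col, y) {
  col <- as.character(col)
  rate <- tapply(y, col, mean)
  ord <- order(rate, names(rate))  # rate ascending, name tie-break
  code <- stats::setNames(seq_along(ord), names(rate)[ord])
  list(values = as.numeric(code[col]), code = code)
}

#' Rank candidate variables by random-forest Gini importance
#'
#' Fits a classification random forest (each tree grown on a bootstrap sample
#' to maximal depth without pruning, \code{floor(sqrt(p))} candidate variables
#' per split) and ranks predictors by mean decrease in Gini impurity: the
#' within-tree sum of weighted node impurity decreases w(tau) * dGini(tau)
#' over nodes splitting on the variable, averaged over trees. Only the order
#' of the ranking is consumed downstream. Categorical predictors are
#' integer-coded by training outcome rate before fitting.
#'
#' @param train training-partition [cohort()]; both outcome classes must be
#'   present and all cells observed (impute first).
#' @param ntree number of trees (default 100).
#' @param seed integer seed for the forest's resampling.
#' @param vars predictors to rank; defaults to every declared predictor.
#' @return a data.frame of class \code{variable_ranking} with columns
#'   \code{variable} and \code{importance}, sorted by decreasing importance
#'   (ties broken by variable name).
#' @export
rank_variables <- function(train, ntree = 100, seed = 1, vars = NULL) {
  stopifnot(inherits(train, "cohort"))
  vars <- vars %||% variables(train)
  y <- train$data[[train$outcome]]
  if (nrow(train$data) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class in the training set; cannot rank",
         call. = FALSE)
  }
  X <- train$data[vars]
  if (anyNA(X)) {
    stop("training data contain missing values; run impute_from_training first",
         call. = FALSE)
  }
  for (v in vars[train$kinds[vars] == "categorical"]) {
    X[[v]] <- encode_by_outcome_rate(X[[v]], y)$values
  }
  X$..outcome.. <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = "..outcome..",
    data = X,
    num.trees = ntree,
    mtry = max(1L, floor(sqrt(length(vars)))),
    importance = "impurity",
    replace = TRUE,
    min.node.size = 1,
    num.threads = 1,
    seed = stage_seed(seed, 1L)
  )
  imp <- fit$variable.importance[vars]
  imp[is.na(imp)] <- 0
  ord <- order(-imp, vars)
  out <- data.frame(
    variable = vars[ord],
    importance = as.numeric(imp[ord]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("variable_ranking", "data.frame")
  out
}

#' @export
print.variable_ranking <- function(x, ...) {
  cat("Variable ranking (mean decrease in Gini impurity):\n")
  print.data.frame(x, row.names = TRUE, ...)
  invisible(x)
}
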