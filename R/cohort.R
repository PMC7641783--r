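#' Construct a cohort table
#'
#' A cohort is a rectangular table of episodes (rows) by candidate predictors
#' plus one binary outcome column (1 = event, e.g. inpatient death). Each
#' predictor is declared continuous or categorical; undeclared kinds are
#' inferred from the column type (numeric columns are continuous, everything
#' else categorical).
#'
#' @param data a data.frame containing the outcome column and all predictors.
#' @param outcome name of the binary outcome column; values must be 0/1 with
#'   no missing entries.
#' @param kinds optional named character vector mapping predictor names to
#'   \code{"continuous"} or \code{"categorical"}; unnamed predictors are
#'   inferred.
#' @return an object of class \code{cohort}: a list with elements
#'   \code{data} (data.frame), \code{outcome} (column name) and \code{kinds}
#'   (named character vector covering every predictor).
#' @export
cohort <- function(data, outcome, kinds = NULL) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found in data", call. = FALSE)
  }
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be coded 0/1 with no missing values", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("cohort must contain at least one row", call. = FALSE)
  data[[outcome]] <- as.integer(y)
  preds <- setdiff(names(data), outcome)
  inferred <- vapply(
    data[preds],
    function(col) if (is.numeric(col)) "continuous" else "categorical",
    character(1)
  )
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), preds)
    if (length(bad)) {
      stop("kinds declared for unknown variables: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!all(kinds %in% c("continuous", "categorical"))) {
      stop("kinds must be 'continuous' or 'categorical'", call. = FALSE)
    }
    inferred[names(kinds)] <- kinds
  }
  # categorical columns kept as character internally; factors are built at
  # transform time so that level sets always come from the training split
  for (v in preds[inferred == "categorical"]) {
    data[[v]] <- as.character(data[[v]])
  }
  for (v in preds[inferred == "continuous"]) {
    if (!is.numeric(data[[v]])) {
      data[[v]] <- suppressWarnings(as.numeric(data[[v]]))
    }
  }
  structure(
    list(data = data, outcome = outcome, kinds = inferred),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$data)
  ev <- sum(x$data[[x$outcome]])
  cat(sprintf(
    "Cohort: %d episodes, %d predictors (%d continuous, %d categorical)\n",
    n, length(x$kinds), sum(x$kinds == "continuous"), sum(x$kinds == "categorical")
  ))
  cat(sprintf("Outcome '%s': %d events (%.1f%%)\n", x$outcome, ev, 100 * ev / n))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$data

#' @export
dim.cohort <- function(x) dim(x$data)

variables <- function(x) names(x$kinds)

#' Read a cohort table from a delimited file
#'
#' Reads a CSV (or TSV, chosen by file extension) with a header row. Empty
#' cells, \code{NA} and \code{n/a} are treated as missing; cells in a declared
#' continuous column that do not parse as numbers also become missing.
#'
#' @inheritParams cohort
#' @param file path to the delimited file.
#' @return a [cohort()] object.
#' @export
read_cohort <- function(file, outcome, kinds = NULL) {
  if (!file.exists(file)) stop("cohort file not found: ", file, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", file, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(
    file, header = TRUE, sep = sep, colClasses = "character",
    na.strings = c("", "NA", "n/a", "N/A"), check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (!outcome %in% names(raw)) {
    stop("outcome column '", outcome, "' not present in ", file, call. = FALSE)
  }
  raw[[outcome]] <- suppressWarnings(as.numeric(raw[[outcome]]))
  preds <- setdiff(names(raw), outcome)
  decl <- kinds
  for (v in preds) {
    k <- if (!is.null(decl) && v %in% names(decl)) decl[[v]] else {
      # infer: continuous if every non-missing cell parses as a number
      obs <- raw[[v]][!is.na(raw[[v]])]
      if (length(obs) && !anyNA(suppressWarnings(as.numeric(obs))))
        "continuous" else "categorical"
    }
    if (k == "continuous") raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  }
  cohort(raw, outcome = outcome, kinds = kinds)
}

#' Read plausibility ranges from a YAML or JSON config
#'
#' @param file path to a YAML/JSON file mapping variable names to
#'   \code{[low, high]} physical-plausibility bounds.
#' @return named list of length-2 numeric vectors.
#' @export
read_ranges <- function(file) {
  if (!file.exists(file)) stop("ranges file not found: ", file, call. = FALSE)
  ranges <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  lapply(ranges, function(r) {
    r <- as.numeric(unlist(r))
    if (length(r) != 2 || !r[1] < r[2]) {
      stop("each plausibility range must be [low, high] with low < high",
           call. = FALSE)
    }
    r
  })
}

#' Set physically implausible values to missing
#'
#' Values of continuous variables outside their plausibility range are
#' regarded as measurement or recording errors (outliers) and replaced by
#' missing values, to be filled later by training-median imputation.
#'
#' @param x a [cohort()] object.
#' @param ranges named list: variable -> c(low, high). Only continuous
#'   variables may be referenced. An empty list returns the cohort unchanged.
#' @return a new cohort with out-of-range cells set to \code{NA}.
#' @export
flag_outliers <- function(x, ranges) {
  stopifnot(inherits(x, "cohort"))
  if (length(ranges) == 0) return(x)
  unknown <- setdiff(names(ranges), variables(x))
  if (length(unknown)) {
    stop("plausibility range given for unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  noncont <- names(ranges)[x$kinds[names(ranges)] != "continuous"]
  if (length(noncont)) {
    stop("plausibility ranges only apply to continuous variables: ",
         paste(noncont, collapse = ", "), call. = FALSE)
  }
  for (v in names(ranges)) {
    r <- as.numeric(ranges[[v]])
    if (length(r) != 2 || !r[1] < r[2]) {
      stop("range for '", v, "' must be c(low, high) with low < high",
           call. = FALSE)
    }
    col <- x$data[[v]]
    out <- !is.na(col) & (col < r[1] | col > r[2])
    col[out] <- NA_real_
    x$data[[v]] <- col
  }
  x
}

#' Randomly split a cohort into training, validation and test sets
#'
#' Simple random, non-overlapping split; an optional outcome-stratified mode
#' draws the same fractions within each outcome class (useful for small
#' cohorts with rare events).
#'
#' @param x a [cohort()] object.
#' @param fractions length-3 positive numeric summing to 1:
#'   (train, validation, test) proportions. Default \code{c(0.7, 0.1, 0.2)}.
#' @param seed integer seed; the same seed always yields the same assignment.
#' @param stratify logical; if \code{TRUE} split within outcome classes.
#' @return list with cohort elements \code{train}, \code{validation},
#'   \code{test}.
#' @export
split_cohort <- function(x, fractions = c(0.7, 0.1, 0.2), seed = 1,
                         stratify = FALSE) {
  stopifnot(inherits(x, "cohort"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive numbers summing to 1", call. = FALSE)
  }
  n <- nrow(x$data)
  assign_rows <- function(idx) {
    m <- length(idx)
    n_train <- round(m * fractions[1])
    n_val <- round(m * fractions[2])
    if (n_train < 1 || n_val < 1 || m - n_train - n_val < 1) {
      stop("cohort too small: a partition would be empty", call. = FALSE)
    }
    perm <- sample(idx)
    list(
      train = perm[seq_len(n_train)],
      validation = perm[n_train + seq_len(n_val)],
      test = perm[(n_train + n_val + 1):m]
    )
  }
  parts <- with_seed(seed, {
    if (stratify) {
      y <- x$data[[x$outcome]]
      p0 <- assign_rows(which(y == 0))
      p1 <- assign_rows(which(y == 1))
      Map(c, p0, p1)
    } else {
      assign_rows(seq_len(n))
    }
  })
  take <- function(idx) {
    out <- x
    out$data <- x$data[sort(idx), , drop = FALSE]
    out
  }
  lapply(parts, take)
}

#' Impute missing values using the training partition only
#'
#' Continuous missing cells in every partition are filled with the median of
#' the observed training values (mean of the two central order statistics for
#' even counts). Categorical missing cells become an explicit
#' \code{"Unknown"} level, so missingness itself can carry points.
#'
#' @param train training-partition [cohort()].
#' @param others list of further cohorts (e.g. validation, test) imputed with
#'   the training medians; may be empty.
#' @return list with elements \code{train}, \code{others} (list) and
#'   \code{medians} (named numeric of the imputation values used).
#' @export
impute_from_training <- function(train, others = list()) {
  stopifnot(inherits(train, "cohort"))
  if (inherits(others, "cohort")) others <- list(others)
  cont <- variables(train)[train$kinds == "continuous"]
  cat_ <- variables(train)[train$kinds == "categorical"]
  medians <- vapply(cont, function(v) {
    obs <- train$data[[v]][!is.na(train$data[[v]])]
    if (!length(obs)) {
      stop("continuous variable '", v, "' has no observed training values; ",
           "cannot impute", call. = FALSE)
    }
    stats::median(obs)
  }, numeric(1))
  fill <- function(x) {
    for (v in cont) {
      col <- x$data[[v]]
      if (anyNA(col)) {
        col[is.na(col)] <- medians[[v]]
        x$data[[v]] <- col
      }
    }
    for (v in cat_) {
      col <- x$data[[v]]
      if (anyNA(col)) {
        col[is.na(col)] <- "Unknown"
        x$data[[v]] <- col
      }
    }
    x
  }
  list(train = fill(train), others = lapply(others, fill), medians = medians)
}
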