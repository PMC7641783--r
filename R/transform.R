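#' Quantile grid for discretising continuous predictors
#'
#' Continuous variables are cut at the k1, k2, k3, k4 sample percentiles of
#' the training data, giving at most \code{K = 5} ordered categories. The
#' defaults (5, 20, 80, 95) put the middle 60 percent of values in one
#' "normal" band with two graded bands on either side, which suits vital
#' signs and laboratory values with near-normal distributions.
#'
#' @param k strictly increasing percentages in (0, 100), default
#'   \code{c(5, 20, 80, 95)}.
#' @param K maximum number of categories per variable (continuous variables
#'   get at most \code{length(k) + 1}; categorical variables with more than
#'   \code{K} observed levels have their rarest levels pooled).
#' @return an object of class \code{quantile_grid}.
#' @export
quantile_grid <- function(k = c(5, 20, 80, 95), K = 5) {
  k <- as.numeric(k)
  if (any(diff(k) <= 0) || any(k <= 0) || any(k >= 100)) {
    stop("quantile percentages must be strictly increasing within (0, 100)",
         call. = FALSE)
  }
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  structure(list(k = k, K = K), class = "quantile_grid")
}

fmt_num <- function(x) {
  gsub(" ", "", formatC(signif(x, 7), format = "fg", digits = 7, big.mark = ""))
}

#' Interval labels for a cutoff vector
#'
#' j cutoffs define j + 1 left-closed bins: \code{(-Inf, c1)},
#' \code{[c1, c2)}, ..., \code{[cj, Inf)}, printed as \code{"<c1"},
#' \code{"c1-c2"}, ..., \code{">=cj"}. A label \code{"a-b"} therefore means
#' a <= x < b.
#'
#' @param cutoffs strictly increasing numeric vector.
#' @return character vector of length \code{length(cutoffs) + 1}.
#' @export
bin_labels <- function(cutoffs) {
  stopifnot(length(cutoffs) >= 1, all(diff(cutoffs) > 0) || length(cutoffs) == 1)
  s <- fmt_num(cutoffs)
  j <- length(cutoffs)
  if (j == 1) return(c(paste0("<", s), paste0(">=", s)))
  c(
    paste0("<", s[1]),
    paste0(s[-j], "-", s[-1]),
    paste0(">=", s[j])
  )
}

#' Derive quantile cutoffs for one continuous variable
#'
#' Computes the grid percentiles of the observed values (linear interpolation
#' between order statistics, \code{stats::quantile} type 7) and collapses
#' duplicates, so heavily tied variables yield fewer categories rather than
#' empty ones.
#'
#' @param x numeric vector of training values (missing values ignored).
#' @param grid a [quantile_grid()].
#' @return strictly increasing numeric cutoff vector of length 1..length(k).
#' @export
derive_cutoffs <- function(x, grid = quantile_grid()) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2) {
    stop("variable is constant; cannot derive cutoffs", call. = FALSE)
  }
  q <- stats::quantile(x, probs = grid$k / 100, type = 7, names = FALSE)
  unique(q)
}

#' Assign continuous values to interval categories
#'
#' Bins are left-closed, right-open: a value equal to a cutoff lands in the
#' bin whose label starts with that cutoff, and the top bin is unbounded
#' above.
#'
#' @param x numeric vector.
#' @param cutoffs strictly increasing numeric vector.
#' @return factor with levels \code{bin_labels(cutoffs)} in bin order.
#' @export
categorize_continuous <- function(x, cutoffs) {
  if (any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  labs <- bin_labels(cutoffs)
  idx <- findInterval(x, cutoffs) + 1L  # 0 below c1 -> level 1
  factor(labs[idx], levels = labs)
}

#' Pool rare categorical levels
#'
#' If a categorical variable has more observed levels than the maximum K, the
#' least frequent levels are pooled into an \code{"Other"} category so that
#' exactly K levels remain. Frequency ties are broken by level name so the
#' result is deterministic.
#'
#' @param counts named vector of level frequencies.
#' @param K maximum number of output levels (>= 2).
#' @return named character vector: observed level -> output level.
#' @export
merge_categories <- function(counts, K) {
  if (length(counts) == 0) stop("empty level set", call. = FALSE)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  lev <- names(counts)
  if (length(lev) <= K) {
    return(stats::setNames(lev, lev))
  }
  ord <- order(-as.numeric(counts), lev)  # frequency desc, name tie-break
  keep <- lev[ord][seq_len(K - 1L)]
  out <- ifelse(lev %in% keep, lev, "Other")
  stats::setNames(out, lev)
}

#' Build a transformation spec from training data
#'
#' For each selected continuous variable, derives quantile cutoffs from the
#' training values; for each categorical variable, builds a level map pooling
#' rare levels into "Other" when the level count exceeds K. Constant
#' continuous variables cannot be binned and are dropped with a warning.
#'
#' @param train training-partition [cohort()] (imputed).
#' @param vars variables to transform (defaults to all predictors).
#' @param grid a [quantile_grid()].
#' @return an object of class \code{transform_spec}: per-variable
#'   categorisation rules, editable and serialisable with
#'   [write_transform_spec()].
#' @export
make_transform_spec <- function(train, vars = NULL, grid = quantile_grid()) {
  stopifnot(inherits(train, "cohort"))
  vars <- vars %||% variables(train)
  rules <- list()
  for (v in vars) {
    if (train$kinds[[v]] == "continuous") {
      cuts <- tryCatch(derive_cutoffs(train$data[[v]], grid), error = function(e) NULL)
      if (is.null(cuts)) {
        warning("dropping constant variable '", v, "'", call. = FALSE)
        next
      }
      rules[[v]] <- list(type = "continuous", cutoffs = cuts)
    } else {
      counts <- table(train$data[[v]])
      map <- merge_categories(counts, grid$K)
      # output levels ordered by training frequency (name tie-break),
      # "Other" placed last; the first level is the initial reference
      kept <- unique(map[order(-as.numeric(counts), names(counts))])
      lev <- c(setdiff(kept, "Other"), intersect("Other", kept))
      rules[[v]] <- list(type = "categorical", map = map, levels = lev)
    }
  }
  structure(list(variables = rules, grid = grid), class = "transform_spec")
}

#' Categorise a cohort according to a transformation spec
#'
#' Continuous variables become ordered interval factors; categorical
#' variables are mapped through the spec's level map. A level unseen at
#' spec-derivation time maps to \code{"Other"} when that category exists,
#' otherwise to the variable's reference (first) level.
#'
#' @param x a [cohort()] (imputed; no missing cells among spec variables).
#' @param spec a [make_transform_spec()] result.
#' @return a cohort whose predictor columns are factors, of class
#'   \code{c("categorized_cohort", "cohort")}, restricted to the spec's
#'   variables plus the outcome.
#' @export
apply_transform <- function(x, spec) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "transform_spec"))
  missing_vars <- setdiff(names(spec$variables), variables(x))
  if (length(missing_vars)) {
    stop("cohort lacks spec variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(x$data)))
  for (v in names(spec$variables)) {
    rule <- spec$variables[[v]]
    col <- x$data[[v]]
    if (anyNA(col)) {
      stop("variable '", v, "' has missing values; impute before transforming",
           call. = FALSE)
    }
    if (rule$type == "continuous") {
      out[[v]] <- categorize_continuous(col, rule$cutoffs)
    } else {
      mapped <- unname(rule$map[as.character(col)])
      fallback <- if ("Other" %in% rule$levels) "Other" else rule$levels[1]
      mapped[is.na(mapped)] <- fallback
      out[[v]] <- factor(mapped, levels = rule$levels)
    }
  }
  out[[x$outcome]] <- x$data[[x$outcome]]
  res <- cohort(out, outcome = x$outcome,
                kinds = stats::setNames(rep("categorical", ncol(out) - 1L),
                                        setdiff(names(out), x$outcome)))
  # keep factor columns (cohort() coerces categoricals to character)
  for (v in setdiff(names(out), x$outcome)) res$data[[v]] <- out[[v]]
  res$spec <- spec
  class(res) <- c("categorized_cohort", "cohort")
  res
}

#' Override automatically derived cutoffs with domain-knowledge values
#'
#' Supports the fine-tuning step: automatically derived quantile cutoffs are
#' replaced by clinically conventional round values, after which the
#' transformation and score derivation are re-run.
#'
#' @param spec a \code{transform_spec}.
#' @param overrides named list: continuous variable -> strictly increasing
#'   cutoff vector. An empty list returns the spec unchanged.
#' @return the spec with the overridden cutoffs.
#' @export
fine_tune_cutoffs <- function(spec, overrides) {
  stopifnot(inherits(spec, "transform_spec"))
  if (length(overrides) == 0) return(spec)
  for (v in names(overrides)) {
    if (!v %in% names(spec$variables)) {
      stop("override for unknown variable '", v, "'", call. = FALSE)
    }
    if (spec$variables[[v]]$type != "continuous") {
      stop("cutoff override only applies to continuous variables ('", v, "')",
           call. = FALSE)
    }
    cuts <- as.numeric(overrides[[v]])
    if (length(cuts) < 1 || any(diff(cuts) <= 0)) {
      stop("override cutoffs for '", v, "' must be strictly increasing",
           call. = FALSE)
    }
    spec$variables[[v]]$cutoffs <- cuts
  }
  spec
}

#' Serialise a transformation spec to JSON
#'
#' The written file is the editable surface for cutoff fine-tuning; read it
#' back with [read_transform_spec()].
#'
#' @param spec a \code{transform_spec}.
#' @param path output file path.
#' @export
write_transform_spec <- function(spec, path) {
  stopifnot(inherits(spec, "transform_spec"))
  payload <- list(
    grid = list(k = spec$grid$k, K = spec$grid$K),
    variables = lapply(spec$variables, function(rule) {
      if (rule$type == "continuous") {
        list(type = "continuous", cutoffs = rule$cutoffs)
      } else {
        list(type = "categorical", map = as.list(rule$map), levels = rule$levels)
      }
    })
  )
  write_json_stable(payload, path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- lapply(payload$variables, function(rule) {
    if (rule$type == "continuous") {
      list(type = "continuous", cutoffs = as.numeric(rule$cutoffs))
    } else {
      list(type = "categorical", map = unlist(rule$map),
           levels = as.character(rule$levels))
    }
  })
  structure(
    list(variables = rules,
         grid = quantile_grid(k = payload$grid$k, K = payload$grid$K)),
    class = "transform_spec"
  )
}
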