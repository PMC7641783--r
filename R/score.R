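# Internal: ridge-penalised logistic regression by iteratively reweighted
# least squares. The penalty (lambda/2)*sum(beta^2) excludes the intercept
# and guarantees finite estimates under (quasi-)separation, e.g. categories
# with zero events. lambda defaults to 1e-4, small enough to leave
# well-conditioned fits essentially at maximum likelihood.
ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-10, max_iter = 100) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))  # column 1 is the intercept
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged)
}

#' Fit category-level logistic weights
#'
#' Fits a multivariable logistic regression of the binary outcome on one-hot
#' indicators of every variable's categories (each variable's first factor
#' level is the omitted reference). A small ridge penalty on the non-intercept
#' coefficients keeps estimates finite when a category has zero events; a
#' separation flag is set when any |coefficient| exceeds 10.
#'
#' @param x a categorized cohort from [apply_transform()].
#' @param vars variables to include, in order; defaults to all predictors.
#' @param lambda ridge penalty on non-intercept coefficients (default 1e-4).
#' @return an object of class \code{weight_fit}: intercept, per-variable
#'   named coefficient vectors over non-reference categories, reference
#'   levels, level orders, and \code{converged}/\code{separation} flags.
#' @export
fit_weights <- function(x, vars = NULL, lambda = 1e-4) {
  stopifnot(inherits(x, "categorized_cohort"))
  vars <- vars %||% variables(x)
  y <- x$data[[x$outcome]]
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; cannot fit weights", call. = FALSE)
  }
  # assemble indicator matrix manually so each coefficient stays tagged with
  # its (variable, level) pair
  cols <- list(`(Intercept)` = rep(1, length(y)))
  tags <- data.frame(variable = "(Intercept)", level = "", stringsAsFactors = FALSE)
  for (v in vars) {
    f <- x$data[[v]]
    if (!is.factor(f)) f <- factor(f)
    lev <- levels(f)
    for (l in lev[-1]) {
      cols[[paste(v, l, sep = "=")]] <- as.numeric(f == l)
      tags <- rbind(tags, data.frame(variable = v, level = l,
                                     stringsAsFactors = FALSE))
    }
  }
  X <- do.call(cbind, cols)
  fit <- ridge_logistic(X, y, lambda = lambda)
  beta <- stats::setNames(fit$beta, colnames(X))
  coefs <- lapply(vars, function(v) {
    idx <- which(tags$variable == v)
    stats::setNames(beta[idx], tags$level[idx])
  })
  names(coefs) <- vars
  refs <- vapply(vars, function(v) {
    f <- x$data[[v]]
    levels(if (is.factor(f)) f else factor(f))[1]
  }, character(1))
  level_order <- lapply(vars, function(v) levels(x$data[[v]]))
  names(level_order) <- vars
  structure(
    list(
      intercept = unname(beta[1]),
      coef = coefs,
      references = refs,
      levels = level_order,
      variables = vars,
      lambda = lambda,
      converged = fit$converged,
      separation = any(abs(beta[-1]) > 10),
      clamped = character(0)
    ),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("Category-level logistic fit: %d variables, intercept %.4f\n",
              length(x$variables), x$intercept))
  if (x$separation) cat("note: quasi-separation detected (|beta| > 10)\n")
  if (length(x$clamped)) {
    cat("note: clamped to zero:", paste(x$clamped, collapse = ", "), "\n")
  }
  for (v in x$variables) {
    cat(v, " (ref: ", x$references[[v]], ")\n", sep = "")
    print(round(x$coef[[v]], 4))
  }
  invisible(x)
}

# coefficient of every category, with the reference explicit at 0, in level order
full_coef <- function(fit, v) {
  lev <- fit$levels[[v]]
  b <- stats::setNames(numeric(length(lev)), lev)
  b[names(fit$coef[[v]])] <- fit$coef[[v]]
  b
}

#' Re-reference categories at the lowest-risk level and refit
#'
#' For each variable, the category with the lowest first-pass coefficient
#' (counting the original reference as zero) becomes the new reference, and
#' the logistic model is refitted. This makes every remaining coefficient
#' nonnegative up to estimation noise; any residual negative second-pass
#' coefficient is clamped to zero with a warning.
#'
#' @param fit a first-pass [fit_weights()] result.
#' @param x the categorized training cohort the fit came from.
#' @return a second-pass \code{weight_fit} with nonnegative coefficients;
#'   clamped categories are listed in \code{$clamped}.
#' @export
relevel_references <- function(fit, x) {
  stopifnot(inherits(fit, "weight_fit"), inherits(x, "categorized_cohort"))
  for (v in fit$variables) {
    b <- full_coef(fit, v)
    new_ref <- names(b)[which.min(b)]  # ties: first level in order
    f <- x$data[[v]]
    x$data[[v]] <- stats::relevel(f, ref = new_ref)
  }
  refit <- fit_weights(x, vars = fit$variables, lambda = fit$lambda)
  clamped <- character(0)
  for (v in refit$variables) {
    b <- refit$coef[[v]]
    neg <- b < 0
    if (any(neg)) {
      clamped <- c(clamped, paste(v, names(b)[neg], sep = "="))
      b[neg] <- 0
      refit$coef[[v]] <- b
    }
  }
  if (length(clamped)) {
    warning("negative second-pass coefficient(s) clamped to 0: ",
            paste(clamped, collapse = ", "), call. = FALSE)
    refit$clamped <- clamped
  }
  refit
}

#' Convert releveled coefficients to integer points
#'
#' All second-pass coefficients are divided by the smallest coefficient
#' exceeding \code{eps} across all variables (\code{beta_lowest}) and rounded
#' half away from zero, so the least influential informative category maps to
#' one point and every reference maps to zero.
#'
#' @param fit a releveled, nonnegative [relevel_references()] fit.
#' @param spec optional \code{transform_spec} embedded in the table so the
#'   table alone can score raw (uncategorised) episodes.
#' @param eps coefficients at or below this value are treated as numerically
#'   zero and excluded from the \code{beta_lowest} search (default 1e-6).
#' @return an object of class \code{score_table}: per-variable named integer
#'   point vectors (in category order, references at 0), \code{min_total},
#'   \code{max_total}, and \code{beta_lowest}.
#' @export
derive_points <- function(fit, spec = NULL, eps = 1e-6) {
  stopifnot(inherits(fit, "weight_fit"))
  all_b <- unlist(lapply(fit$variables, function(v) fit$coef[[v]]))
  if (any(all_b < 0)) {
    stop("coefficients must be nonnegative; run relevel_references first",
         call. = FALSE)
  }
  pos <- all_b[all_b > eps]
  if (!length(pos)) {
    stop("no coefficient exceeds eps; score would be identically zero",
         call. = FALSE)
  }
  beta_lowest <- min(pos)
  pts <- lapply(fit$variables, function(v) {
    b <- full_coef(fit, v)
    p <- round_half_up(b / beta_lowest)
    # keep the variable's natural (bin/frequency) order for presentation
    lev <- fit$levels[[v]]
    natural <- if (!is.null(spec) && !is.null(spec$variables[[v]])) {
      rule <- spec$variables[[v]]
      if (rule$type == "continuous") bin_labels(rule$cutoffs) else rule$levels
    } else lev
    p[intersect(natural, names(p))]
  })
  names(pts) <- fit$variables
  structure(
    list(
      points = pts,
      references = fit$references,
      beta_lowest = beta_lowest,
      min_total = sum(vapply(pts, min, numeric(1))),
      max_total = sum(vapply(pts, max, numeric(1))),
      ceiling = NULL,
      spec = spec
    ),
    class = "score_table"
  )
}

#' Assemble a score table from explicit category points
#'
#' Builds a \code{score_table} directly from per-variable category point
#' maps, e.g. to encode a published point score for scoring or evaluation.
#' When \code{cutoffs} are supplied for a continuous variable, the category
#' names must equal \code{bin_labels(cutoffs)} and the table can then score
#' raw values via [score_episodes()].
#'
#' @param points named list: variable -> named nonnegative integer vector
#'   (category label -> points).
#' @param cutoffs optional named list: continuous variable -> strictly
#'   increasing cutoff vector.
#' @param references optional named character vector of reference categories;
#'   defaults to each variable's first zero-point category (or first
#'   category).
#' @return a \code{score_table}.
#' @export
as_score_table <- function(points, cutoffs = NULL, references = NULL) {
  stopifnot(is.list(points), length(points) >= 1)
  for (v in names(points)) {
    p <- points[[v]]
    if (is.null(names(p)) || any(p < 0) || any(p != round(p))) {
      stop("points for '", v, "' must be named nonnegative integers",
           call. = FALSE)
    }
  }
  if (is.null(references)) {
    references <- vapply(points, function(p) {
      zero <- names(p)[p == 0]
      if (length(zero)) zero[1] else names(p)[1]
    }, character(1))
  }
  spec <- NULL
  if (!is.null(cutoffs)) {
    rules <- list()
    for (v in names(points)) {
      if (!is.null(cutoffs[[v]])) {
        if (!identical(bin_labels(cutoffs[[v]]), names(points[[v]]))) {
          stop("category names for '", v, "' must match bin_labels(cutoffs)",
               call. = FALSE)
        }
        rules[[v]] <- list(type = "continuous", cutoffs = cutoffs[[v]])
      } else {
        lev <- names(points[[v]])
        rules[[v]] <- list(type = "categorical",
                           map = stats::setNames(lev, lev), levels = lev)
      }
    }
    spec <- structure(list(variables = rules, grid = quantile_grid()),
                      class = "transform_spec")
  }
  structure(
    list(
      points = points,
      references = references,
      beta_lowest = NA_real_,
      min_total = sum(vapply(points, min, numeric(1))),
      max_total = sum(vapply(points, max, numeric(1))),
      ceiling = NULL,
      spec = spec
    ),
    class = "score_table"
  )
}

#' Rescale a score table to a total-score ceiling
#'
#' Multiplies every point value by \code{ceiling / max_total} and rounds half
#' away from zero; references stay at zero. Because each variable rounds
#' independently, the rescaled maximum can exceed the ceiling by at most the
#' number of variables.
#'
#' @param table a [derive_points()] score table with \code{max_total > 0}.
#' @param ceiling target maximum total score; must be at least the number of
#'   variables, otherwise the rescaled points would collapse together.
#' @return the rescaled \code{score_table}.
#' @export
normalize_to_ceiling <- function(table, ceiling) {
  stopifnot(inherits(table, "score_table"))
  if (table$max_total <= 0) stop("max_total must be positive", call. = FALSE)
  if (ceiling < length(table$points)) {
    stop("ceiling must be at least the number of variables", call. = FALSE)
  }
  f <- ceiling / table$max_total
  table$points <- lapply(table$points, function(p) round_half_up(p * f))
  table$min_total <- sum(vapply(table$points, min, numeric(1)))
  table$max_total <- sum(vapply(table$points, max, numeric(1)))
  table$ceiling <- ceiling
  table
}

#' Total score of categorised episodes
#'
#' Sums each episode's per-variable points. A category absent from the table
#' falls back to \code{"Other"} when the variable has one, otherwise to the
#' variable's reference category.
#'
#' @param x a categorized cohort, or a data.frame whose columns give each
#'   score-table variable's category label per episode.
#' @param table a \code{score_table}.
#' @return integer-valued numeric vector of total scores.
#' @export
compute_score <- function(x, table) {
  stopifnot(inherits(table, "score_table"))
  df <- if (inherits(x, "cohort")) x$data else x
  totals <- numeric(nrow(df))
  for (v in names(table$points)) {
    if (!v %in% names(df)) {
      stop("episodes lack score variable '", v, "'", call. = FALSE)
    }
    p <- table$points[[v]]
    lab <- as.character(df[[v]])
    pts <- unname(p[lab])
    if (anyNA(pts)) {
      fallback <- if ("Other" %in% names(p)) "Other" else table$references[[v]]
      if (is.na(fallback) || !fallback %in% names(p)) {
        stop("unknown category in '", v, "' and no fallback available",
             call. = FALSE)
      }
      pts[is.na(pts)] <- p[[fallback]]
    }
    totals <- totals + pts
  }
  totals
}

#' Score raw (uncategorised) episodes with a score table
#'
#' Categorises episodes with the transform spec embedded in the table, then
#' sums points. This makes a persisted score table the complete deployable
#' object.
#'
#' @param table a \code{score_table} carrying a transform spec.
#' @param data data.frame of raw predictor values (no missing cells among
#'   score variables).
#' @param outcome optional name of an outcome column present in \code{data}.
#' @return numeric vector of total scores.
#' @export
score_episodes <- function(table, data, outcome = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(table$spec)) {
    stop("score table carries no transform spec; use compute_score on ",
         "categorised episodes instead", call. = FALSE)
  }
  spec <- table$spec
  spec$variables <- spec$variables[names(table$points)]
  tmp <- data[names(table$points)]
  tmp$..y.. <- if (!is.null(outcome)) data[[outcome]] else 0L
  ch <- cohort(tmp, outcome = "..y..")
  compute_score(apply_transform(ch, spec), table)
}

# linear predictor (type "lp", includes the intercept) or pre-rounding
# normalised score sum(beta / beta_lowest) (type "prerounding") of
# categorised episodes under a weight fit
predict_weights <- function(fit, x, type = c("lp", "prerounding"), eps = 1e-6) {
  type <- match.arg(type)
  df <- if (inherits(x, "cohort")) x$data else x
  denom <- 1
  if (type == "prerounding") {
    all_b <- unlist(fit$coef)
    pos <- all_b[all_b > eps]
    denom <- min(pos)
  }
  out <- if (type == "lp") rep(fit$intercept, nrow(df)) else numeric(nrow(df))
  for (v in fit$variables) {
    b <- full_coef(fit, v) / denom
    out <- out + unname(b[as.character(df[[v]])])
  }
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat("Point-based risk score\n")
  if (!is.null(x$ceiling)) cat("(normalised to ceiling", x$ceiling, ")\n")
  df <- as.data.frame(x)
  for (v in unique(df$variable)) {
    cat("\n", v, "\n", sep = "")
    sub <- df[df$variable == v, c("interval", "points")]
    cat(sprintf("  %-14s %4d\n", sub$interval, as.integer(sub$points)), sep = "")
  }
  cat(sprintf("\nTotal score range: %d to %d\n",
              as.integer(x$min_total), as.integer(x$max_total)))
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  do.call(rbind, lapply(names(x$points), function(v) {
    data.frame(
      variable = v,
      interval = names(x$points[[v]]),
      points = as.numeric(x$points[[v]]),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }))
}

#' Serialise a score table to JSON
#'
#' @param table a \code{score_table}.
#' @param path output path; read back with [read_score_table()].
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  payload <- list(
    points = lapply(table$points, as.list),
    references = as.list(table$references),
    beta_lowest = table$beta_lowest,
    min_total = table$min_total,
    max_total = table$max_total,
    ceiling = table$ceiling
  )
  if (!is.null(table$spec)) {
    payload$spec <- list(
      grid = list(k = table$spec$grid$k, K = table$spec$grid$K),
      variables = lapply(table$spec$variables, function(rule) {
        if (rule$type == "continuous") {
          list(type = "continuous", cutoffs = rule$cutoffs)
        } else {
          list(type = "categorical", map = as.list(rule$map),
               levels = rule$levels)
        }
      })
    )
  }
  write_json_stable(payload, path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- NULL
  if (!is.null(payload$spec)) {
    rules <- lapply(payload$spec$variables, function(rule) {
      if (rule$type == "continuous") {
        list(type = "continuous", cutoffs = as.numeric(rule$cutoffs))
      } else {
        list(type = "categorical", map = unlist(rule$map),
             levels = as.character(rule$levels))
      }
    })
    spec <- structure(
      list(variables = rules,
           grid = quantile_grid(k = payload$spec$grid$k, K = payload$spec$grid$K)),
      class = "transform_spec"
    )
  }
  structure(
    list(
      points = lapply(payload$points, unlist),
      references = unlist(payload$references),
      beta_lowest = payload$beta_lowest,
      min_total = payload$min_total,
      max_total = payload$max_total,
      ceiling = payload$ceiling,
      spec = spec
    ),
    class = "score_table"
  )
}
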