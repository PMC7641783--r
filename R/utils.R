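#' Round half away from zero
#'
#' Rounding rule used when converting normalised regression coefficients to
#' integer points: 2.5 becomes 3 and -2.5 becomes -3, unlike [base::round()]
#' which rounds half to even. This is the convention of hand-computed clinical
#' scores.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, -2.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# fan a user seed out to stage-specific seeds, keeping them in 32-bit range
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% .Machine$integer.max
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  expr
}

# deterministic JSON writer: fixed precision-free number formatting,
# stable key order as supplied by the caller
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
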