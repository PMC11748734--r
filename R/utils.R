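#' Run an expression under a fixed seed without disturbing the session RNG
#'
#' Thin wrapper over [withr::with_seed()]; when `seed` is `NULL` the
#' expression runs under the current RNG state.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a stream of child seeds from one master seed
#'
#' Stages of the pipeline each get their own deterministic seed so that a
#' stage can be re-run in isolation. Seeds stay below 2^31 - 1.
#'
#' @keywords internal
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' `base::round` rounds half to even; edge-count rounding in proportional
#' thresholding uses the half-away-from-zero convention instead.
#'
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Two-tailed Pearson correlation with t-based p value
#'
#' @keywords internal
pearson_test <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in input")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}
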