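#' Test-retest reliability of network edges
#'
#' Edgewise intraclass correlation (one-way random-effects ICC) across
#' repeated sessions, reliability bin classification, and permutation
#' comparison of reliability between edge sets.
#'
#' @name trt-reliability
NULL

#' One-way random-effects intraclass correlation
#'
#' `ICC = (MS_b - MS_w) / (MS_b + (k - 1) MS_w)` where MS_b and MS_w are
#' the between- and within-subject mean squares of a one-way ANOVA with
#' subject as the random factor and k repeated observations per subject.
#' Values can be negative when within-subject variability exceeds
#' between-subject variability; they are reported unclamped.
#'
#' @param measurements numeric matrix, subjects x sessions, no missing
#'   cells.
#' @return ICC value (<= 1).
#' @export
#' @examples
#' icc(cbind(c(1, 2, 3), c(1.2, 2.1, 2.9)))
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("ICC requires complete data: missing session value")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("ICC needs at least 2 subjects")
  if (k < 2) stop("ICC needs at least 2 sessions")
  grand <- mean(m)
  subj_means <- rowMeans(m)
  ss_b <- k * sum((subj_means - grand)^2)
  ss_w <- sum((m - subj_means)^2)
  if (ss_b + ss_w == 0) stop("ICC undefined: zero total variance")
  ms_b <- ss_b / (n - 1)
  ms_w <- ss_w / (n * (k - 1))
  (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
}

#' Edgewise ICC for a network block across sessions
#'
#' Computes the ICC of every unique edge of the requested block across the
#' supplied sessions. For more than two sessions, pass the session pair
#' (or triple) of interest via `sessions`; reliability between e.g.
#' sessions 1 and 2, 1 and 3, and 2 and 3 is obtained by three calls.
#'
#' @param networks nested list `networks[[subject]][[session]]` of
#'   `morph_network` objects (as from [build_cohort_networks()]).
#' @param block `"gg"`, `"ss"`, `"gs"` or `"gsgs"`.
#' @param sessions indices of the sessions to use (default: all).
#' @return An `icc_result`: list with `icc` (one value per unique edge),
#'   `bin` (reliability bin per edge), `k` (sessions used) and `block`.
#' @export
edgewise_icc <- function(networks, block = c("gg", "ss", "gs", "gsgs"),
                         sessions = NULL) {
  block <- match.arg(block)
  n_sess <- unique(lengths(networks))
  if (length(n_sess) != 1) stop("subjects differ in session count")
  if (is.null(sessions)) sessions <- seq_len(n_sess)
  if (length(sessions) < 2) stop("need at least 2 sessions for ICC")
  if (any(sessions > n_sess)) stop("session index out of range")
  # edge matrix per session: subjects x edges
  edge_mats <- lapply(sessions, function(t) {
    do.call(rbind, lapply(networks, function(subj) {
      .block_edge_vector(subj[[t]], block)
    }))
  })
  n_edges <- ncol(edge_mats[[1]])
  vals <- vapply(seq_len(n_edges), function(e) {
    icc(do.call(cbind, lapply(edge_mats, function(m) m[, e])))
  }, 0)
  structure(list(icc = vals, bin = classify_icc(vals),
                 k = length(sessions), block = block),
            class = "icc_result")
}

.icc_bins <- data.frame(
  label = c("poor", "low", "fair", "good", "excellent"),
  lo = c(-Inf, 0.25, 0.4, 0.6, 0.75),
  hi = c(0.25, 0.4, 0.6, 0.75, Inf),
  stringsAsFactors = FALSE
)

#' Reliability bin of an ICC value
#'
#' Bins follow the conventional breakpoints 0.25 / 0.4 / 0.6 / 0.75 with
#' half-open intervals \[lo, hi): poor (< 0.25, including negative
#' values), low, fair, good, excellent (>= 0.75, including 1).
#'
#' @param value ICC value(s) (<= 1).
#' @return Character vector of bin labels.
#' @export
classify_icc <- function(value) {
  if (any(value > 1 + 1e-12)) stop("ICC cannot exceed 1")
  idx <- findInterval(value, .icc_bins$lo[-1]) + 1L
  .icc_bins$label[idx]
}

#' Permutation comparison of two edge reliability distributions
#'
#' Observed statistic is `mean(icc_a) - mean(icc_b)`; the null pools both
#' edge sets and re-splits at the original sizes. Edges are treated as
#' exchangeable units. Two-tailed p with the add-one convention.
#'
#' @param icc_a,icc_b numeric vectors of edgewise ICCs.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `mean_diff`, `p` and `n_perm`.
#' @export
compare_reliability <- function(icc_a, icc_b, n_perm = 10000, seed = NULL) {
  if (length(icc_a) == 0 || length(icc_b) == 0) stop("empty ICC list")
  obs <- mean(icc_a) - mean(icc_b)
  pooled <- c(icc_a, icc_b)
  na <- length(icc_a)
  total <- sum(pooled)
  n_tot <- length(pooled)
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    ia <- sample.int(n_tot, na)
    sa <- sum(pooled[ia])
    sa / na - (total - sa) / (n_tot - na)
  }, 0))
  p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (1 + n_perm)
  list(mean_diff = obs, p = p, n_perm = n_perm)
}
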