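#' Shared evaluation grid for a pair of vertex samples
#'
#' Divergences require the two densities to live on one support. The grid
#' is `n_points` equally spaced values spanning the pooled range of both
#' samples, padded by 10% of the pooled range on each side so Gaussian
#' tails are not clipped at the extremes.
#'
#' @param values_a,values_b numeric vertex samples (each with SD > 0).
#' @param n_points grid length; 256 (2^8) by default.
#' @return Strictly increasing numeric vector of length `n_points`.
#' @export
common_grid <- function(values_a, values_b, n_points = 256) {
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("degenerate sample: zero variance, density comparison undefined")
  }
  rng <- range(c(values_a, values_b))
  pad <- 0.1 * diff(rng)
  seq(rng[1] - pad, rng[2] + pad, length.out = n_points)
}

#' Discretized kernel density estimate on a grid
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth evaluated on an
#' equally spaced grid, then renormalized to sum to 1 — the sampled density
#' is treated as a discrete probability distribution, which is what the
#' divergence formulas consume.
#'
#' @param values numeric sample (>= 10 values).
#' @param grid equally spaced, strictly increasing support points.
#' @return Numeric vector of probabilities, same length as `grid`,
#'   summing to 1.
#' @export
estimate_density <- function(values, grid) {
  if (length(values) < 10) stop("need at least 10 values for a density estimate")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  bw <- stats::bw.nrd0(values)
  if (bw <= 0) stop("zero bandwidth: sample is degenerate")
  if (length(grid) >= 8) {
    d <- stats::density(values, bw = bw, n = length(grid),
                        from = grid[1], to = grid[length(grid)])
    p <- d$y
  } else {
    # density() needs a power-of-two internal grid; tiny grids are evaluated
    # exactly instead
    p <- vapply(grid, function(g) mean(stats::dnorm(g, values, bw)), 0)
  }
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) stop("density vanished on the supplied grid")
  p / s
}

.check_support <- function(P, Q) {
  if (length(P) != length(Q)) stop("support mismatch: P and Q differ in length")
  if (any(P < 0) || any(Q < 0)) stop("probabilities must be non-negative")
}

#' Kullback-Leibler divergence of discrete distributions (bits)
#'
#' `sum(P[i] * log2(P[i] / Q[i]))` over points with `P[i] > 0`; terms with
#' `P[i] = 0` contribute 0. Base-2 logarithms throughout, so the derived
#' Jensen-Shannon divergence is bounded by 1.
#'
#' @param P,Q probability vectors on a shared support.
#' @return Non-negative divergence in bits.
#' @export
kld <- function(P, Q) {
  .check_support(P, Q)
  i <- P > 0
  if (any(Q[i] == 0)) {
    stop("KLD undefined: Q is zero where P has mass")
  }
  sum(P[i] * log2(P[i] / Q[i]))
}

#' Jensen-Shannon divergence (bits)
#'
#' Symmetrized divergence `0.5 * KLD(P || M) + 0.5 * KLD(Q || M)` with
#' `M = (P + Q) / 2`. With base-2 logarithms JSD lies in \[0, 1\]; the
#' mixture is strictly positive wherever either argument has mass, so JSD
#' is always defined.
#'
#' @inheritParams kld
#' @return Divergence in \[0, 1\].
#' @export
jsd <- function(P, Q) {
  .check_support(P, Q)
  M <- (P + Q) / 2
  0.5 * kld(P, M) + 0.5 * kld(Q, M)
}

#' Similarity transform of a Jensen-Shannon divergence
#'
#' `1 - sqrt(j)`: identical distributions map to 1, maximally divergent
#' ones to 0. A `j` outside \[0, 1\] signals a wrong logarithm base
#' upstream and is rejected.
#'
#' @param j JSD value(s) in \[0, 1\].
#' @return Similarity in \[0, 1\].
#' @export
similarity_from_jsd <- function(j) {
  if (any(j < -1e-12 | j > 1 + 1e-12)) {
    stop("JSD outside [0, 1]: check the logarithm base")
  }
  1 - sqrt(pmin(pmax(j, 0), 1))
}
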