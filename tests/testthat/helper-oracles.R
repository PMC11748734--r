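# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the libraries standing behind them) so that every
# cross-check is a genuine dual route.

oracle_jsd <- function(P, Q) {
  M <- (P + Q) / 2
  acc <- 0
  for (i in seq_along(P)) {
    if (P[i] > 0) acc <- acc + 0.5 * P[i] * log(P[i] / M[i]) / log(2)
    if (Q[i] > 0) acc <- acc + 0.5 * Q[i] * log(Q[i] / M[i]) / log(2)
  }
  acc
}

oracle_kld <- function(P, Q) {
  acc <- 0
  for (i in seq_along(P)) {
    if (P[i] > 0) acc <- acc + P[i] * log(P[i] / Q[i]) / log(2)
  }
  acc
}

# mean local clustering by explicit triangle counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + adj[nb[a], nb[b]]
    }
    vals[v] <- 2 * links / (k * (k - 1))
  }
  mean(vals)
}

# mean shortest path over reachable pairs by Floyd-Warshall
oracle_path_length <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  up <- d[upper.tri(d)]
  list(lp = mean(up[is.finite(up)]), disconnected = any(!is.finite(up)))
}

# one-way random-effects ICC through R's ANOVA machinery
oracle_icc <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- stats::anova(stats::lm(y ~ subject, data = df))
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Benjamini-Hochberg step-up written out by hand
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  kmax <- max(c(0L, which(ranked <= seq_len(m) / m * q)))
  sig <- logical(m)
  if (kmax > 0) sig[o[seq_len(kmax)]] <- TRUE
  adj <- pmin(rev(cummin(rev(ranked * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- adj
  list(significant = sig, adjusted = out)
}

oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

random_discrete_dist <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

random_graph_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# adjacency of the i-th of the 2^(n(n-1)/2) labelled graphs on n nodes
indexed_graph_adj <- function(i, n) {
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(i))[seq_len(m)]
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- bits
  a + t(a)
}
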