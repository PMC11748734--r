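#' Graph topology of thresholded similarity networks
#'
#' Weighted similarity matrices are binarized by proportional (sparsity)
#' thresholding, and characterised by the two small-world parameters —
#' clustering coefficient Cp and characteristic path length Lp — normalized
#' against degree-preserving rewired null networks, across a sparsity
#' range summarized by the area under each curve.
#'
#' @name graph-topology
NULL

#' Maximum possible edge count of an undirected simple graph
#'
#' @param N node count (>= 1).
#' @return `N * (N - 1) / 2`.
#' @export
#' @examples
#' max_edges(58) # 1653
#' max_edges(62) # 1891
max_edges <- function(N) {
  stopifnot(N >= 1)
  as.integer(round(N * (N - 1) / 2))
}

#' Minimal sparsity at which small-world attributes are estimable
#'
#' A binary network is taken as estimable when its average degree
#' `s * (N - 1)` reaches `log(N)` (natural log). The smallest such
#' sparsity, `log(N) / (N - 1)`, is returned rounded to 3 decimals:
#' 0.071 for N = 58 and 0.068 for N = 62.
#'
#' @param N node count (>= 3).
#' @return Sparsity threshold, rounded to 3 decimals.
#' @export
min_estimable_sparsity <- function(N) {
  stopifnot(N >= 3)
  round(log(N) / (N - 1), 3)
}

#' Proportional (sparsity-based) thresholding
#'
#' Retains the `round(s * N(N-1)/2)` strongest unique edges of a weighted
#' symmetric matrix (rounding half away from zero). Ties at the cutoff are
#' broken by ascending (row, column) index, which makes thresholding
#' deterministic and edge sets nested across increasing sparsities.
#'
#' @param W symmetric numeric matrix with finite entries; the diagonal is
#'   ignored.
#' @param s target sparsity in (0, 1].
#' @return A `binary_graph`: list with `adj` (0/1 symmetric matrix, zero
#'   diagonal), `n`, `n_edges` and realized `sparsity`.
#' @export
proportional_threshold <- function(W, s) {
  if (!isSymmetric(unname(W), tol = 1e-8)) stop("W must be symmetric")
  if (any(!is.finite(W))) stop("W must be finite")
  if (s <= 0 || s > 1) stop("sparsity must be in (0, 1]")
  N <- nrow(W)
  m_max <- max_edges(N)
  k <- as.integer(round_half_away(s * m_max))
  if (k < 1) stop(sprintf("sparsity %.4f retains zero edges for N = %d", s, N))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(-W[upper.tri(W)], ut[, 1], ut[, 2])
  keep <- ut[ord[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, N, N, dimnames = dimnames(W))
  adj[keep] <- 1L
  adj <- adj + t(adj)
  structure(list(adj = adj, n = N, n_edges = k, sparsity = k / m_max),
            class = "binary_graph")
}

#' @keywords internal
as_binary_graph <- function(adj) {
  dn <- dimnames(adj)
  adj <- (unname(adj) != 0) * 1L
  diag(adj) <- 0L
  if (!isSymmetric(adj)) stop("adjacency must be symmetric")
  dimnames(adj) <- dn
  n <- nrow(adj)
  m <- sum(adj) / 2
  structure(list(adj = adj, n = n, n_edges = as.integer(m),
                 sparsity = m / max_edges(n)),
            class = "binary_graph")
}

#' @keywords internal
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected", diag = FALSE)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d nodes, %d edges (sparsity %.3f)\n",
              x$n, x$n_edges, x$sparsity))
  invisible(x)
}

#' Mean clustering coefficient Cp
#'
#' Average over nodes of the local clustering coefficient (closed triangles
#' over possible triangles at the node); nodes of degree < 2 contribute 0.
#'
#' @param g a `binary_graph`.
#' @return Cp in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n >= 3)
  local <- igraph::transitivity(as_igraph(g), type = "localundirected",
                                isolates = "zero")
  mean(local)
}

#' Characteristic path length Lp
#'
#' Mean shortest-path length over reachable unordered node pairs. If the
#' graph is disconnected the mean is taken over reachable pairs only and
#' the result carries attribute `disconnected = TRUE`, which keeps
#' sparsity curves finite.
#'
#' @param g a `binary_graph` with at least one edge.
#' @return Lp (>= 1) with logical attribute `disconnected`.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "binary_graph"), g$n >= 2)
  if (g$n_edges == 0) stop("Lp undefined for an edgeless graph")
  d <- igraph::distances(as_igraph(g))
  dv <- d[upper.tri(d)]
  reachable <- is.finite(dv)
  lp <- mean(dv[reachable])
  attr(lp, "disconnected") <- any(!reachable)
  lp
}

#' Degree-preserving rewiring (double edge swaps)
#'
#' Produces a randomized null network with exactly the input's degree
#' sequence via repeated double edge swaps. If no swap could be applied
#' (e.g. a complete graph) the input topology is returned with a warning.
#'
#' @param g a `binary_graph`.
#' @param n_swaps number of attempted swaps (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return Rewired `binary_graph`.
#' @export
rewire_preserving_degree <- function(g, n_swaps, seed = NULL) {
  stopifnot(inherits(g, "binary_graph"), n_swaps >= 1)
  ig <- as_igraph(g)
  rg <- with_seed(seed,
                  igraph::rewire(ig, igraph::keeping_degseq(niter = n_swaps)))
  adj <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both", sparse = FALSE))
  dimnames(adj) <- dimnames(g$adj)
  out <- as_binary_graph(adj)
  complete <- g$n_edges == max_edges(g$n)
  if (identical(out$adj, g$adj) && !complete && g$n_edges >= 2) {
    warning("rewiring left the graph unchanged: no admissible swap found")
  }
  out
}

#' Small-world parameters normalized by rewired nulls
#'
#' gamma = Cp / mean(Cp of nulls), lambda = Lp / mean(Lp of nulls), with
#' `n_null` degree-matched rewired networks of `10 * |E|` swaps each. A
#' small-world network has gamma > 1 and lambda ~ 1.
#'
#' @param g a `binary_graph`.
#' @param n_null number of null networks (default 100).
#' @param seed RNG seed.
#' @return List with `gamma`, `lambda`, `cp`, `lp`, `cp_rand`, `lp_rand`,
#'   and `disconnected` (flag from the observed graph's Lp).
#' @export
normalized_small_world <- function(g, n_null = 100, seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  cp <- clustering_coefficient(g)
  lp <- characteristic_path_length(g)
  n_swaps <- max(1L, 10L * g$n_edges)
  null_seeds <- spawn_seeds(seed, n_null)
  null_stats <- vapply(seq_len(n_null), function(b) {
    rg <- suppressWarnings(
      rewire_preserving_degree(g, n_swaps, seed = null_seeds[b]))
    c(clustering_coefficient(rg),
      as.numeric(characteristic_path_length(rg)))
  }, numeric(2))
  cp_rand <- mean(null_stats[1, ])
  lp_rand <- mean(null_stats[2, ])
  if (cp_rand <= 0) stop("null clustering is zero: normalization undefined")
  list(gamma = cp / cp_rand, lambda = as.numeric(lp) / lp_rand,
       cp = cp, lp = as.numeric(lp),
       cp_rand = cp_rand, lp_rand = lp_rand,
       disconnected = isTRUE(attr(lp, "disconnected")))
}

#' Small-world curves across a sparsity range
#'
#' Thresholds a weighted network at each sparsity of the range (default
#' 0.08 to 0.40, step 0.02 — 17 thresholds), computes Cp, Lp and their
#' null-normalized versions, and summarizes each curve by its area under
#' the curve over the sparsity range.
#'
#' @param W weighted symmetric similarity matrix.
#' @param sparsities increasing sparsity values.
#' @param n_null rewired nulls per sparsity.
#' @param seed RNG seed.
#' @return A `small_world_result`: list with `curves` (data frame: one row
#'   per sparsity with `sparsity`, `cp`, `lp`, `cp_rand`, `lp_rand`,
#'   `gamma`, `lambda`, `disconnected`) and `auc` (named list with the
#'   trapezoidal AUC of each curve).
#' @export
sparsity_sweep <- function(W, sparsities = seq(0.08, 0.40, by = 0.02),
                           n_null = 100, seed = NULL) {
  stopifnot(length(sparsities) >= 2, all(diff(sparsities) > 0))
  seeds <- spawn_seeds(seed, length(sparsities))
  rows <- lapply(seq_along(sparsities), function(k) {
    g <- proportional_threshold(W, sparsities[k])
    # a triangle-free graph can yield zero null clustering; the sweep
    # records such points as NA instead of aborting the whole curve
    sw <- tryCatch(normalized_small_world(g, n_null = n_null,
                                          seed = seeds[k]),
                   error = function(e) {
                     if (!grepl("normalization undefined", conditionMessage(e))) {
                       stop(e)
                     }
                     list(cp = clustering_coefficient(g),
                          lp = as.numeric(characteristic_path_length(g)),
                          cp_rand = NA_real_, lp_rand = NA_real_,
                          gamma = NA_real_, lambda = NA_real_,
                          disconnected = TRUE)
                   })
    data.frame(sparsity = sparsities[k], cp = sw$cp, lp = sw$lp,
               cp_rand = sw$cp_rand, lp_rand = sw$lp_rand,
               gamma = sw$gamma, lambda = sw$lambda,
               disconnected = sw$disconnected)
  })
  curves <- do.call(rbind, rows)
  auc <- lapply(curves[c("cp", "lp", "gamma", "lambda")], function(v) {
    if (anyNA(v)) NA_real_ else curve_auc(v, sparsities = curves$sparsity)
  })
  structure(list(curves = curves, auc = auc), class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("small_world_result over %d sparsities [%.2f, %.2f]\n",
              nrow(x$curves), min(x$curves$sparsity), max(x$curves$sparsity)))
  cat(sprintf("  AUC: Cp %.3f | Lp %.3f | gamma %.3f | lambda %.3f\n",
              x$auc$cp, x$auc$lp, x$auc$gamma, x$auc$lambda))
  invisible(x)
}

#' Trapezoidal area under a metric-vs-sparsity curve
#'
#' @param values metric values at each sparsity.
#' @param sparsities strictly increasing sparsity values (>= 2 points).
#' @return Trapezoidal integral over the sparsity range.
#' @export
curve_auc <- function(values, sparsities) {
  if (length(values) != length(sparsities)) stop("length mismatch")
  if (length(values) < 2) stop("AUC needs at least 2 points")
  if (any(diff(sparsities) <= 0)) stop("sparsities must be strictly increasing")
  sum(diff(sparsities) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
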