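#' Behavioural associations of morphological networks
#'
#' Item standardization and domain aggregation, the between-subject
#' network similarity matrix, a variance-component (morphometricity-style)
#' estimate of the behavioural variance explained by network similarity,
#' permutation inference, FDR control, and edgewise correlation
#' localization.
#'
#' @name association
NULL

#' Standardize items and aggregate into domain scores
#'
#' Each item is z-scored across subjects; a domain score is the mean of
#' its standardized member items. Items with zero variance carry no
#' information and are dropped with a warning.
#'
#' @param items numeric matrix (subjects x items) with column names.
#' @param domains named character vector or data frame (`item`, `domain`)
#'   mapping every item to exactly one domain.
#' @return List with `z` (standardized item matrix) and `scores`
#'   (subjects x domains matrix of domain scores).
#' @export
standardize_and_aggregate <- function(items, domains) {
  items <- as.matrix(items)
  if (nrow(items) < 2) stop("need at least 2 subjects")
  if (is.data.frame(domains)) {
    domains <- stats::setNames(as.character(domains$domain),
                               as.character(domains$item))
  }
  if (is.null(colnames(items))) colnames(items) <- names(domains)
  unmapped <- setdiff(colnames(items), names(domains))
  if (length(unmapped) > 0) {
    stop("item(s) without a domain: ", paste(unmapped, collapse = ", "))
  }
  sds <- apply(items, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance item(s): ",
            paste(colnames(items)[sds == 0], collapse = ", "))
    items <- items[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(items)
  dom <- domains[colnames(items)]
  scores <- vapply(unique(dom), function(d) {
    rowMeans(z[, dom == d, drop = FALSE])
  }, numeric(nrow(items)))
  list(z = z, scores = scores)
}

#' Between-subject network similarity matrix
#'
#' Each subject's network block is vectorized into its unique edges, every
#' edge is z-scored across subjects (so high-variance edges do not
#' dominate), and M[i, j] is the Pearson correlation between subjects i
#' and j's standardized edge vectors. The diagonal is set to 1.
#'
#' @param networks list of per-subject `morph_network` objects (one
#'   session), or a subjects x edges matrix.
#' @param block which block to vectorize (default whole GS-GS network).
#' @return Symmetric subjects x subjects matrix with unit diagonal.
#' @export
subject_similarity_matrix <- function(networks, block = "gsgs") {
  if (is.matrix(networks)) {
    E <- networks
  } else {
    E <- do.call(rbind, lapply(networks, function(net) {
      .block_edge_vector(net, block)
    }))
    rownames(E) <- names(networks)
  }
  if (nrow(E) < 3) stop("need at least 3 subjects")
  sds <- apply(E, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d edge(s) with zero cross-subject variance",
                    sum(sds == 0)))
    E <- E[, sds > 0, drop = FALSE]
  }
  M <- stats::cor(t(scale(E)))
  diag(M) <- 1
  dimnames(M) <- list(rownames(E), rownames(E))
  M
}

#' Variance-component estimate of behavioural variance explained
#'
#' Fits, per phenotype column y of `Y`, the model Y = B + E with
#' B ~ N(0, sigma_b^2 M) and E ~ N(0, sigma_e^2 I) by the method of
#' moments: solving
#' \deqn{[tr(M^2) tr(M); tr(M) n] (sigma_b^2, sigma_e^2)' = (y'My, y'y)'}
#' Negative component estimates are clamped to 0. Components are summed
#' over phenotypes into tr(Sigma_B) and tr(Sigma_E), and the variance
#' explained is V = tr(Sigma_B) / (tr(Sigma_B) + tr(Sigma_E)).
#'
#' @param Y numeric matrix (subjects x phenotypes); columns are centered
#'   internally.
#' @param M subject similarity matrix (symmetric, unit diagonal).
#' @return A `variance_estimate`: list with `components` (per-phenotype
#'   sigma_b^2 and sigma_e^2, clamped), `trace_B`, `trace_E`, `trace_P`,
#'   `V` and `n_clamped`.
#' @export
estimate_variance_explained <- function(Y, M) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 10) stop("variance-component estimation needs >= 10 subjects")
  if (!is.matrix(M) || nrow(M) != n || ncol(M) != n) {
    stop("M must be an n x n matrix matching the subjects of Y")
  }
  A <- rbind(c(sum(M * M), sum(diag(M))),
             c(sum(diag(M)), n))
  if (rcond(A) < 1e-10) {
    stop("non-identifiable: M is too close to the identity to separate ",
         "network from environmental variance")
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  MY <- M %*% Yc
  qb <- colSums(Yc * MY)   # y' M y per phenotype
  qt <- colSums(Yc * Yc)   # y' y per phenotype
  raw <- solve(A, rbind(qb, qt))
  clamped <- pmax(raw, 0)
  comps <- data.frame(phenotype = colnames(Y, do.NULL = FALSE, prefix = "P"),
                      sigma_b2 = clamped[1, ], sigma_e2 = clamped[2, ],
                      row.names = NULL)
  tr_b <- sum(comps$sigma_b2)
  tr_e <- sum(comps$sigma_e2)
  structure(list(components = comps,
                 trace_B = tr_b, trace_E = tr_e, trace_P = tr_b + tr_e,
                 V = if (tr_b + tr_e > 0) tr_b / (tr_b + tr_e) else NA_real_,
                 n_clamped = sum(raw < 0)),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("variance_estimate: V = %.3f (tr_B = %.3f, tr_E = %.3f, %d clamped)\n",
              x$V, x$trace_B, x$trace_E, x$n_clamped))
  invisible(x)
}

#' Permutation p value for the variance explained V
#'
#' Subject rows of `Y` are shuffled jointly across phenotypes (breaking
#' the link between behaviour and network similarity while preserving the
#' phenotype correlation structure), V is re-estimated for each shuffle,
#' and the one-sided p value is `(1 + #{V_perm >= V_obs}) / (1 + n_perm)`.
#'
#' @inheritParams estimate_variance_explained
#' @param n_perm number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return List with `V`, `p`, `n_perm` and the fitted `estimate`.
#' @export
permutation_pvalue_V <- function(Y, M, n_perm = 1000, seed = NULL) {
  est <- estimate_variance_explained(Y, M)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  v_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    estimate_variance_explained(Yp, M)$V
  }, 0))
  p <- (1 + sum(v_perm >= est$V)) / (1 + n_perm)
  list(V = est$V, p = p, n_perm = n_perm, estimate = est)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) plus the significance
#' mask at level `q`.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `significant` (logical mask) and `adjusted`
#'   (BH-adjusted p values).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) {
    return(list(significant = logical(0), adjusted = numeric(0)))
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p values must be in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(significant = adj <= q, adjusted = adj)
}

#' Edgewise correlation between network edges and a behavioural score
#'
#' Pearson correlation (two-tailed t-based p) of each edge with the score,
#' BH-FDR across edges, and per-node counts of incident significant edges
#' to summarize where associations concentrate. Constant edges are
#' excluded with a warning.
#'
#' @param edge_matrix numeric matrix (subjects x edges).
#' @param score numeric vector (one value per subject).
#' @param q FDR level.
#' @param edge_nodes optional 2-column matrix giving the endpoint node
#'   indices of each edge (for the per-node counts).
#' @return List with `r`, `p`, `adjusted`, `significant`, and — when
#'   `edge_nodes` is supplied — `node_counts`.
#' @export
edgewise_correlation <- function(edge_matrix, score, q = 0.05,
                                 edge_nodes = NULL) {
  E <- as.matrix(edge_matrix)
  n <- nrow(E)
  if (n < 4) stop("need at least 4 subjects")
  if (length(score) != n) stop("score length must match subject count")
  sds <- apply(E, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d constant edge(s)", sum(!keep)))
  }
  r <- p <- rep(NA_real_, ncol(E))
  rv <- as.vector(stats::cor(E[, keep, drop = FALSE], score))
  r[keep] <- rv
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p[keep] <- 2 * stats::pt(-abs(tv), df = n - 2)
  fdr <- bh_fdr(p[keep], q)
  adjusted <- significant <- rep(NA, ncol(E))
  adjusted[keep] <- fdr$adjusted
  significant[keep] <- fdr$significant
  out <- list(r = r, p = p, adjusted = as.numeric(adjusted),
              significant = as.logical(significant))
  if (!is.null(edge_nodes)) {
    edge_nodes <- as.matrix(edge_nodes)
    if (nrow(edge_nodes) != ncol(E)) stop("edge_nodes must have one row per edge")
    sig <- which(out$significant %in% TRUE)
    out$node_counts <- tabulate(as.vector(edge_nodes[sig, , drop = FALSE]),
                                nbins = max(edge_nodes))
  }
  out
}

#' Endpoint node indices of the unique edges of a block
#'
#' Companion to [block_edges()]: row k gives the two node indices of the
#' k-th vectorized edge (upper-triangle order for square blocks; for the
#' rectangular G-S block, column nodes are offset by the row count).
#'
#' @param n_row,n_col block dimensions.
#' @param square logical; upper-triangle enumeration when `TRUE`.
#' @return Integer matrix with 2 columns.
#' @export
edge_endpoints <- function(n_row, n_col = n_row, square = n_row == n_col) {
  if (square) {
    idx <- which(upper.tri(matrix(0, n_row, n_col)), arr.ind = TRUE)
    unname(idx)
  } else {
    cbind(rep(seq_len(n_row), times = n_col),
          n_row + rep(seq_len(n_col), each = n_row))
  }
}
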