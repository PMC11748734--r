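#' Group comparisons of network summaries
#'
#' Covariate-adjusted two-sample permutation tests (patient vs control),
#' paired sign-flip tests for within-subject subcomponent contrasts, nodal
#' gyral/sulcal contrasts with FDR, and clinical correlations.
#'
#' @name group-comparison
NULL

#' Residualize values on covariates by ordinary least squares
#'
#' Regresses `y` on an intercept plus the covariates and returns the
#' residuals, removing e.g. age and sex effects before permutation
#' testing.
#'
#' @param y numeric vector of per-subject values.
#' @param covariates numeric matrix or data frame (subjects x covariates).
#' @return Residual vector.
#' @export
adjust_covariates <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  fit <- stats::lm.fit(X, y)
  as.vector(fit$residuals)
}

#' Covariate-adjusted two-sample permutation test
#'
#' Residualizes the values on the covariates, takes the mean difference of
#' residuals (first group minus second) as the observed statistic, and
#' builds the null by shuffling group labels. Two-tailed p with the
#' add-one convention.
#'
#' @param values numeric vector of per-subject summaries.
#' @param labels factor or character vector with exactly two levels; the
#'   first level (alphabetically, or the factor's first level) is the
#'   "first" group of the difference.
#' @param covariates optional covariate matrix; `NULL` skips adjustment.
#' @param n_perm number of label shuffles (default 10000).
#' @param seed RNG seed.
#' @return List with `statistic` (mean difference), `p`, `direction`,
#'   `n_perm` and `seed`.
#' @export
permutation_group_test <- function(values, labels, covariates = NULL,
                                   n_perm = 10000, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 subjects")
  r <- if (is.null(covariates)) values - mean(values)
       else adjust_covariates(values, covariates)
  grp1 <- labels == levels(labels)[1]
  n1 <- sum(grp1)
  n <- length(r)
  total <- sum(r)
  stat <- function(mask1) {
    s1 <- sum(r[mask1])
    s1 / n1 - (total - s1) / (n - n1)
  }
  obs <- stat(grp1)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    stat(sample.int(n, n1))
  }, 0))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  list(statistic = obs, p = p,
       direction = if (obs >= 0) paste(levels(labels)[1], ">", levels(labels)[2])
                   else paste(levels(labels)[1], "<", levels(labels)[2]),
       n_perm = n_perm, seed = seed)
}

#' Paired sign-flip permutation test
#'
#' For within-subject contrasts (e.g. each subject's G-G vs S-S mean
#' similarity) the observed statistic is the mean paired difference and
#' the null is built by randomly flipping the sign of each subject's
#' difference. Two-tailed p with the add-one convention.
#'
#' @param values_a,values_b paired per-subject summaries (same length).
#' @param n_perm number of sign-flip draws (default 10000).
#' @param seed RNG seed.
#' @return List with `statistic`, `p`, `n_perm` and `seed`.
#' @export
paired_subcomponent_test <- function(values_a, values_b, n_perm = 10000,
                                     seed = NULL) {
  if (length(values_a) != length(values_b)) stop("paired vectors differ in length")
  d <- values_a - values_b
  n <- length(d)
  obs <- mean(d)
  perm <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    colMeans(signs * d)
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  list(statistic = obs, p = p, n_perm = n_perm, seed = seed)
}

#' Nodal intra-class vs inter-class similarity contrast
#'
#' For each non-ambiguous region: per subject, its mean similarity with
#' the other regions of its own class (excluding self) and with all
#' regions of the other class; the paired difference is tested by
#' sign-flip permutation, and BH-FDR is applied across regions within
#' each class.
#'
#' @param networks list of per-subject `morph_network` objects.
#' @param n_perm sign-flip draws per region.
#' @param seed RNG seed.
#' @param q FDR level within each class.
#' @return Data frame with one row per region: `name`, `region_class`,
#'   `mean_intra`, `mean_inter`, `statistic`, `p`, `adjusted`,
#'   `significant`, `direction`.
#' @export
nodal_class_contrast <- function(networks, n_perm = 10000, seed = NULL,
                                 q = 0.05) {
  if (length(networks) < 5) stop("nodal contrasts need >= 5 subjects")
  nodes <- networks[[1]]$nodes
  cls <- nodes$region_class
  for (want in c("gyral", "sulcal")) {
    if (sum(cls == want) < 2) stop("class with < 2 members: ", want)
  }
  n_nodes <- nrow(nodes)
  n_subj <- length(networks)
  # per subject, per node: intra- and inter-class means
  intra <- inter <- matrix(NA_real_, n_subj, n_nodes)
  for (s in seq_len(n_subj)) {
    W <- networks[[s]]$W
    for (v in seq_len(n_nodes)) {
      same <- which(cls == cls[v])
      same <- setdiff(same, v)
      other <- which(cls != cls[v])
      intra[s, v] <- mean(W[v, same])
      inter[s, v] <- mean(W[v, other])
    }
  }
  seeds <- spawn_seeds(seed, n_nodes)
  res <- lapply(seq_len(n_nodes), function(v) {
    t <- paired_subcomponent_test(intra[, v], inter[, v], n_perm = n_perm,
                                  seed = seeds[v])
    data.frame(name = nodes$name[v], region_class = cls[v],
               mean_intra = mean(intra[, v]), mean_inter = mean(inter[, v]),
               statistic = t$statistic, p = t$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted <- NA_real_
  out$significant <- NA
  for (cl in c("gyral", "sulcal")) {
    i <- out$region_class == cl
    fdr <- bh_fdr(out$p[i], q)
    out$adjusted[i] <- fdr$adjusted
    out$significant[i] <- fdr$significant
  }
  out$direction <- ifelse(out$statistic >= 0, "intra > inter", "intra < inter")
  out
}

#' Correlation of a network measure with a clinical variable
#'
#' Pearson (default) or Spearman correlation with a two-tailed p value,
#' e.g. between a patient's network summary and symptom severity.
#'
#' @param measure,clinical numeric vectors over the same patients (>= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r` and `p`.
#' @export
clinical_correlation <- function(measure, clinical,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(measure) != length(clinical)) stop("length mismatch")
  if (length(measure) < 4) stop("need at least 4 patients")
  if (any(!is.finite(measure)) || any(!is.finite(clinical))) {
    stop("inputs must be finite")
  }
  if (method == "spearman") {
    measure <- rank(measure)
    clinical <- rank(clinical)
  }
  pearson_test(measure, clinical)
}
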