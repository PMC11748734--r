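test_that("item standardization and domain aggregation", {
  withr::with_seed(70, {
    items <- matrix(rnorm(20 * 6, mean = 10, sd = 3), 20, 6,
                    dimnames = list(NULL, paste0("it", 1:6)))
  })
  domains <- setNames(rep(c("cognition", "emotion", "motor"), each = 2),
                      paste0("it", 1:6))
  out <- standardize_and_aggregate(items, domains)
  expect_equal(colMeans(out$z), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(out$z, 2, sd), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colnames(out$scores), c("cognition", "emotion", "motor"))
  # single-item domain equals the item z-score; duplicated item changes nothing
  one <- standardize_and_aggregate(items[, 1, drop = FALSE],
                                   setNames("d", "it1"))
  expect_equal(unname(one$scores[, 1]), unname(scale(items[, 1])[, 1]))
  dup <- standardize_and_aggregate(cbind(items[, 1, drop = FALSE],
                                         it1b = items[, 1]),
                                   setNames(c("d", "d"), c("it1", "it1b")))
  expect_equal(dup$scores[, "d"], one$scores[, "d"])
  # zero-variance item dropped with a warning
  items2 <- cbind(items, itc = 5)
  expect_warning(out2 <- standardize_and_aggregate(
    items2, c(domains, itc = "motor")), "zero-variance")
  expect_equal(ncol(out2$z), 6)
  expect_error(standardize_and_aggregate(items, domains[1:5]),
               "without a domain")
})

test_that("a 60-item, 6-domain battery aggregates to 6 domain scores", {
  withr::with_seed(71, items <- matrix(rnorm(30 * 60), 30, 60,
                                       dimnames = list(NULL, paste0("q", 1:60))))
  domains <- setNames(rep(paste0("dom", 1:6), each = 10), paste0("q", 1:60))
  out <- standardize_and_aggregate(items, domains)
  expect_equal(dim(out$scores), c(30, 6))
})

test_that("subject similarity matrix is a valid correlation kernel", {
  withr::with_seed(72, E <- matrix(rnorm(12 * 40), 12, 40))
  M <- subject_similarity_matrix(E)
  expect_equal(dim(M), c(12, 12))
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 12))
  expect_true(all(abs(M) <= 1 + 1e-12))
  # a duplicated subject correlates perfectly with its twin
  E2 <- rbind(E, E[3, ])
  M2 <- subject_similarity_matrix(E2)
  expect_equal(M2[3, 13], 1, tolerance = 1e-12)
  # independent random networks: off-diagonal similarity stays near zero
  withr::with_seed(73, En <- matrix(rnorm(50 * 500), 50, 500))
  Mn <- subject_similarity_matrix(En)
  expect_lt(mean(abs(Mn[upper.tri(Mn)])), 0.2)
})

test_that("variance components: degeneracy, invariance, and conservation", {
  expect_error(estimate_variance_explained(matrix(rnorm(40), 20, 2), diag(20)),
               "non-identifiable")
  M <- random_corr(60, seed = 5)
  Y <- simulate_behavior(M, 4, 0.5, seed = 6)
  est <- estimate_variance_explained(Y, M)
  # V invariant to common rescaling of all phenotypes
  est10 <- estimate_variance_explained(Y * 10, M)
  expect_equal(est$V, est10$V, tolerance = 1e-12)
  # unclamped fits conserve total variance: tr_B + tr_E = sum y'y / n
  if (est$n_clamped == 0) {
    Yc <- scale(Y, scale = FALSE)
    expect_equal(est$trace_P, sum(Yc^2) / nrow(Y), tolerance = 1e-8)
  }
  expect_true(est$V >= 0 && est$V <= 1)
})

test_that("permutation p for V is seeded and hits the ceiling under strong signal", {
  M <- random_corr(100, seed = 7)
  Y <- simulate_behavior(M, 4, 0.8, seed = 8)
  r1 <- permutation_pvalue_V(Y, M, n_perm = 200, seed = 9)
  r2 <- permutation_pvalue_V(Y, M, n_perm = 200, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$p, 1 / 201)
})

test_that("permutation p for V is calibrated under the null", {
  M <- random_corr(80, seed = 10)
  ps <- vapply(1:20, function(k) {
    Y <- simulate_behavior(M, 3, 0, seed = 100 + k)  # no network effect
    permutation_pvalue_V(Y, M, n_perm = 99, seed = 200 + k)$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("BH-FDR matches the hand-written step-up procedure", {
  r <- bh_fdr(rep(0.001, 6))
  expect_true(all(r$significant))
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(r2$significant, c(TRUE, TRUE, TRUE, FALSE))
  r0 <- bh_fdr(numeric(0))
  expect_length(r0$significant, 0)
  withr::with_seed(74, {
    for (rep in 1:40) {
      m <- sample(1:50, 1)
      p <- runif(m)^sample(1:3, 1)
      got <- bh_fdr(p)
      want <- oracle_bh(p)
      expect_equal(got$significant, want$significant)
      expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    }
  })
})

test_that("edgewise correlation localizes associations and controls the FDR", {
  withr::with_seed(75, {
    score <- rnorm(30)
    E <- cbind(score, matrix(rnorm(30 * 20), 30, 20))
  })
  res <- edgewise_correlation(E, score)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  # brute-force Pearson on toy columns
  withr::with_seed(76, {
    E4 <- matrix(rnorm(4 * 5), 4, 5)
    s4 <- rnorm(4)
  })
  r4 <- edgewise_correlation(E4, s4)
  for (j in 1:5) {
    expect_equal(r4$r[j], oracle_pearson(E4[, j], s4), tolerance = 1e-12)
  }
  # constant edge excluded with warning
  expect_warning(rc <- edgewise_correlation(cbind(E, 1), score), "constant")
  expect_true(is.na(rc$r[ncol(E) + 1]))
  # node attribution counts incident significant edges
  ep <- edge_endpoints(4, square = TRUE)
  Es <- cbind(score, matrix(rnorm(30 * 5), 30, 5))
  rs <- edgewise_correlation(Es, score, edge_nodes = ep)
  expect_length(rs$node_counts, 4)
  expect_equal(sum(rs$node_counts), 2 * sum(rs$significant, na.rm = TRUE))
})

test_that("null edgewise screening keeps the significant fraction near zero", {
  fracs <- vapply(1:10, function(k) {
    withr::with_seed(300 + k, {
      E <- matrix(rnorm(25 * 80), 25, 80)
      s <- rnorm(25)
    })
    r <- edgewise_correlation(E, s)
    mean(r$significant, na.rm = TRUE)
  }, 0)
  expect_lte(mean(fracs), 0.05 + 0.03)
})
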