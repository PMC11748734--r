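test_that("common_grid spans the pooled range with 10% padding", {
  withr::with_seed(1, {
    a <- rnorm(100)
    b <- rnorm(100, 2)
  })
  g <- common_grid(a, b)
  expect_length(g, 256)
  rng <- range(c(a, b))
  pad <- 0.1 * diff(rng)
  expect_equal(g[1], rng[1] - pad)
  expect_equal(g[256], rng[2] + pad)
  expect_true(all(diff(g) > 0))
  # two-point grid is just the padded endpoints
  g2 <- common_grid(a, b, n_points = 2)
  expect_equal(g2, c(rng[1] - pad, rng[2] + pad))
  expect_error(common_grid(rep(1, 50), b), "degenerate")
})

test_that("estimate_density returns a normalized, shape-faithful distribution", {
  withr::with_seed(2, v <- rnorm(500))
  g <- seq(-4, 4, length.out = 256)
  p <- estimate_density(v, g)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  # mirror check: density of a sample symmetrized about 0 is symmetric
  vm <- c(v, -v)
  pm <- estimate_density(vm, g)
  expect_lt(max(abs(pm - rev(pm))), 1e-3)
  # mode of a large standard normal sample lands near 0
  withr::with_seed(3, big <- rnorm(10000))
  pb <- estimate_density(big, seq(-4.5, 4.5, length.out = 256))
  expect_lt(abs(seq(-4.5, 4.5, length.out = 256)[which.max(pb)]), 0.2)
  expect_error(estimate_density(v[1:5], g), "at least 10")
})

test_that("kld matches hand-evaluated discrete cases", {
  P <- c(0.3, 0.7)
  expect_equal(kld(P, P), 0)
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), 1)
  expect_error(kld(c(0.5, 0.5), c(1, 0)), "zero where P")
  expect_error(kld(c(0.5, 0.5), c(1, 0, 0)), "support mismatch")
})

test_that("jsd is symmetric, bounded, and matches brute-force summation", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  # frozen value computed by direct evaluation of the two KLD terms
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.3112781, tolerance = 1e-4)
  withr::with_seed(4, {
    for (rep in 1:50) {
      P <- random_discrete_dist(5)
      Q <- random_discrete_dist(5)
      expect_equal(jsd(P, Q), jsd(Q, P), tolerance = 1e-14)
      expect_equal(jsd(P, Q), oracle_jsd(P, Q), tolerance = 1e-12)
      expect_gte(jsd(P, Q), 0)
      expect_lte(jsd(P, Q), 1)
    }
  })
})

test_that("similarity transform maps divergence to [0, 1]", {
  expect_equal(similarity_from_jsd(0), 1)
  expect_equal(similarity_from_jsd(1), 0)
  expect_equal(similarity_from_jsd(0.25), 0.5)
  expect_error(similarity_from_jsd(1.2), "logarithm base")
})

test_that("build_network produces a valid canonical similarity matrix", {
  atlas <- small_atlas(3, 3, 1)  # bilateral: 6 gyral + 6 sulcal retained
  cohort <- quick_cohort(n_subjects = 1, atlas = atlas, seed = 21)
  net <- build_network(cohort$features[[1]][[1]], atlas)
  W <- net$W
  expect_equal(dim(W), c(12, 12))
  expect_equal(W, t(W))
  expect_equal(diag(W), setNames(rep(1, 12), rownames(W)))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(net$nodes$region_class, rep(c("gyral", "sulcal"), each = 6))

  # invariant to the order the atlas lists its rows
  shuffled <- withr::with_seed(99, atlas[sample(nrow(atlas)), ])
  net2 <- build_network(cohort$features[[1]][[1]], shuffled)
  expect_equal(net2$W, W)
})

test_that("build_network limits: identical, overlapping, and disjoint regions", {
  atlas <- make_default_atlas(1, 1, 0)  # L_G, L_S, R_G, R_S
  withr::with_seed(5, {
    v <- rnorm(200, 0, 0.5)
    fm <- cbind(v, v, rnorm(200, 50, 0.5), rnorm(200, 0.1, 0.5))
  })
  colnames(fm) <- atlas$name  # L_G and L_S share the identical sample
  net <- build_network(fm, atlas)
  # identical samples: similarity 1 up to grid effects
  expect_gte(net$W["L_G_01", "L_S_01"], 0.99)
  # disjoint ranges far beyond the bandwidth: similarity near 0
  expect_lt(net$W["L_G_01", "R_G_01"], 0.05)
  # degenerate region is named in the error
  fm2 <- fm
  fm2[, "R_S_01"] <- 1
  expect_error(build_network(fm2, atlas), "R_S_01", fixed = TRUE)
})

test_that("binned and reference engines agree", {
  atlas <- small_atlas(3, 3, 0)
  cohort <- quick_cohort(n_subjects = 1, atlas = atlas, seed = 8)
  fm <- cohort$features[[1]][[1]]
  w_fast <- build_network(fm, atlas)$W
  w_ref <- build_network(fm, atlas, engine = "reference")$W
  expect_lt(max(abs(w_fast - w_ref)), 1e-3)
})

test_that("subcomponent views carry the parent's entries at the right shapes", {
  atlas <- small_atlas(4, 5, 0)
  cohort <- quick_cohort(n_subjects = 1, atlas = atlas, seed = 13)
  net <- build_network(cohort$features[[1]][[1]], atlas)
  sub <- extract_subcomponents(net)
  expect_equal(dim(sub$gg), c(8, 8))
  expect_equal(dim(sub$ss), c(10, 10))
  expect_equal(dim(sub$gs), c(8, 10))
  expect_equal(sub$gg, net$W[1:8, 1:8])
  expect_equal(sub$gs, net$W[1:8, 9:18])
  expect_equal(sub$ss, t(sub$ss))
  expect_equal(unname(diag(sub$ss)), rep(1, 10))
  # toy 2G + 2S network
  toy <- extract_subcomponents(diag(4), classes = rep(c("gyral", "sulcal"), each = 2))
  expect_equal(dim(toy$gg), c(2, 2))
  expect_equal(dim(toy$gs), c(2, 2))
})

test_that("mean_similarity averages unique edges only", {
  sq <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(mean_similarity(sq), 0.8)
  m3 <- matrix(0, 3, 3)
  m3[upper.tri(m3)] <- c(0.2, 0.4, 0.6)
  m3 <- m3 + t(m3)
  diag(m3) <- 1
  expect_equal(mean_similarity(m3), 0.4)
  rect <- matrix(0.5, 3, 4)
  expect_equal(mean_similarity(rect, square = FALSE), 0.5)
  expect_error(mean_similarity(matrix(numeric(0), 0, 0)), "empty")
})
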