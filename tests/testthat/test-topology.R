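test_that("edge-count arithmetic and estimability limits", {
  expect_equal(max_edges(58), 1653)
  expect_equal(max_edges(62), 1891)
  expect_equal(max_edges(2), 1)
  expect_equal(min_estimable_sparsity(58), 0.071)
  expect_equal(min_estimable_sparsity(62), 0.068)
  expect_equal(min_estimable_sparsity(10), 0.256)
})

test_that("proportional thresholding keeps exactly the strongest edges", {
  # 4-node weighted matrix with 6 distinct weights; s = 1/3 keeps the top 2
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.1, 0.5, 0.8, 0.3, 0.6)
  W <- W + t(W)
  g <- proportional_threshold(W, 1 / 3)
  expect_equal(g$n_edges, 2)
  # brute force over the column-major upper triangle: the two largest
  # weights are 0.9 on edge (1,2) and 0.8 on edge (1,4)
  expected <- matrix(0L, 4, 4)
  expected[1, 2] <- expected[2, 1] <- 1L
  expected[1, 4] <- expected[4, 1] <- 1L
  expect_equal(g$adj, expected)
  # s = 1 gives the complete graph
  full <- proportional_threshold(W, 1)
  expect_equal(sum(full$adj) / 2, 6)
  expect_error(proportional_threshold(W, 0.01), "zero edges")
})

test_that("thresholding is deterministic under ties and nested across sparsities", {
  withr::with_seed(10, {
    W <- matrix(0, 12, 12)
    # coarse weights force many ties
    W[upper.tri(W)] <- sample(seq(0, 1, by = 0.2), 66, replace = TRUE)
    W <- W + t(W)
  })
  g1 <- proportional_threshold(W, 0.3)
  g2 <- proportional_threshold(W, 0.3)
  expect_identical(g1$adj, g2$adj)
  # nested edge sets as sparsity grows
  prev <- proportional_threshold(W, 0.1)$adj
  for (s in seq(0.2, 1, by = 0.1)) {
    cur <- proportional_threshold(W, s)$adj
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("clustering coefficient matches hand-computed graphs", {
  k4 <- as_binary_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(clustering_coefficient(k4), 1)
  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  expect_equal(clustering_coefficient(as_binary_graph(star)), 0)
  # 5-node graph, edges {12, 13, 23, 34, 45}: nodal values 1, 1, 1/3, 0, 0
  adj <- matrix(0L, 5, 5)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
  }
  expect_equal(clustering_coefficient(as_binary_graph(adj)), 7 / 15,
               tolerance = 1e-4)
})

test_that("characteristic path length handles paths and disconnection", {
  k4 <- as_binary_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)
  # path 1-2-3-4: distances 1,2,3,1,2,1 -> mean 10/6
  p4 <- matrix(0L, 4, 4)
  p4[cbind(1:3, 2:4)] <- 1L
  p4 <- p4 + t(p4)
  lp <- characteristic_path_length(as_binary_graph(p4))
  expect_equal(as.numeric(lp), 10 / 6)
  expect_false(attr(lp, "disconnected"))
  # two disjoint dyads: reachable pairs only, flagged
  two_k2 <- matrix(0L, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1L
  lp2 <- characteristic_path_length(as_binary_graph(two_k2))
  expect_equal(as.numeric(lp2), 1)
  expect_true(attr(lp2, "disconnected"))
  empty <- matrix(0L, 3, 3)
  expect_error(characteristic_path_length(as_binary_graph(empty)), "edgeless")
})

test_that("Cp and Lp agree with brute force on random graphs up to N = 8", {
  withr::with_seed(20, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      adj <- random_graph_adj(n, p = runif(1, 0.25, 0.8))
      g <- as_binary_graph(adj)
      expect_equal(clustering_coefficient(g), oracle_clustering(adj),
                   tolerance = 1e-12)
      if (g$n_edges > 0) {
        o <- oracle_path_length(adj)
        lp <- characteristic_path_length(g)
        expect_equal(as.numeric(lp), o$lp, tolerance = 1e-12)
        expect_equal(attr(lp, "disconnected"), o$disconnected)
      }
    }
  })
})

test_that("rewiring preserves the degree sequence exactly and is seeded", {
  withr::with_seed(30, adj <- random_graph_adj(20, 0.3))
  g <- as_binary_graph(adj)
  r1 <- rewire_preserving_degree(g, n_swaps = 200, seed = 4)
  r2 <- rewire_preserving_degree(g, n_swaps = 200, seed = 4)
  expect_identical(r1$adj, r2$adj)
  expect_equal(sort(rowSums(r1$adj)), sort(rowSums(adj)))
  expect_false(identical(r1$adj, adj))
  # complete graph admits no swap and is returned unchanged
  k4 <- as_binary_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(rewire_preserving_degree(k4, 50, seed = 1)$adj, k4$adj)
  # property: degree sequences preserved across random graphs
  withr::with_seed(31, {
    for (rep in 1:10) {
      a <- random_graph_adj(sample(8:15, 1), runif(1, 0.2, 0.6))
      gg <- as_binary_graph(a)
      if (gg$n_edges < 2) next
      rw <- rewire_preserving_degree(gg, 10 * gg$n_edges, seed = rep)
      expect_identical(rowSums(rw$adj), rowSums(a))
    }
  })
})

test_that("normalization behaves on lattice and random references", {
  # ring lattice N=60, k=6: clustering far above degree-matched random
  n <- 60
  lat <- matrix(0L, n, n)
  for (d in 1:3) {
    for (i in 1:n) {
      j <- ((i + d - 1) %% n) + 1
      lat[i, j] <- lat[j, i] <- 1L
    }
  }
  sw <- normalized_small_world(as_binary_graph(lat), n_null = 30, seed = 2)
  expect_gt(sw$gamma, 1)
  # dense random graph: rewired nulls are statistically the same graph
  withr::with_seed(33, {
    gl <- vapply(1:5, function(k) {
      adj <- random_graph_adj(40, 0.5)
      s <- normalized_small_world(as_binary_graph(adj), n_null = 30, seed = k)
      c(s$gamma, s$lambda)
    }, numeric(2))
  })
  expect_lt(max(abs(gl[1, ] - 1)), 0.15)
  expect_lt(max(abs(gl[2, ] - 1)), 0.15)
})

test_that("sparsity sweep evaluates the default range with finite curves", {
  withr::with_seed(40, {
    W <- matrix(0, 30, 30)
    W[upper.tri(W)] <- runif(435)
    W <- W + t(W)
    diag(W) <- 1
  })
  res <- sparsity_sweep(W, n_null = 10, seed = 3)
  expect_s3_class(res, "small_world_result")
  expect_equal(nrow(res$curves), 17)
  expect_equal(res$curves$sparsity, seq(0.08, 0.40, by = 0.02))
  expect_true(all(is.finite(res$curves$cp)))
  expect_true(all(is.finite(res$curves$lp)))
  expect_true(all(res$curves$gamma > 0))
  expect_true(all(res$curves$lambda > 0))
  # Lp is non-increasing where the graphs are connected (nested edge sets)
  conn <- !res$curves$disconnected
  lp_conn <- res$curves$lp[conn]
  expect_true(all(diff(lp_conn) <= 1e-12))
})

test_that("trapezoidal AUC matches closed forms and an independent summation", {
  s <- seq(0.08, 0.40, by = 0.02)
  expect_equal(curve_auc(rep(1, 17), s), 0.32)
  expect_equal(curve_auc(c(0, 1), c(0, 1)), 0.5)
  withr::with_seed(50, {
    v <- runif(5)
    x <- sort(runif(5))
  })
  manual <- 0
  for (i in 1:4) manual <- manual + (x[i + 1] - x[i]) * (v[i] + v[i + 1]) / 2
  expect_equal(curve_auc(v, x), manual, tolerance = 1e-14)
  expect_error(curve_auc(1, 0.1), "at least 2")
})
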