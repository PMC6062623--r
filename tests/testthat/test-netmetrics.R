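# Graph construction and metrics: thresholding, geodesic substrate,
# canonical closed forms, oracle equivalence on random graphs, and metric
# invariants.

test_that("proportional thresholding keeps the strongest edges", {
  z <- matrix(0, 4, 4)
  z[1, 2] <- 0.9; z[1, 3] <- 0.1; z[1, 4] <- 0.5
  z[2, 3] <- 0.2; z[2, 4] <- 0.4; z[3, 4] <- 0.3
  z <- z + t(z)
  g <- threshold_proportional(z, 0.5)
  expect_equal(n_edges(g), 3)
  expect_equal(g$adj[1, 2], 1L)
  expect_equal(g$adj[1, 4], 1L)
  expect_equal(g$adj[2, 4], 1L)
  expect_equal(sum(g$adj), 6L)
  # k = 1 retains everything
  expect_equal(n_edges(threshold_proportional(z, 1)), 6)
  # zero-edge density errors
  expect_error(threshold_proportional(z, 1e-6), "zero edges")
  # abs mode ranks magnitudes
  z2 <- z; z2[1, 2] <- z2[2, 1] <- -0.95
  g_abs <- threshold_proportional(z2, 1 / 6, mode = "abs")
  expect_equal(g_abs$adj[1, 2], 1L)
})

test_that("thresholding is equivariant under node permutation", {
  withr::with_seed(31, {
    z <- matrix(rnorm(64), 8, 8); z <- (z + t(z)) / 2; diag(z) <- 0
  })
  perm <- sample(8)
  g1 <- threshold_proportional(z, 0.3)
  g2 <- threshold_proportional(z[perm, perm], 0.3)
  expect_equal(g2$adj, g1$adj[perm, perm], ignore_attr = TRUE)
})

test_that("edge count matches round(k * N(N-1)/2) across the grid", {
  withr::with_seed(32, {
    z <- matrix(rnorm(60^2), 60); z <- (z + t(z)) / 2; diag(z) <- 0
  })
  for (k in c(0.10, 0.15, 0.20, 0.25))
    expect_equal(n_edges(threshold_proportional(z, k)),
                 round(k * 60 * 59 / 2))
})

test_that("geodesic distances and path counts are exact on known graphs", {
  ps <- shortest_paths(graph_path3())
  expect_equal(ps$dist[1, 3], 2)
  expect_equal(ps$sigma[1, 3], 1)
  ps4 <- shortest_paths(graph_cycle(4))
  expect_equal(ps4$dist[1, 3], 2)
  expect_equal(ps4$sigma[1, 3], 2)   # two equal geodesics around the cycle
  # disconnected pair
  a <- matrix(0L, 4, 4); a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1L
  psd <- shortest_paths(bin_graph(a))
  expect_true(is.infinite(psd$dist[1, 3]))
  expect_equal(psd$sigma[1, 3], 0)
})

test_that("path statistics match brute-force enumeration on random graphs", {
  withr::with_seed(33, {
    for (rep in 1:25) {
      a <- rand_graph(8, runif(1, 0.2, 0.8))
      g <- bin_graph(a)
      ps <- shortest_paths(g)
      d_or <- oracle_dist(a)
      expect_equal(ps$dist, d_or, ignore_attr = TRUE)
      for (s in 1:8) for (t in 1:8) {
        if (s == t) next
        expect_equal(ps$sigma[s, t],
                     if (is.finite(d_or[s, t])) oracle_sigma(a, s, t) else 0)
      }
    }
  })
})

test_that("canonical closed forms hold exactly", {
  star <- graph_star(6)
  expect_identical(betweenness(star, 1), 1)
  expect_identical(flow_coefficient(star, 1), 1)
  expect_identical(local_efficiency(star, 1), 0)
  k4 <- graph_complete(4)
  expect_identical(betweenness(k4, 2), 0)
  expect_identical(flow_coefficient(k4, 2), 0)
  expect_identical(local_efficiency(k4, 2), 1)
  expect_identical(global_efficiency(k4), 1)
  expect_equal(global_efficiency(graph_path3()), 5 / 6)
  # degree-4 node with 2 edges into each of two modules
  a <- matrix(0L, 5, 5); a[1, 2:5] <- 1L; a[2:5, 1] <- 1L
  g <- bin_graph(a)
  expect_equal(participation(g, c(1, 1, 1, 2, 2), 1), 0.5)
  # all edges inside own module -> 0
  expect_equal(participation(graph_two_triangles(), rep(1:2, each = 3), 2), 0)
  # degenerate conventions: isolated and leaf nodes
  iso <- bin_graph(rbind(c(0L, 1L, 0L), c(1L, 0L, 0L), c(0L, 0L, 0L)))
  expect_identical(flow_coefficient(iso, 3), 0)
  expect_identical(local_efficiency(iso, 3), 0)
  expect_identical(participation(iso, c(1, 1, 2), 3), 0)
  expect_identical(local_efficiency(iso, 1), 0)   # degree 1
})

test_that("node metrics equal their brute-force oracles on random graphs", {
  withr::with_seed(34, {
    for (rep in 1:20) {
      n <- sample(5:9, 1)
      a <- rand_graph(n, runif(1, 0.2, 0.8))
      g <- bin_graph(a)
      part <- sample(1:3, n, replace = TRUE)
      ps <- shortest_paths(g)
      for (i in seq_len(n)) {
        expect_equal(betweenness(g, i, ps), oracle_betweenness(a, i),
                     tolerance = 1e-12)
        expect_equal(flow_coefficient(g, i), oracle_flow(a, i),
                     tolerance = 1e-12)
        expect_equal(participation(g, part, i),
                     oracle_participation(a, part, i), tolerance = 1e-12)
        expect_equal(local_efficiency(g, i), oracle_local_eff(a, i),
                     tolerance = 1e-12)
      }
      expect_equal(global_efficiency(g, ps), oracle_global_eff(a),
                   tolerance = 1e-12)
      expect_equal(compute_q(g, part), oracle_q(a, part), tolerance = 1e-12)
    }
  })
})

test_that("metrics agree with igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  withr::with_seed(35, {
    for (rep in 1:10) {
      n <- 12
      a <- rand_graph(n, 0.4)
      g <- bin_graph(a)
      ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      ps <- shortest_paths(g)
      d_ig <- igraph::distances(ig)
      expect_equal(ps$dist, d_ig, ignore_attr = TRUE)
      # igraph betweenness counts unordered pairs, unnormalised
      b_ig <- igraph::betweenness(ig, directed = FALSE)
      for (i in seq_len(n))
        expect_equal(betweenness(g, i, ps),
                     2 * b_ig[[i]] / ((n - 1) * (n - 2)), tolerance = 1e-10)
    }
  })
})

test_that("adding an edge never decreases global efficiency", {
  withr::with_seed(36, {
    for (rep in 1:10) {
      a <- rand_graph(9, 0.3)
      e0 <- global_efficiency(bin_graph(a))
      missing_idx <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
      if (!nrow(missing_idx)) next
      pick <- missing_idx[sample(nrow(missing_idx), 1), ]
      a[pick[1], pick[2]] <- a[pick[2], pick[1]] <- 1L
      expect_gte(global_efficiency(bin_graph(a)), e0 - 1e-14)
    }
  })
})

test_that("metrics are invariant under node relabeling", {
  withr::with_seed(37, {
    a <- rand_graph(10, 0.4)
    perm <- sample(10)
  })
  g <- bin_graph(a)
  gp <- bin_graph(a[perm, perm])
  part <- rep(1:2, 5)
  for (i in 1:10) {
    expect_equal(betweenness(gp, which(perm == i)), betweenness(g, i))
    expect_equal(flow_coefficient(gp, which(perm == i)), flow_coefficient(g, i))
    expect_equal(local_efficiency(gp, which(perm == i)), local_efficiency(g, i))
    expect_equal(participation(gp, part[perm], which(perm == i)),
                 participation(g, part, i))
  }
  expect_equal(global_efficiency(gp), global_efficiency(g))
  expect_equal(global_flow(gp), global_flow(g))
})

test_that("metric ranges stay in their stated intervals", {
  withr::with_seed(38, {
    for (rep in 1:10) {
      a <- rand_graph(10, runif(1, 0.1, 0.9))
      if (sum(a) == 0) next
      g <- bin_graph(a)
      mr <- modularity_spectral(g)
      mb <- metric_bundle(g, target_nodes = g$node_labels)
      expect_true(mr$q >= -1 && mr$q <= 1)
      expect_true(mb$global["global_efficiency"] >= 0 &&
                    mb$global["global_efficiency"] <= 1)
      expect_true(mb$global["global_flow"] >= 0 &&
                    mb$global["global_flow"] <= 1)
      expect_true(all(mb$nodes$betweenness >= 0 & mb$nodes$betweenness <= 1))
      expect_true(all(mb$nodes$flow >= 0 & mb$nodes$flow <= 1))
      expect_true(all(mb$nodes$participation >= 0 & mb$nodes$participation < 1))
      expect_true(all(mb$nodes$local_efficiency >= 0 &
                        mb$nodes$local_efficiency <= 1))
    }
  })
})

test_that("metric_bundle composes the pieces consistently", {
  k6 <- graph_complete(6)
  mb <- metric_bundle(k6, target_nodes = character())
  expect_equal(unname(mb$global["q"]), 0)
  expect_equal(unname(mb$global["global_efficiency"]), 1)
  expect_equal(unname(mb$global["global_flow"]), 0)
  expect_null(mb$nodes)
  tt <- graph_two_triangles()
  mbt <- metric_bundle(tt, target_nodes = tt$node_labels[1])
  expect_equal(unname(mbt$global["q"]), 0.5)
  # each component is a K3: within-component efficiency 1, cross pairs 0;
  # 12 of 30 ordered pairs connected
  expect_equal(unname(mbt$global["global_efficiency"]), 12 / 30)
  expect_equal(mbt$nodes$local_efficiency, 1)
  expect_error(betweenness(graph_path3(), 1, shortest_paths(graph_path3())),
               NA)
  expect_error(betweenness(bin_graph(matrix(0L, 2, 2) + rbind(c(0L, 1L),
                                                              c(1L, 0L))), 1),
               "at least 3")
})
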