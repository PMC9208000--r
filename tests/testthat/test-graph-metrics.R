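# Weighted graph measures against hand values and brute-force oracles.

star5 <- function() {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 1; W[2:5, 1] <- 1
  W
}

test_that("degree counts nonzero edges", {
  expect_identical(node_degree(star5()), c(4L, 1L, 1L, 1L, 1L))
  expect_identical(node_degree(matrix(0, 4, 4)), rep(0L, 4))
  W <- random_weight_matrix(10, seed = 3)
  brute <- vapply(1:10, function(i) sum(W[i, ] > 0), integer(1))
  expect_identical(node_degree(W), brute)
})

test_that("weighted clustering matches hand evaluation and binary reduction", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(node_clustering(tri), rep(1, 3))
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(node_clustering(path3)[2L], 0)
  # triangle with weights (1, 1, 0.125): geometric mean (1*1*0.125)^(1/3) = 0.5
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[1, 3] <- W[3, 1] <- 1
  W[2, 3] <- W[3, 2] <- 0.125
  expect_equal(node_clustering(W)[1L], 0.5)
  # binary graphs: reduces to triangle fraction
  W <- (random_weight_matrix(8, seed = 4) > 0) * 1
  k <- node_degree(W)
  brute <- vapply(1:8, function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    tri_count <- 0
    for (a in nb) for (b in nb) if (a != b && W[a, b] > 0)
      tri_count <- tri_count + 1
    tri_count / (k[i] * (k[i] - 1))
  }, numeric(1))
  expect_equal(node_clustering(W), brute, tolerance = 1e-12)
})

test_that("efficiency uses inverse-weight shortest paths", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  eff <- node_efficiency(full)
  expect_equal(eff$nodal, rep(1, 4))
  expect_equal(eff$global, 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(node_efficiency(path3)$nodal[1L], 0.75)
  # isolated node has zero efficiency
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(node_efficiency(W)$nodal[3L], 0)
})

test_that("leverage centrality matches the neighbor-contrast formula", {
  expect_equal(leverage_centrality(star5()), c(0.6, rep(-0.6, 4)))
  cycle <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    cycle[i, j] <- cycle[j, i] <- 1
  }
  expect_equal(leverage_centrality(cycle), rep(0, 6))
  W <- random_weight_matrix(10, seed = 5)
  k <- node_degree(W)
  brute <- vapply(1:10, function(i) {
    if (k[i] == 0) return(0)
    nb <- which(W[i, ] > 0)
    mean((k[i] - k[nb]) / (k[i] + k[nb]))
  }, numeric(1))
  expect_equal(leverage_centrality(W), brute, tolerance = 1e-14)
  expect_equal(leverage_centrality(matrix(0, 3, 3)), rep(0, 3))
})

test_that("modularity matches hand evaluation and is seed-deterministic", {
  tri2 <- matrix(0, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1
  tri2 <- tri2 + t(tri2)
  expect_equal(modularity_from_partition(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_from_partition(tri2, rep(1, 6)), 0)
  m1 <- modularity_weighted(tri2, seed = 7)
  m2 <- modularity_weighted(tri2, seed = 7)
  expect_identical(m1, m2)
  expect_equal(m1$Q, 0.5)
  # returned Q always equals a from-scratch recomputation for the partition
  W <- random_weight_matrix(12, seed = 6)
  m <- modularity_weighted(W, seed = 2)
  expect_equal(m$Q, modularity_from_partition(W, m$membership),
               tolerance = 1e-12)
  expect_error(modularity_weighted(matrix(0, 3, 3)), "zero total weight")
})

test_that("metrics are invariant to node relabeling", {
  W <- random_weight_matrix(9, seed = 8)
  perm <- withr::with_seed(9, sample(9))
  Wp <- W[perm, perm]
  expect_equal(node_degree(Wp), node_degree(W)[perm])
  expect_equal(node_clustering(Wp), node_clustering(W)[perm],
               tolerance = 1e-12)
  expect_equal(node_efficiency(Wp)$nodal, node_efficiency(W)$nodal[perm],
               tolerance = 1e-12)
  expect_equal(leverage_centrality(Wp), leverage_centrality(W)[perm],
               tolerance = 1e-12)
  expect_equal(node_efficiency(Wp)$global, node_efficiency(W)$global,
               tolerance = 1e-12)
})

test_that("dyad covariates combine node metrics and coordinates", {
  gt <- tiny_ground_truth()
  d <- tiny_design()
  P <- gt$P; W <- gt$W; N <- gt$N
  expect_equal(nrow(d), N * W * dyad_count(P))
  # hand checks on a direct construction
  nets <- structure(list(participant_id = "p1",
                         windows = list(random_weight_matrix(4, seed = 2)),
                         window_starts = 1L,
                         node_labels = c("a", "b", "c", "d")),
                    class = "dyn_nets")
  metrics <- node_metric_table(nets, seed = 1)
  coords <- data.frame(node = c("a", "b", "c", "d"),
                       x = c(0, 3, 0, 1), y = c(0, 4, 0, 1),
                       z = c(0, 0, 2, 1))
  dc <- dyad_covariates(metrics, coords)
  expect_equal(nrow(dc), dyad_count(4))
  ab <- dc[dc$node_j == "a" & dc$node_k == "b", ]
  expect_equal(ab$dist, 5)
  expect_equal(ab$dist2, 25)
  nm <- metrics$nodes
  expect_equal(ab$C_avg, (nm$C[nm$node == "a"] + nm$C[nm$node == "b"]) / 2)
  expect_equal(ab$k_diff, abs(nm$k[nm$node == "a"] - nm$k[nm$node == "b"]))
  expect_true(all(dc$Q == dc$Q[1L]))  # window-level constant
  expect_error(dyad_covariates(metrics, coords[-1L, ]), "a")
})

test_that("dyad count is P(P-1)/2", {
  expect_identical(dyad_count(268), 35778L)
  expect_identical(dyad_count(3), 3L)
})
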