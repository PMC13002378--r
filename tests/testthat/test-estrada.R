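two_clique_bridge <- function(k = 10) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- 1; A[(k + 1):n, (k + 1):n] <- 1
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- 1
  A
}

core_periphery <- function(core = 6, leaves_per = 2) {
  n <- core * (1 + leaves_per)
  A <- matrix(0, n, n)
  A[1:core, 1:core] <- 1; diag(A) <- 0
  leaf <- core + 1
  for (c_ in 1:core) for (k in 1:leaves_per) {
    A[c_, leaf] <- A[leaf, c_] <- 1
    leaf <- leaf + 1
  }
  A
}

test_that("Estrada index matches closed-form spectra", {
  expect_equal(estrada_index(matrix(0, 7, 7)), 7, tolerance = 1e-9)
  K2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(estrada_index(K2), exp(1) + exp(-1), tolerance = 1e-9)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(estrada_index(K5), exp(4) + 4 * exp(-1), tolerance = 1e-9)
  star <- graph_fixtures()$star
  expect_equal(estrada_index(star), exp(2) + 3 + exp(-2), tolerance = 1e-9)
  expect_error(estrada_index(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("subgraph centralities satisfy the spectral identity", {
  set.seed(400)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    A <- random_adjacency(n, runif(1, 0.1, 0.5))
    expect_equal(sum(subgraph_centrality(A, "full")), estrada_index(A),
                 tolerance = 1e-9)
    # odd + even parts recompose the full centrality
    expect_equal(subgraph_centrality(A, "odd") + subgraph_centrality(A, "even"),
                 subgraph_centrality(A, "full"), tolerance = 1e-9)
  }
})

test_that("odd-subgraph centrality vanishes exactly where odd walks are absent", {
  K2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(odd_subgraph_centrality(K2), c(0, 0), tolerance = 1e-12)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(odd_subgraph_centrality(tri),
               rep(sinh(2) / 3 + (2 / 3) * sinh(-1), 3), tolerance = 1e-12)
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1  # node 3 isolated
  expect_equal(odd_subgraph_centrality(iso)[3], 0, tolerance = 1e-12)
})

test_that("Estrada index strictly increases when an edge is added", {
  set.seed(401)
  for (rep in 1:10) {
    A <- random_adjacency(12, 0.3)
    miss <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (!nrow(miss)) next
    e <- miss[sample(nrow(miss), 1), , drop = FALSE]
    A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1
    expect_gt(estrada_index(A2), estrada_index(A))
  }
})

test_that("homogeneous random graphs classify predominantly as class I", {
  set.seed(402)
  frac <- replicate(25, {
    A <- random_adjacency(50, 0.3)
    cl <- classify_nodes(A)
    mean(cl$nodes$node_class == "I")
  })
  expect_gte(mean(frac), 0.7)
})

test_that("structural holes produce class II and cores produce class III nodes", {
  cl2 <- classify_nodes(two_clique_bridge())
  expect_gt(sum(cl2$nodes$node_class == "II"), 0)

  cl3 <- classify_nodes(core_periphery())
  expect_gt(sum(cl3$nodes$node_class == "III"), 0)
})

test_that("regular connected non-bipartite graphs are entirely class I", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_true(all(classify_nodes(K5)$nodes$node_class == "I"))
  C5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; C5[i, j] <- C5[j, i] <- 1 }
  expect_true(all(classify_nodes(C5)$nodes$node_class == "I"))
})

test_that("bipartite graphs are reported unclassifiable", {
  K2 <- matrix(c(0, 1, 1, 0), 2)
  expect_error(classify_nodes(K2), "no classifiable node")
})

test_that("classification is invariant to node relabeling", {
  set.seed(403)
  A <- two_clique_bridge(6)
  perm <- sample(nrow(A))
  cl <- classify_nodes(A)
  clp <- classify_nodes(A[perm, perm])
  expect_equal(clp$nodes$node_class, cl$nodes$node_class[perm])
  expect_equal(clp$tau, cl$tau, tolerance = 1e-9)
})

test_that("weighted matrices in [0, 1] are classified like their scaled versions", {
  set.seed(404)
  W <- random_adjacency(30, 0.25) * matrix(runif(900, 0.2, 0.9), 30)
  W <- (W + t(W)) / 2; diag(W) <- 0
  cl <- classify_nodes(W)
  expect_true(all(cl$nodes$node_class %in% c("I", "II", "III", "unclassified")))
  expect_equal(sum(exp(cl$eigenvalues)), cl$estrada_index, tolerance = 1e-9)
})

test_that("network classes follow the percentage rule", {
  expect_equal(classify_network(rep("I", 20))$network_class, "I")
  cls3 <- c(rep("I", 14), rep("III", 6))
  r3 <- classify_network(cls3)
  expect_equal(r3$network_class, "III")
  expect_equal(r3$ratio_II_III, 0)
  cls4 <- c(rep("I", 11), rep("II", 4), rep("III", 5))
  r4 <- classify_network(cls4)
  expect_equal(r4$network_class, "IV")
  expect_equal(r4$ratio_II_III, 0.8)
  expect_equal(sum(r4$percentages), 100)
  expect_error(classify_network(rep("unclassified", 3)), "zero classified")
})
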