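test_that("hand-computed star, path, cycle and clique values are reproduced", {
  fx <- graph_fixtures()

  G <- as_mea_graph(fx$star)           # K_{1,4}, center first
  nm <- node_metrics(G)
  expect_equal(nm$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nm$closeness, c(1 / 4, rep(1 / 7, 4)))
  expect_equal(nm$eigenvector[1] / nm$eigenvector[2], 2, tolerance = 1e-6)
  expect_equal(nm$degree, c(4, 1, 1, 1, 1))

  net <- network_metrics(as_mea_graph(fx$p4))
  expect_equal(net$avg_degree, 1.5)
  expect_equal(net$density, 0.5)
  expect_equal(net$components, 1)
  expect_equal(net$char_path_length, 10 / 6)

  netc <- network_metrics(as_mea_graph(fx$c4))
  expect_equal(netc$char_path_length, 4 / 3)
  expect_equal(netc$avg_clustering, 0)

  nmt <- node_metrics(as_mea_graph(fx$tri_pend))  # triangle a-b-c + pendant d on c
  expect_equal(nmt$clustering, c(1, 1, 1 / 3, 0))
  expect_equal(nmt$eccentricity[4], 2)

  nm4 <- node_metrics(as_mea_graph(fx$k4))
  expect_true(all(nm4$degree == 3))
  expect_true(all(nm4$clustering == 1))
  expect_true(all(nm4$betweenness == 0))
  expect_true(all(nm4$eccentricity == 1))
})

test_that("degenerate graphs yield defined values", {
  empty5 <- as_mea_graph(matrix(0, 5, 5))
  net <- network_metrics(empty5)
  expect_equal(net$avg_degree, 0)
  expect_equal(net$density, 0)
  expect_equal(net$components, 5)
  expect_true(is.na(net$char_path_length))
  expect_equal(net$avg_clustering, 0)

  none <- node_metrics(as_mea_graph(matrix(0, 0, 0)))
  expect_equal(nrow(none), 0)
})

test_that("all metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(200)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.6))
    G <- as_mea_graph(A)
    nm <- node_metrics(G)
    net <- network_metrics(G)

    expect_equal(nm$degree, rowSums(A))
    expect_equal(nm$clustering, oracle_clustering(A), tolerance = 1e-12)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-9)
    expect_equal(nm$closeness, oracle_closeness(A), tolerance = 1e-12)
    expect_equal(nm$eccentricity, oracle_eccentricity(A))
    # the leading eigenvector is only well-defined (Perron) on connected
    # graphs; on disconnected ones it concentrates on the dominant component
    if (max(oracle_components(A)) == 1) {
      expect_equal(nm$eigenvector, oracle_eigenvector(A), tolerance = 1e-6)
    }
    expect_equal(net$components, max(oracle_components(A)))
    expect_equal(net$char_path_length, oracle_char_path_length(A),
                 tolerance = 1e-12)
    expect_equal(net$avg_clustering, mean(oracle_clustering(A)),
                 tolerance = 1e-12)

    # structural identities
    expect_equal(sum(nm$degree), 2 * G$m)
    expect_equal(net$density, 2 * G$m / (n * (n - 1)))
    expect_equal(net$count_deg_1_6 + net$count_deg_ge7 + sum(nm$degree == 0), n)
  }
})

test_that("adding an edge never decreases degree-based summaries", {
  set.seed(201)
  A <- random_adjacency(8, 0.3)
  miss <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  net0 <- network_metrics(as_mea_graph(A))
  e <- miss[sample(nrow(miss), 1), ]
  A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1
  net1 <- network_metrics(as_mea_graph(A2))
  expect_gte(net1$avg_degree, net0$avg_degree)
  expect_gte(net1$density, net0$density)

  expect_equal(network_metrics(as_mea_graph(graph_fixtures()$k5))$density, 1)
})

test_that("closeness is bounded by direct adjacency within a component", {
  set.seed(202)
  for (rep in 1:10) {
    A <- random_adjacency(9, 0.35)
    nm <- node_metrics(as_mea_graph(A))
    for (i in seq_len(9)) {
      comp_size <- sum(oracle_components(A) == oracle_components(A)[i])
      if (comp_size > 1) {
        expect_lte(nm$closeness[i], 1 / (comp_size - 1) + 1e-12)
        if (sum(A[i, ]) == comp_size - 1) {
          expect_equal(nm$closeness[i], 1 / (comp_size - 1))
        }
      }
    }
  }
})
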