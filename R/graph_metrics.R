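# Graph-theoretic metrics on the binary functional-connectivity graph.
#
# Conventions for disconnected graphs (the data routinely yield 3-4
# components): the characteristic path length averages over connected pairs
# only (the excluded fraction is reported); closeness and eccentricity are
# restricted to a node's own component; eigenvector centrality comes from
# the leading (Perron) eigenvector of the full adjacency matrix, which
# concentrates on the dominant component — this is flagged in the output.

#' Construct a graph object from an adjacency or weight matrix
#'
#' @param A square symmetric matrix; any entry with `|A| > 0` is an edge.
#'   A binary adjacency is derived; the original values are retained as
#'   weights.
#' @param node_ids optional node identifiers (default rownames or 1..n).
#' @return object of class `mea_graph`: list with `n`, `m`, `A` (binary),
#'   `W` (weights), `node_ids`, and the underlying `igraph` object.
#' @export
as_mea_graph <- function(A, node_ids = NULL) {
  A <- .check_square_symmetric(A, what = "adjacency matrix")
  diag(A) <- 0
  Ab <- (abs(A) > 0) + 0
  n <- nrow(Ab)
  node_ids <- node_ids %||% rownames(A) %||% as.character(seq_len(n))
  dimnames(Ab) <- list(node_ids, node_ids)
  g <- igraph::graph_from_adjacency_matrix(Ab, mode = "undirected")
  structure(list(n = n, m = sum(Ab) / 2, A = Ab, W = A, node_ids = node_ids,
                 igraph = g), class = "mea_graph")
}

#' Per-node graph metrics
#'
#' Degree, local clustering coefficient (0 for nodes of degree < 2),
#' betweenness centrality (unnormalized, endpoints excluded, each unordered
#' pair counted once), closeness centrality (reciprocal of the total hop
#' distance to the reachable nodes of the node's component), eigenvector
#' centrality (leading eigenvector of the adjacency matrix, non-negative,
#' scaled to max 1), and eccentricity (hops to the farthest node in the
#' component).
#'
#' @param G an [as_mea_graph()] object.
#' @return data frame with one row per node: `node`, `degree`, `clustering`,
#'   `betweenness`, `closeness`, `eigenvector`, `eccentricity`, `component`.
#' @export
node_metrics <- function(G) {
  .assert(inherits(G, "mea_graph"), "G must be an mea_graph")
  if (G$n == 0) {
    return(data.frame(node = character(0), degree = numeric(0),
                      clustering = numeric(0), betweenness = numeric(0),
                      closeness = numeric(0), eigenvector = numeric(0),
                      eccentricity = numeric(0), component = integer(0)))
  }
  g <- G$igraph
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all",
                                            normalized = FALSE))
  clo[deg == 0] <- 0   # isolated node reaches nothing
  # leading eigenvector from a full symmetric eigendecomposition: exact and
  # deterministic (ARPACK would introduce a random start vector)
  eig <- if (G$m > 0) {
    v <- eigen(G$A, symmetric = TRUE)$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / max(v)
  } else rep(0, G$n)
  ecc <- igraph::eccentricity(g, mode = "all")
  comp <- igraph::components(g)$membership
  data.frame(node = G$node_ids, degree = as.numeric(deg),
             clustering = as.numeric(cc), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), eigenvector = as.numeric(eig),
             eccentricity = as.numeric(ecc), component = as.integer(comp),
             row.names = NULL)
}

#' Network-level graph metrics
#'
#' Average degree, density `2m / (n (n - 1))`, number of connected
#' components, characteristic path length (mean shortest path over connected
#' node pairs, with the excluded-pair fraction reported), average clustering
#' coefficient (mean of local coefficients, 0 for degree < 2), the degree
#' histogram and cumulative distribution, and the node counts in the degree
#' bands 1-6 and >= 7.
#'
#' @param G an [as_mea_graph()] object.
#' @return list of network summaries; `char_path_length` is `NA` when no
#'   connected pair exists.
#' @export
network_metrics <- function(G) {
  .assert(inherits(G, "mea_graph"), "G must be an mea_graph")
  nm <- node_metrics(G)
  n <- G$n
  deg <- nm$degree
  K <- if (n > 0) mean(deg) else NA_real_
  rho <- if (n > 1) 2 * G$m / (n * (n - 1)) else 0
  comp <- if (n > 0) igraph::components(G$igraph)$no else 0L
  if (n > 1) {
    D <- igraph::distances(G$igraph)
    finite_off <- is.finite(D) & upper.tri(D)
    n_conn_pairs <- sum(finite_off)
    l <- if (n_conn_pairs > 0) mean(D[finite_off]) else NA_real_
    frac_excluded <- 1 - n_conn_pairs / (n * (n - 1) / 2)
  } else {
    l <- NA_real_; frac_excluded <- NA_real_
  }
  cc_bar <- if (n > 0) mean(nm$clustering) else NA_real_
  hist <- if (n > 0) {
    tab <- tabulate(deg + 1L, nbins = max(deg) + 1L)
    data.frame(degree = seq_along(tab) - 1L, count = tab,
               probability = tab / n)
  } else data.frame(degree = integer(0), count = integer(0),
                    probability = numeric(0))
  cumdist <- if (nrow(hist)) cumsum(hist$probability) else numeric(0)
  list(n = n, m = G$m, avg_degree = K, density = rho, components = comp,
       char_path_length = l, frac_pairs_excluded = frac_excluded,
       avg_clustering = cc_bar, degree_hist = hist,
       degree_cumulative = cumdist,
       count_deg_1_6 = sum(deg >= 1 & deg <= 6),
       count_deg_ge7 = sum(deg >= 7),
       max_degree = if (n > 0) max(deg) else NA_real_)
}
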