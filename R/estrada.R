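# Estrada index, odd-subgraph centrality, spectral scaling and the
# topological classification of nodes and networks into classes I-IV.
#
# The classification compares each node's global communicability (principal
# eigenvector component x_i) with its local communicability (odd-subgraph
# centrality SC_odd) on a log10 scale. In a perfectly "spectrally scaled"
# network, log10 x_i = 0.5 * log10(SC_odd(i) / sinh(lambda_max)); departures
# from that ideal line below (class II, structural holes) or above
# (class III, central cores) beyond a data-derived threshold mark
# heterogeneous topology; class IV networks contain both. The threshold is
# derived from the spread of the distances to the ideal line, floored at the
# classical good-expansion tolerance of 0.01 log10 units below which
# departures are negligible (see classify_nodes), and the method runs on the
# positive weighted correlation matrix, whose entries lie in [0, 1].

#' Estrada index
#'
#' `EE = sum(exp(lambda_i))` over the full spectrum of a symmetric (binary
#' or weighted) matrix. For a binary adjacency `EE >= n`, with equality only
#' for an edgeless graph.
#'
#' @param M symmetric numeric matrix.
#' @param tol asymmetry tolerance.
#' @return the Estrada index (scalar).
#' @export
estrada_index <- function(M, tol = 1e-8) {
  M <- .check_square_symmetric(M, tol = tol, what = "matrix")
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sum(exp(lam))
}

#' Subgraph centralities from the full eigendecomposition
#'
#' `SC(i) = sum_j phi_j(i)^2 * f(lambda_j)` with orthonormal eigenvectors
#' `phi_j`; `f = exp` gives the total subgraph centrality (which sums to the
#' Estrada index), `f = sinh` the odd-closed-walk part used for spectral
#' scaling, `f = cosh` the even part.
#'
#' @param M symmetric numeric matrix.
#' @param kind one of `"odd"` (sinh), `"even"` (cosh), `"full"` (exp).
#' @param tol asymmetry tolerance.
#' @return numeric vector of per-node centralities.
#' @export
subgraph_centrality <- function(M, kind = c("full", "odd", "even"),
                                tol = 1e-8) {
  kind <- match.arg(kind)
  M <- .check_square_symmetric(M, tol = tol, what = "matrix")
  eg <- eigen(M, symmetric = TRUE)
  f <- switch(kind, full = exp, odd = sinh, even = cosh)
  as.numeric(eg$vectors^2 %*% f(eg$values))
}

#' @rdname subgraph_centrality
#' @export
odd_subgraph_centrality <- function(M, tol = 1e-8) {
  subgraph_centrality(M, kind = "odd", tol = tol)
}

#' Spectral-scaling classification of nodes
#'
#' Computes the principal eigenpair of the non-negative weighted matrix
#' `W_pos`, the odd-subgraph centralities, and each node's vertical distance
#' (residual) in log10 space from the ideal scaling line
#' `log10 x_i = 0.5 * log10(SC_odd(i) / sinh(lambda_max))`. The
#' classification threshold `tau` is derived from the distances to the ideal
#' line: with `threshold_mode = "sd"` (default) `tau` is the root mean
#' square of the residuals, so the bound has the same (log10) units as the
#' residuals; with `"variance"` it is their mean square, kept for
#' comparability with threshold conventions stated in squared units. In both
#' modes `tau` is floored at `min_band` (default 0.01 log10 units, the
#' classical good-expansion tolerance): in networks with near-perfect
#' spectral scaling the residual spread collapses towards numerical noise,
#' and a purely relative band would then misread that noise as topology.
#' Nodes with `|r_i| <= tau` are class I (homogeneous), `r_i < -tau` class
#' II (below the lower bound: structural holes), `r_i > tau` class III
#' (above the upper bound: central cores). Nodes whose `SC_odd` or
#' eigenvector component does not exceed `eps` (e.g. every node of a
#' bipartite graph, which has no odd closed walks) are unclassified.
#'
#' @param W_pos symmetric non-negative matrix with zero diagonal (binary
#'   adjacency or positive weighted correlation matrix).
#' @param threshold_mode `"sd"` (RMS distance, default) or `"variance"`.
#' @param min_band lower bound on the class-I half-width in log10 units
#'   (`min_band^2` in `"variance"` mode).
#' @param eps positivity floor for classifiability (default 1e-12).
#' @param tol asymmetry tolerance.
#' @return object of class `SpectralClassification`: `eigenvalues`
#'   (ascending), `estrada_index`, and a per-node data frame `nodes` with
#'   `x` (principal eigenvector, unit 2-norm), `sc_odd`, `residual`,
#'   `node_class` (`"I"`, `"II"`, `"III"`, `"unclassified"`); plus `tau`,
#'   `threshold_mode`, `lambda_max`.
#' @export
classify_nodes <- function(W_pos, threshold_mode = c("sd", "variance"),
                           min_band = 0.01, eps = 1e-12, tol = 1e-8) {
  threshold_mode <- match.arg(threshold_mode)
  W_pos <- .check_square_symmetric(W_pos, tol = tol, what = "W_pos")
  .assert(min(W_pos) >= 0, "W_pos must be non-negative")
  .assert(all(abs(diag(W_pos)) <= eps), "W_pos must have zero diagonal")
  n <- nrow(W_pos)
  ids <- rownames(W_pos) %||% as.character(seq_len(n))
  eg <- eigen(W_pos, symmetric = TRUE)
  lam <- eg$values                   # decreasing from eigen()
  lambda_max <- lam[1]
  x <- eg$vectors[, 1]
  if (sum(x) < 0) x <- -x            # Perron vector, non-negative orientation
  x <- pmax(x, 0)
  sc_odd <- as.numeric(eg$vectors^2 %*% sinh(lam))
  classifiable <- sc_odd > eps & x > eps & sinh(lambda_max) > eps
  if (!any(classifiable)) {
    stop(paste0("no classifiable node: all odd-subgraph centralities or ",
                "eigenvector components are <= eps (e.g. bipartite or ",
                "edgeless input)"), call. = FALSE)
  }
  residual <- rep(NA_real_, n)
  residual[classifiable] <-
    log10(x[classifiable]) -
    0.5 * (log10(sc_odd[classifiable]) - log10(sinh(lambda_max)))
  r <- residual[classifiable]
  rms2 <- mean(r^2)
  tau <- if (threshold_mode == "sd") max(sqrt(rms2), min_band)
         else max(rms2, min_band^2)
  # small slack so graphs whose residuals are all exactly equal (regular
  # graphs) sit on, not beyond, the class-I boundary
  cls <- rep("unclassified", n)
  cls[classifiable] <- ifelse(abs(r) <= tau + 1e-9, "I",
                              ifelse(r < -tau, "II", "III"))
  nodes <- data.frame(node = ids, x = x, sc_odd = sc_odd,
                      residual = residual, node_class = cls,
                      row.names = NULL)
  structure(list(eigenvalues = rev(lam),
                 estrada_index = sum(exp(lam)),
                 lambda_max = lambda_max, tau = tau,
                 threshold_mode = threshold_mode, nodes = nodes),
            class = "SpectralClassification")
}

#' Network-level topological class from node classes
#'
#' Percentages of classes I/II/III are taken over classified nodes. The
#' network is class IV when both class II and class III percentages reach
#' `min_fraction`; class II or III when only the respective class does; and
#' class I otherwise. The ratio CII/CIII is reported (absent when the class
#' III percentage is zero).
#'
#' @param classification a [classify_nodes()] result, or a character vector
#'   of node classes.
#' @param min_fraction minimum class fraction (default 0.05).
#' @return list with `percentages` (named, classes I/II/III, summing to
#'   100), `network_class`, `ratio_II_III`, `n_classified`,
#'   `n_unclassified`.
#' @export
classify_network <- function(classification, min_fraction = 0.05) {
  cls <- if (inherits(classification, "SpectralClassification")) {
    classification$nodes$node_class
  } else as.character(classification)
  cls <- cls[cls %in% c("I", "II", "III")]
  n_un <- length(classification) - length(cls)
  if (inherits(classification, "SpectralClassification")) {
    n_un <- sum(classification$nodes$node_class == "unclassified")
  }
  .assert(length(cls) > 0, "zero classified nodes")
  pct <- 100 * c(I = mean(cls == "I"), II = mean(cls == "II"),
                 III = mean(cls == "III"))
  has_II <- pct[["II"]] >= 100 * min_fraction
  has_III <- pct[["III"]] >= 100 * min_fraction
  network_class <- if (has_II && has_III) "IV"
    else if (has_II) "II" else if (has_III) "III" else "I"
  ratio <- if (pct[["III"]] > 0) pct[["II"]] / pct[["III"]] else NA_real_
  list(percentages = pct, network_class = network_class,
       ratio_II_III = ratio, n_classified = length(cls),
       n_unclassified = n_un)
}
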