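# Small-world sigma and omega indices against null ensembles.
#
# "Equivalent random network": degree-preserving double-edge-swap
# randomization (preserves n, m and the degree sequence). "Equivalent
# lattice": swap-based latticization — double-edge swaps accepted only when
# they do not increase the total distance of edges from the diagonal of the
# adjacency matrix under a random node ordering, which concentrates edges
# into a ring-lattice-like band. Both inherit the connected-pairs convention
# for path length from network_metrics().

# Clustering coefficient (mean local, 0 for degree < 2) and characteristic
# path length (connected pairs only) of an igraph object.
.graph_CL <- function(g) {
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  D <- igraph::distances(g)
  finite_off <- is.finite(D) & upper.tri(D)
  L <- if (any(finite_off)) mean(D[finite_off]) else NA_real_
  c(C = mean(cc), L = L)
}

# Latticization: accepted double-edge swaps that do not increase
# sum(|pos(u) - pos(v)|) over edges, under a random node ordering. The swap
# loop lives in compiled code (src/latticize.cpp) and draws from R's RNG.
.latticize <- function(g, n_accept, max_attempts = NULL) {
  n <- igraph::vcount(g)
  E <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(E)
  if (m < 2) return(g)
  max_attempts <- max_attempts %||% (50L * n_accept)
  pos <- sample.int(n)
  E2 <- .latticize_edges(E, n, pos, as.integer(n_accept),
                         as.integer(max_attempts))
  igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                    as.vector(t(E2)))
}

#' Null ensembles for small-world analysis
#'
#' Draws `n_nulls` random (degree-preserving rewired) and `n_nulls` lattice
#' (latticized) surrogates of `G` and records the clustering coefficient and
#' characteristic path length of each. Every surrogate preserves n, m and
#' the degree sequence of the source graph. Graphs admitting no valid swap
#' (e.g. stars) return surrogates equal to the source, with a warning.
#'
#' @param G an [as_mea_graph()] object with at least one edge.
#' @param n_nulls ensemble size (default 1000; around 100 is adequate for
#'   exploratory runs).
#' @param seed integer seed.
#' @param kinds which ensembles to build.
#' @return named list of `NullEnsemble` objects (`kind`, `size`, `C`, `L`,
#'   `C_mean`, `L_mean`, `seed`).
#' @export
null_ensembles <- function(G, n_nulls = 1000, seed = 1L,
                           kinds = c("random", "lattice")) {
  .assert(inherits(G, "mea_graph"), "G must be an mea_graph")
  .assert(G$m >= 1, "G must have at least one edge")
  g <- G$igraph
  m <- G$m
  out <- list()
  .with_seed(seed, {
    for (kind in kinds) {
      CL <- matrix(NA_real_, n_nulls, 2)
      warned <- FALSE
      for (r in seq_len(n_nulls)) {
        gn <- if (kind == "random") {
          igraph::rewire(g, igraph::keeping_degseq(niter = 20 * m))
        } else {
          .latticize(g, n_accept = 10L * m)
        }
        if (!warned && r == 1 && m >= 2 &&
            identical(igraph::as_edgelist(gn), igraph::as_edgelist(g))) {
          warning(sprintf("%s ensemble: no valid swap found, nulls equal the source graph",
                          kind), call. = FALSE)
          warned <- TRUE
        }
        CL[r, ] <- .graph_CL(gn)
      }
      out[[kind]] <- structure(
        list(kind = kind, size = n_nulls, C = CL[, 1], L = CL[, 2],
             C_mean = mean(CL[, 1]), L_mean = mean(CL[, 2], na.rm = TRUE),
             seed = seed),
        class = "NullEnsemble")
    }
  })
  out
}

#' Ensembles consisting of the graph itself
#'
#' Degenerate "nulls" equal to the source graph; useful as a calibration
#' check, since measuring a graph against itself must give sigma = 1.
#'
#' @param G an [as_mea_graph()] object.
#' @return the same structure as [null_ensembles()].
#' @export
identity_ensembles <- function(G) {
  cl <- .graph_CL(G$igraph)
  mk <- function(kind) structure(
    list(kind = kind, size = 1L, C = cl["C"], L = cl["L"],
         C_mean = unname(cl["C"]), L_mean = unname(cl["L"]), seed = NA),
    class = "NullEnsemble")
  list(random = mk("random"), lattice = mk("lattice"))
}

#' Small-world sigma and omega indices
#'
#' `sigma = (C / C_rand) / (L / L_rand)` and
#' `omega = L_rand / L - C / C_latt`. Values of omega between -0.3 and 0.3
#' are conventionally read as small-world; more negative is lattice-like,
#' more positive random-like. Omega outside `[-1, 1]` is clipped with a
#' warning.
#'
#' @param G an [as_mea_graph()] object.
#' @param ensembles output of [null_ensembles()] (or
#'   [identity_ensembles()]); built with `n_nulls` and `seed` if `NULL`.
#' @param n_nulls,seed used only when `ensembles` is `NULL`.
#' @return object of class `SmallWorldResult`: `C`, `L`, `C_rand`, `L_rand`,
#'   `C_latt`, `gamma`, `lambda_ratio`, `sigma`, `omega`, `n_nulls`,
#'   `reason` (non-`NA` when an index is unavailable).
#' @export
small_world_indices <- function(G, ensembles = NULL, n_nulls = 1000,
                                seed = 1L) {
  .assert(inherits(G, "mea_graph"), "G must be an mea_graph")
  if (is.null(ensembles)) {
    ensembles <- null_ensembles(G, n_nulls = n_nulls, seed = seed)
  }
  cl <- .graph_CL(G$igraph)
  C <- unname(cl["C"]); L <- unname(cl["L"])
  C_rand <- ensembles$random$C_mean
  L_rand <- ensembles$random$L_mean
  C_latt <- ensembles$lattice$C_mean
  reason <- NA_character_
  gamma <- lambda_ratio <- sigma <- omega <- NA_real_
  if (is.na(L)) {
    reason <- "characteristic path length undefined (no connected pair)"
  } else if (!is.finite(C_rand) || C_rand == 0) {
    reason <- "C_rand is zero: gamma undefined"
  } else {
    gamma <- C / C_rand
    lambda_ratio <- L / L_rand
    sigma <- gamma / lambda_ratio
    if (is.finite(C_latt) && C_latt > 0) {
      omega <- L_rand / L - C / C_latt
      if (omega < -1 || omega > 1) {
        warning(sprintf("omega = %.3f outside [-1, 1]: clipped", omega),
                call. = FALSE)
        omega <- max(-1, min(1, omega))
      }
    } else {
      reason <- "C_latt is zero: omega undefined"
    }
  }
  structure(list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                 C_latt = C_latt, gamma = gamma, lambda_ratio = lambda_ratio,
                 sigma = sigma, omega = omega,
                 n_nulls = ensembles$random$size, reason = reason),
            class = "SmallWorldResult")
}
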