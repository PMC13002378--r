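# Brute-force graph oracles, independent of the package's igraph-backed
# implementation: distances by repeated boolean matrix products, shortest-path
# counts by dynamic programming on the distance matrix, eigenvector centrality
# by power iteration.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- (Ak %*% A) > 0
    newly <- Ak & !reach
    D[newly] <- k
    reach <- reach | Ak
    if (all(reach | D == Inf)) next
  }
  D
}

# sigma[s, t]: number of shortest s-t paths, via DP over distance layers.
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    cnt <- numeric(n)
    cnt[s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      preds <- which(A[, v] > 0 & D[s, ] == D[s, v] - 1)
      cnt[v] <- sum(cnt[preds])
    }
    S[s, ] <- cnt
  }
  S
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  btw <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i || !is.finite(D[s, t])) next
      # paths through i: s->i->t on shortest route
      if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == D[s, t]) {
        btw[i] <- btw[i] + S[s, i] * S[i, t] / S[s, t]
      }
    }
  }
  btw
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / sum(d)
  }, numeric(1))
}

oracle_eccentricity <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, ]
    max(d[is.finite(d)])
  }, numeric(1))
}

oracle_eigenvector <- function(A, iter = 5000) {
  n <- nrow(A)
  if (sum(A) == 0) return(rep(0, n))
  # iterate on A + I: same eigenvectors, but convergent also for bipartite
  # graphs where plain power iteration oscillates between +/- lambda
  M <- A + diag(n)
  x <- rep(1, n)
  for (k in seq_len(iter)) {
    x2 <- as.numeric(M %*% x)
    nrm <- max(abs(x2))
    if (nrm == 0) return(rep(0, n))
    x2 <- x2 / nrm
    if (max(abs(x2 - x)) < 1e-14) { x <- x2; break }
    x <- x2
  }
  x / max(x)
}

oracle_components <- function(A) {
  D <- oracle_distances(A)
  memb <- integer(nrow(A))
  cid <- 0L
  for (i in seq_len(nrow(A))) {
    if (memb[i] == 0L) {
      cid <- cid + 1L
      memb[is.finite(D[i, ])] <- cid
    }
  }
  memb
}

oracle_char_path_length <- function(A) {
  D <- oracle_distances(A)
  up <- D[upper.tri(D)]
  up <- up[is.finite(up)]
  if (!length(up)) NA_real_ else mean(up)
}

# Random symmetric adjacency with no self-loops.
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A + t(A)
}

# Named small fixtures used across graph tests.
graph_fixtures <- function() {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star) * 0
  star[2:5, 1] <- 1
  p4 <- matrix(0, 4, 4); for (i in 1:3) p4[i, i + 1] <- p4[i + 1, i] <- 1
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- c4[j, i] <- 1 }
  tri_pend <- matrix(0, 4, 4)
  tri_pend[1, 2] <- tri_pend[2, 3] <- tri_pend[1, 3] <- tri_pend[3, 4] <- 1
  tri_pend <- tri_pend + t(tri_pend); tri_pend[tri_pend > 1] <- 1
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  list(star = star, p4 = p4, c4 = c4, tri_pend = tri_pend, k4 = k4, k5 = k5)
}
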