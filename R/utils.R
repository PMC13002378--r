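# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.check_square_symmetric <- function(M, tol = 1e-8, what = "matrix") {
  .assert(is.matrix(M) && is.numeric(M), "%s must be a numeric matrix", what)
  .assert(nrow(M) == ncol(M), "%s must be square (got %d x %d)",
          what, nrow(M), ncol(M))
  .assert(all(is.finite(M)), "%s must be finite", what)
  asym <- max(abs(M - t(M)))
  .assert(asym <= tol,
          "%s must be symmetric (max |M - t(M)| = %g > tol %g)",
          what, asym, tol)
  invisible((M + t(M)) / 2)
}

# Sample standard deviation is not what Cohen's d pools: use the pooled SD
# with (n1 + n2 - 2) degrees of freedom.
cohens_d_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  .assert(nx >= 2 && ny >= 2, "Cohen's d needs at least 2 values per group")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Derive a reproducible child seed from a base seed and a stream label,
# staying below .Machine$integer.max.
.child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's RNG afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))
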