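test_that("correlogram normalization and lag conventions are correct", {
  set.seed(99)
  t1 <- sort(runif(600, 0, 60000))
  cc_self <- cross_correlogram(t1, t1)
  expect_equal(cc_self$values[cc_self$lags == 0], 1)

  t2 <- t1 + 3
  cc <- cross_correlogram(t1, t2)
  expect_equal(cc$peak_lag, 3)
  cc_rev <- cross_correlogram(t2, t1)
  expect_equal(cc_rev$peak_lag, -3)
  # antisymmetry of the full correlogram
  expect_equal(cc$values, rev(cc_rev$values))
})

test_that("pairs with too few spikes are skipped with a warning", {
  expect_warning(out <- cross_correlogram(c(1, 2, 3), sort(runif(100, 0, 1000))),
                 "skipped")
  expect_null(out)
})

test_that("uncoupled pairs stay below the 5-SD threshold almost always", {
  cfg <- population_config(n_sua = 21, n_mua = 0, rate_pyr_hz = 5,
                           rate_in_hz = 5, rate_sd_log10 = 0.1,
                           duration_s = 600, seed = 100)
  gb <- generate_baseline(cfg)   # no coupling
  ccs <- cross_correlogram_set(gb$set)
  z <- vapply(ccs$pairs, function(p)
    (p$cc$peak_value - p$cc$flank_mean) / p$cc$flank_sd, numeric(1))
  expect_gte(mean(z < 5), 0.99)
  conn <- build_connectivity(ccs)
  expect_lte((conn$n_pos + conn$n_neg) / length(ccs$pairs), 0.01)
})

test_that("a single planted coupling yields exactly that link", {
  n <- 3
  C <- matrix(0, n, n); C[1, 2] <- C[2, 1] <- 0.3
  cfg <- population_config(n_sua = n, n_mua = 0, rate_pyr_hz = 4,
                           rate_in_hz = 4, rate_sd_log10 = 0,
                           duration_s = 600, seed = 101)
  gb <- generate_baseline(cfg, coupling = C)
  conn <- build_connectivity(cross_correlogram_set(gb$set))
  expect_equal(conn$n_pos, 1)
  expect_gt(conn$W_pos[1, 2], 0)
  expect_equal(conn$W_pos, t(conn$W_pos))
  expect_true(all(diag(conn$W_pos) == 0))
  expect_true(all(conn$W_pos >= 0 & conn$W_pos <= 1))
  expect_identical(unname(conn$A_pos > 0), unname(conn$W_pos > 0))
})

test_that("planted couplings >= 0.1 are recovered with high sensitivity", {
  n <- 30
  set.seed(102)
  C <- matrix(0, n, n)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  picked <- pairs[sample(nrow(pairs), 20), ]
  for (r in seq_len(nrow(picked))) {
    i <- picked[r, 1]; j <- picked[r, 2]
    C[i, j] <- C[j, i] <- runif(1, 0.1, 0.2)
  }
  cfg <- population_config(n_sua = 28, n_mua = 2, duration_s = 600,
                           seed = 103)
  gb <- generate_baseline(cfg, coupling = C)
  conn <- build_connectivity(cross_correlogram_set(gb$set))
  up <- upper.tri(C)
  sens <- sum(conn$A_pos[up & C > 0]) / sum(C[up] > 0)
  fpr <- sum(conn$A_pos[up & C == 0]) / sum(up & C == 0)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.01)
})

test_that("raising the significance multiplier never adds links", {
  cfg <- population_config(n_sua = 15, n_mua = 0, duration_s = 300, seed = 104)
  C <- matrix(0.1, 15, 15); diag(C) <- 0
  gb <- generate_baseline(cfg, coupling = C)
  ccs <- cross_correlogram_set(gb$set)
  prev <- NULL
  for (k in c(3, 5, 8, 12)) {
    conn <- build_connectivity(ccs, k_sd = k)
    if (!is.null(prev)) {
      expect_true(all(conn$A_pos <= prev$A_pos))
      expect_true(all(conn$A_neg <= prev$A_neg))
    }
    prev <- conn
  }
})

test_that("weights are invariant to a uniform time shift of all trains", {
  cfg <- population_config(n_sua = 8, n_mua = 0, duration_s = 300, seed = 105)
  C <- matrix(0.15, 8, 8); diag(C) <- 0
  gb <- generate_baseline(cfg, coupling = C)
  conn1 <- build_connectivity(cross_correlogram_set(gb$set))
  shifted <- gb$set
  shifted$units <- lapply(shifted$units, function(u) {
    u$timestamps_ms <- u$timestamps_ms + 1000; u
  })
  shifted$duration_ms <- shifted$duration_ms + 1000
  conn2 <- build_connectivity(cross_correlogram_set(shifted))
  expect_equal(conn1$W_pos, conn2$W_pos)
})

test_that("connectivity comparison splits differences by sign", {
  cfg <- population_config(n_sua = 6, n_mua = 0, duration_s = 120, seed = 106)
  gb <- generate_baseline(cfg)
  conn <- build_connectivity(cross_correlogram_set(gb$set))
  same <- compare_connectivity(conn, conn)
  expect_true(all(same$delta == 0))
  expect_equal(same$n_increase + same$n_decrease, 0)

  treated <- conn
  treated$W_pos[1, 2] <- treated$W_pos[2, 1] <- 0.3
  cmp <- compare_connectivity(conn, treated)
  expect_equal(cmp$n_increase, 1)
  expect_equal(cmp$n_decrease, 0)
  expect_equal(cmp$mean_abs_increase, 0.3)
})

test_that("Cohen's d of equal-mean difference samples is near zero", {
  set.seed(107)
  inc <- rnorm(1000, 0.03, 0.01)
  dec <- rnorm(1000, 0.03, 0.01)
  expect_lt(abs(cohens_d_stat(inc, dec)), 0.01 + 3 / sqrt(1000))
})
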