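test_that("unit rates are spike count over window length", {
  set <- spike_train_set(list(
    list(unit_id = "a", kind = "SUA",
         timestamps_ms = seq(0, 59999, length.out = 600)),
    list(unit_id = "b", kind = "SUA", timestamps_ms = numeric(0))),
    duration_ms = 60000)
  r <- unit_rates(set)
  expect_equal(unname(r["a"]), 10)
  expect_equal(unname(r["b"]), 0)
  expect_error(unit_rates(set, window = c(5, 5)), "positive length")
})

test_that("burst detection recovers constructed peaks above 5 SD of the noise", {
  # flat popsum has no events
  flat <- structure(list(bin_ms = 1, bins = 4000, t0_ms = 0,
                         occupancy = matrix(1L, 4, 4000)), class = "Raster")
  expect_equal(detect_bursts(flat, bin_ms = 500)$count, 0)

  # background ~4 per 500-ms bin with five isolated peaks of 60
  set.seed(8)
  n_bins <- 600 * 1000
  occ <- matrix(0L, 8, n_bins)
  bg <- sample(n_bins, 4 * 1200)
  occ[cbind(sample(8, length(bg), TRUE), bg)] <- 1L
  peak_bins <- c(100, 300, 500, 700, 900)      # coarse 500-ms bin indices
  for (pb in peak_bins) {
    cols <- ((pb - 1) * 500 + 1):((pb - 1) * 500 + 60)
    for (u in 1:8) occ[u, cols[((u - 1) * 7 + 1):((u - 1) * 7 + 7)]] <- 1L
  }
  raster <- structure(list(bin_ms = 1, bins = n_bins, t0_ms = 0,
                           occupancy = occ), class = "Raster")
  b <- detect_bursts(raster, bin_ms = 500)
  expect_equal(b$count, 5)
  expect_setequal(b$events$bin, peak_bins)
  expect_true(all(b$events$height >= b$threshold))
})

test_that("burst count is monotone non-increasing in the SD multiplier", {
  cfg <- population_config(n_sua = 30, n_mua = 2, duration_s = 300, seed = 9)
  gb <- generate_baseline(cfg)
  tr <- apply_condition(gb$set, condition_effect(burst_rate_per_min = 2),
                        seed = 10, baseline_truth = gb$ground_truth)
  raster <- bin_raster(tr$set, bin_ms = 1)
  counts <- vapply(c(2, 3, 5, 8), function(k)
    detect_bursts(raster, bin_ms = 500, k_sd = k)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("injected synchrony epochs are detected at about the planted rate", {
  cfg <- population_config(n_sua = 40, n_mua = 4, duration_s = 600, seed = 12)
  gb <- generate_baseline(cfg)
  tr <- apply_condition(gb$set, condition_effect(burst_rate_per_min = 1),
                        seed = 13, baseline_truth = gb$ground_truth)
  b <- detect_bursts(bin_raster(tr$set, bin_ms = 1), bin_ms = 500)
  expect_true(abs(b$count - 10) <= 2)
})

test_that("rate-change classification follows the relative tolerance rule", {
  base <- c(a = 2, b = 1, c = 5)
  trt <- c(a = 1, b = 2, c = 5)
  res <- classify_rate_change(base, trt, rel_tol = 0.01)
  expect_equal(unname(res$direction), c("decrease", "increase", "unchanged"))
  expect_equal(sum(res$proportions), 1)

  same <- classify_rate_change(base, base)
  expect_equal(unname(same$proportions["unchanged"]), 1)

  expect_warning(classify_rate_change(c(a = 1, b = 2), c(a = 1)), "excluded")
})

test_that("cell typing separates the two planted classes and anchors labels", {
  set.seed(14)
  n <- 500; npyr <- round(0.789 * n)
  feat <- data.frame(
    unit_id = as.character(seq_len(n)),
    trough_to_peak_ms = c(rnorm(npyr, 0.76, 0.10), rnorm(n - npyr, 0.22, 0.10)),
    rate_hz = 10 ^ c(rnorm(npyr, log10(3.2), 0.4),
                     rnorm(n - npyr, log10(6.9), 0.4)))
  truth <- c(rep("PPyrN", npyr), rep("PIN", n - npyr))
  ct <- classify_cell_types(feat, seed = 15)
  expect_gte(mean(ct$labels == truth), 0.95)
  # label anchoring: mirrored input row order gives the same labelling
  ct2 <- classify_cell_types(feat[rev(seq_len(n)), ], seed = 15)
  expect_gte(mean(ct2$labels[names(ct$labels)] == ct$labels), 0.99)
  # the broader-waveform cluster is always the pyramidal one
  expect_gt(ct$cluster_stats$median_ttp_ms[ct$cluster_stats$cell_class == "PPyrN"],
            ct$cluster_stats$median_ttp_ms[ct$cluster_stats$cell_class == "PIN"])
})

test_that("Cohen's d matches its definition on calibrated groups", {
  set.seed(16)
  x <- rnorm(4000, 1, 1); y <- rnorm(4000, 0, 1)
  expect_equal(cohens_d_stat(x, y), 1, tolerance = 0.1)
  expect_equal(cohens_d_stat(y, x), -cohens_d_stat(x, y))
  expect_equal(cohens_d_stat(rep(2, 5), rep(2, 5)), 0)
})

test_that("chi-square association matches the hand-computed 2x2 example", {
  tab <- rbind(c(10, 20), c(20, 10))   # all expecteds 15
  res <- association_stats(tab)
  expect_equal(res$chisq, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_equal(association_stats(rbind(c(5, 5), c(5, 5)))$chisq, 0)
  expect_equal(association_stats(t(tab))$chisq, res$chisq)
  expect_warning(association_stats(rbind(c(0, 1), c(1, 2))), "expected")
})

test_that("band power localizes pure tones and satisfies Parseval sharing", {
  t <- seq(0, 120 - 1 / 500, by = 1 / 500)
  tone6 <- lfp_trace(sin(2 * pi * 6 * t), fs = 500)
  bp <- band_power(tone6)
  expect_gte(bp$band_power[["theta"]] / bp$broadband, 0.9)

  two <- lfp_trace(sin(2 * pi * 2 * t) + sin(2 * pi * 30 * t), fs = 500)
  bp2 <- band_power(two)
  expect_equal(bp2$band_power[["delta"]], bp2$band_power[["gamma"]],
               tolerance = 0.05)

  zero <- lfp_trace(numeric(60 * 500), fs = 500)
  expect_true(all(band_power(zero)$band_power == 0))
  # broadband equals the band sum plus the sub-delta remainder
  expect_gte(bp2$broadband - sum(bp2$band_power), -1e-9)
})

test_that("white-noise band power is approximately proportional to bandwidth", {
  set.seed(17)
  tr <- lfp_trace(rnorm(500 * 120), fs = 500)
  bp <- band_power(tr)
  bw <- vapply(lfp_bands(), diff, numeric(1))
  dens <- bp$band_power / bw
  expect_lt(max(dens) / min(dens), 1.25 / 0.75)
})

test_that("paired comparison selects the test by normality of differences", {
  a <- c(1, 2, 3, 4, 5)
  same <- paired_compare(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 0)

  set.seed(18)
  x <- rnorm(10)
  shifted <- paired_compare(x, x + 10 + rnorm(10, 0, 0.1))
  expect_equal(shifted$test, "paired t")
  expect_lt(shifted$p, 0.001)

  # contaminated-normal differences fail Shapiro-Wilk
  y <- rnorm(50)
  d <- c(rnorm(45, 0, 0.1), rnorm(5, 0, 30))
  heavy <- paired_compare(y, y + d)
  expect_equal(heavy$test, "wilcoxon signed-rank")
})
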