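test_that("baseline generation matches the Poisson count oracle", {
  cfg <- population_config(n_sua = 4, n_mua = 0, rate_pyr_hz = 10,
                           rate_in_hz = 10, rate_sd_log10 = 0,
                           duration_s = 600, seed = 11)
  gb <- generate_baseline(cfg)
  counts <- vapply(gb$set$units, function(u) length(u$timestamps_ms),
                   numeric(1))
  # Poisson(6000): 3 sigma band (refractory deletion removes ~2% at most)
  expect_true(all(abs(counts - 6000) < 3 * sqrt(6000) + 0.025 * 6000))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- population_config(n_sua = 6, n_mua = 2, duration_s = 60, seed = 21)
  expect_identical(generate_baseline(cfg), generate_baseline(cfg))
  gb <- generate_baseline(cfg)
  eff <- condition_effect()
  expect_identical(apply_condition(gb$set, eff, seed = 3),
                   apply_condition(gb$set, eff, seed = 3))
  expect_identical(generate_lfp(fs = 250, duration_s = 20, seed = 5),
                   generate_lfp(fs = 250, duration_s = 20, seed = 5))
})

test_that("every generated inter-spike interval respects the refractory period", {
  n <- 10
  C <- matrix(0.2, n, n); diag(C) <- 0
  cfg <- population_config(n_sua = n, n_mua = 0, duration_s = 120,
                           refractory_ms = 2, seed = 31)
  gb <- generate_baseline(cfg, coupling = C)
  tr <- apply_condition(gb$set, condition_effect(), seed = 32,
                        baseline_truth = gb$ground_truth)
  for (set in list(gb$set, tr$set)) {
    ok <- vapply(set$units, function(u)
      length(u$timestamps_ms) < 2 || min(diff(u$timestamps_ms)) >= 2,
      logical(1))
    expect_true(all(ok))
  }
})

test_that("invalid generator inputs are rejected", {
  expect_error(population_config(n_sua = 0), "n_sua")
  expect_error(population_config(duration_s = -1), "duration_s")
  expect_error(population_config(fraction_pyr = 1.2), "fraction_pyr")
  cfg <- population_config(n_sua = 3, n_mua = 0, duration_s = 10, seed = 1)
  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)  # asymmetric
  expect_error(generate_baseline(cfg, coupling = bad), "symmetric")
  bad2 <- matrix(0.5, 3, 3)  # nonzero diagonal
  expect_error(generate_baseline(cfg, coupling = bad2), "diagonal")
  expect_error(condition_effect(frac_decrease = 0.5, frac_increase = 0.5,
                                frac_unchanged = 0.2), "sum to 1")
})

test_that("thinning halves rates and identity leaves timestamps untouched", {
  cfg <- population_config(n_sua = 20, n_mua = 0, duration_s = 300, seed = 41)
  gb <- generate_baseline(cfg)
  half <- apply_condition(gb$set, condition_effect(
    frac_decrease = 1, frac_increase = 0, frac_unchanged = 0,
    decrease_scale = 0.5, burst_rate_per_min = 0), seed = 42)
  r0 <- unit_rates(gb$set); r1 <- unit_rates(half$set)
  ratio <- r1 / r0
  se <- 3 / sqrt(pmax(r0, 0.5) * 300)   # 3 SE of a binomial-thinned rate
  expect_true(all(abs(ratio - 0.5) < pmax(3 * se, 0.1)))

  ident <- apply_condition(gb$set, condition_effect(
    frac_decrease = 0, frac_increase = 0, frac_unchanged = 1,
    burst_rate_per_min = 0), seed = 43)
  expect_identical(lapply(ident$set$units, `[[`, "timestamps_ms"),
                   lapply(gb$set$units, `[[`, "timestamps_ms"))
})

test_that("assigned rate-change directions are recovered from the data", {
  cfg <- population_config(n_sua = 56, n_mua = 4, duration_s = 600, seed = 51)
  gb <- generate_baseline(cfg)
  tr <- apply_condition(gb$set, condition_effect(), seed = 52,
                        baseline_truth = gb$ground_truth)
  res <- classify_rate_change(unit_rates(gb$set), unit_rates(tr$set))
  agree <- mean(res$direction == tr$ground_truth$true_change)
  expect_gte(agree, 0.9)
  expect_equal(sum(res$proportions), 1)
})

test_that("coupling injections share near-coincident spikes at the planted strength", {
  n <- 6
  C <- matrix(0, n, n); C[1, 2] <- C[2, 1] <- 0.3
  cfg <- population_config(n_sua = n, n_mua = 0, rate_pyr_hz = 5,
                           rate_in_hz = 5, rate_sd_log10 = 0,
                           duration_s = 600, seed = 61)
  gb <- generate_baseline(cfg, coupling = C)
  t1 <- gb$set$units[[1]]$timestamps_ms
  t2 <- gb$set$units[[2]]$timestamps_ms
  # coincidences within +/-2 ms should be ~ injected count >> chance level
  hits <- sum(vapply(t1, function(t) any(abs(t2 - t) <= 2), logical(1)))
  expected_inj <- 0.3 * 5 * 600
  chance <- length(t1) * length(t2) * 4 / 6e5
  expect_gt(hits, chance + 0.5 * expected_inj)
})

test_that("synthesized LFP matches requested band weights", {
  w <- c(delta = 0.2, theta = 0.5, beta = 0.1, gamma = 0.2)
  tr <- generate_lfp(w, fs = 500, duration_s = 120, seed = 71)
  bp <- band_power(tr, segment_s = 60)
  shares <- bp$band_power / sum(bp$band_power)
  expect_true(all(abs(shares - w) < 0.1 * pmax(w, 0.1) + 0.02))

  z <- generate_lfp(c(delta = 0, theta = 0, beta = 0, gamma = 0),
                    fs = 500, duration_s = 60, seed = 1)
  expect_true(all(z$samples == 0))
  expect_error(generate_lfp(w, fs = 500, duration_s = 2), "duration")
  expect_error(generate_lfp(w, fs = 150), "fs")
})
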