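# Synthetic paired-condition MEA recordings with known ground truth.
#
# The generative model is deliberately simple: homogeneous Poisson background
# activity with refractory deletion, pairwise coupling as common-parent
# coincidence injection (<= 2 ms relative jitter), condition effects as
# thinning / superposition, and population-synchrony epochs as transient rate
# multiplications. This is the weakest process that still carries the
# statistical structure the downstream analysis assumes (tight near-zero-lag
# synchrony, two waveform/rate cell classes, majority rate decreases,
# raster-sum burst peaks), so parameter-recovery tests are meaningful.

#' Population configuration for the synthetic generator
#'
#' Defaults emulate a CA1 slice recording: a few tens of single units per
#' slice plus a handful of multi-unit channels, 10-minute duration, a 2-ms
#' refractory period, and two cell classes — putative pyramidal neurons
#' (broad waveform, trough-to-peak around 0.76 ms, lower rate) and putative
#' interneurons (narrow waveform around 0.22 ms, higher rate).
#'
#' @param n_sua number of single units (> 0).
#' @param n_mua number of multi-unit channels (each a superposition of 2-4
#'   hidden trains; excluded from cell typing).
#' @param fraction_pyr proportion of SUA units that are pyramidal-like.
#' @param rate_pyr_hz,rate_in_hz class mean firing rates (Hz); individual
#'   unit rates are log-normal around these with spread `rate_sd_log10`.
#' @param ttp_pyr_ms,ttp_in_ms class mean trough-to-peak widths (ms).
#' @param ttp_sd_ms Gaussian spread of the waveform width within a class.
#' @param rate_sd_log10 spread of log10 unit rates within a class.
#' @param duration_s recording length in seconds.
#' @param refractory_ms minimum inter-spike interval (ms).
#' @param seed integer seed; fixes all randomness in [generate_baseline()].
#' @return a list of class `PopulationConfig`.
#' @export
population_config <- function(n_sua = 60, n_mua = 6, fraction_pyr = 0.789,
                              rate_pyr_hz = 3.2, rate_in_hz = 6.9,
                              ttp_pyr_ms = 0.76, ttp_in_ms = 0.22,
                              ttp_sd_ms = 0.10, rate_sd_log10 = 0.4,
                              duration_s = 600, refractory_ms = 2,
                              seed = 1L) {
  .assert(n_sua > 0, "n_sua must be > 0")
  .assert(n_mua >= 0, "n_mua must be >= 0")
  .assert(fraction_pyr >= 0 && fraction_pyr <= 1,
          "fraction_pyr must be in [0, 1]")
  .assert(duration_s > 0, "duration_s must be > 0")
  .assert(refractory_ms > 0, "refractory_ms must be > 0")
  .assert(rate_pyr_hz > 0 && rate_in_hz > 0, "rates must be > 0")
  structure(as.list(environment()), class = "PopulationConfig")
}

#' Condition-effect configuration
#'
#' Describes how a treated condition is derived from a baseline recording:
#' proportions of units whose rate decreases, increases or stays unchanged
#' (defaults follow the observed majority-decrease pattern, 62/37/1 percent),
#' multiplicative rate factors, population-synchrony epochs, and optional
#' additional pairwise coupling (e.g. hub creation).
#'
#' @param frac_decrease,frac_increase,frac_unchanged proportions summing to 1.
#' @param decrease_scale,increase_scale multiplicative rate factors (> 0).
#' @param burst_rate_per_min rate of injected synchrony epochs (per minute).
#' @param burst_participation proportion of units co-activated in an epoch.
#' @param burst_rate_mult rate multiplication applied inside an epoch.
#' @param burst_len_range_ms epoch duration range (ms).
#' @param coupling_delta optional symmetric matrix of additional coupling
#'   strengths in `[0, 1]` (zero diagonal) applied on top of the baseline
#'   coupling, e.g. from [signature_coupling_delta()] or
#'   [hub_coupling_delta()].
#' @param comp_free_frac fraction of a unit's rate that injected
#'   coincidences may add without compensation (default 0.25); injected load
#'   beyond it is offset by thinning the unit's existing spikes. This
#'   implements hypersynchrony: overall rates barely rise while the
#'   proportion of synchronous spikes does.
#' @param load_cap_frac hard cap on a unit's injected load as a fraction of
#'   its rate (default 0.5); coupling rows are rescaled above it.
#' @return a list of class `ConditionEffect`.
#' @export
condition_effect <- function(frac_decrease = 0.62, frac_increase = 0.37,
                             frac_unchanged = 0.01,
                             decrease_scale = 0.4, increase_scale = 1.5,
                             burst_rate_per_min = 1, burst_participation = 0.5,
                             burst_rate_mult = 8,
                             burst_len_range_ms = c(100, 500),
                             coupling_delta = NULL, comp_free_frac = 0.25,
                             load_cap_frac = 0.5) {
  .assert(abs(frac_decrease + frac_increase + frac_unchanged - 1) <= 1e-9,
          "fractions must sum to 1")
  .assert(min(frac_decrease, frac_increase, frac_unchanged) >= 0,
          "fractions must be non-negative")
  .assert(decrease_scale > 0 && increase_scale > 0, "scales must be > 0")
  .assert(burst_participation >= 0 && burst_participation <= 1,
          "burst_participation must be in [0, 1]")
  structure(as.list(environment()), class = "ConditionEffect")
}

# Delete spikes violating the refractory period: scan once, keeping a spike
# only if it falls >= refractory_ms after the last kept spike.
.enforce_refractory <- function(ts, refractory_ms) {
  n <- length(ts)
  if (n < 2) return(ts)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- ts[1]
  for (i in 2:n) {
    if (ts[i] - last >= refractory_ms) {
      keep[i] <- TRUE
      last <- ts[i]
    }
  }
  ts[keep]
}

.rpoisson_train_ms <- function(rate_hz, duration_s) {
  n <- stats::rpois(1, rate_hz * duration_s)
  sort(stats::runif(n, 0, duration_s * 1000))
}

.validate_coupling <- function(coupling, n) {
  if (is.null(coupling)) return(matrix(0, n, n))
  coupling <- .check_square_symmetric(coupling, what = "coupling matrix")
  .assert(nrow(coupling) == n, "coupling matrix must be %d x %d", n, n)
  .assert(all(diag(coupling) == 0), "coupling matrix must have zero diagonal")
  .assert(min(coupling) >= 0 && max(coupling) <= 1,
          "coupling entries must lie in [0, 1]")
  coupling
}

# Inject common-parent coincidences: for each coupled pair, a latent parent
# Poisson train at rate c * min(rate_i, rate_j) contributes one spike to each
# member, independently jittered by <= 1 ms (relative jitter <= 2 ms).
# Returns the augmented trains plus per-pair injection records (child times),
# which apply_condition() uses to scale synchrony at the parent level.
.inject_coincidences <- function(spikes, coupling, rates_hz, duration_s) {
  idx <- which(upper.tri(coupling) & coupling > 0, arr.ind = TRUE)
  injections <- list()
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      prate <- coupling[i, j] * min(rates_hz[i], rates_hz[j])
      parents <- .rpoisson_train_ms(prate, duration_s)
      if (length(parents)) {
        t_i <- parents + stats::runif(length(parents), -1, 1)
        t_j <- parents + stats::runif(length(parents), -1, 1)
        spikes[[i]] <- c(spikes[[i]], t_i)
        spikes[[j]] <- c(spikes[[j]], t_j)
        injections[[length(injections) + 1]] <-
          list(i = i, j = j, strength = coupling[i, j], t_i = t_i, t_j = t_j)
      }
    }
  }
  list(spikes = spikes, injections = injections)
}

#' Generate a baseline synthetic recording
#'
#' Draws per-unit spike trains over `[0, duration_s)`: homogeneous Poisson
#' background with refractory deletion, two (trough-to-peak, rate) Gaussian
#' cell classes, MUA channels as superpositions of 2-4 hidden trains, and
#' pairwise coupling planted as common-parent coincidence injection with at
#' most 2 ms relative jitter. Each unit's background rate is reduced by its
#' expected injected load so realized rates concentrate near the class means.
#'
#' @param config a [population_config()].
#' @param coupling optional symmetric n x n matrix (n = `n_sua + n_mua`) of
#'   coupling strengths in `[0, 1]`, zero diagonal. `NULL` means uncoupled.
#' @return a list with elements `set` (a [spike_train_set()]) and
#'   `ground_truth` (coupling matrix, per-unit true class labels, target
#'   rates).
#' @export
generate_baseline <- function(config, coupling = NULL) {
  .assert(inherits(config, "PopulationConfig"), "config must be a PopulationConfig")
  n <- config$n_sua + config$n_mua
  coupling <- .validate_coupling(coupling, n)
  .with_seed(config$seed, {
    n_pyr <- round(config$fraction_pyr * config$n_sua)
    labels <- c(rep("PPyrN", n_pyr), rep("PIN", config$n_sua - n_pyr),
                rep("MUA", config$n_mua))
    class_rate <- ifelse(labels == "PIN", config$rate_in_hz, config$rate_pyr_hz)
    class_ttp <- ifelse(labels == "PIN", config$ttp_in_ms, config$ttp_pyr_ms)
    target <- 10 ^ (log10(class_rate) +
                      stats::rnorm(n, 0, config$rate_sd_log10))
    ttp <- pmax(0.05, stats::rnorm(n, class_ttp, config$ttp_sd_ms))
    # MUA channels: sum of several hidden trains, so higher aggregate rate
    n_hidden <- rep(1L, n)
    if (config$n_mua > 0) {
      mua_i <- which(labels == "MUA")
      n_hidden[mua_i] <- sample(2:4, length(mua_i), replace = TRUE)
      target[mua_i] <- target[mua_i] * n_hidden[mua_i]
    }
    load <- rowSums(coupling * outer(target, target, pmin)) / pmax(target, 1e-12)
    background <- pmax(target * (1 - pmin(load, 0.95)), 0.05 * target)
    spikes <- lapply(seq_len(n), function(i) {
      if (n_hidden[i] > 1) {
        sort(unlist(lapply(seq_len(n_hidden[i]), function(k)
          .rpoisson_train_ms(background[i] / n_hidden[i], config$duration_s))))
      } else {
        .rpoisson_train_ms(background[i], config$duration_s)
      }
    })
    inj <- .inject_coincidences(spikes, coupling, target, config$duration_s)
    spikes <- inj$spikes
    span <- config$duration_s * 1000
    units <- lapply(seq_len(n), function(i) {
      ts <- sort(spikes[[i]])
      ts <- ts[ts >= 0 & ts < span]
      ts <- .enforce_refractory(ts, config$refractory_ms)
      u <- list(unit_id = sprintf("u%03d", i),
                kind = if (labels[i] == "MUA") "MUA" else "SUA",
                timestamps_ms = ts)
      if (labels[i] != "MUA") u$trough_to_peak_ms <- ttp[i]
      u
    })
    set <- spike_train_set(units, slice_id = "synthetic", condition = "baseline",
                           duration_ms = span)
    list(set = set,
         ground_truth = list(coupling = coupling, true_labels = labels,
                             target_rates_hz = target,
                             trough_to_peak_ms = ttp,
                             injections = inj$injections))
  })
}

#' Derive a treated condition from a baseline recording
#'
#' Applies the condition effect unit by unit: rates are decreased by random
#' thinning, increased by superposition of an independent Poisson train, or
#' left untouched (unchanged units keep their exact timestamps). Optional
#' additional coupling (`coupling_delta`) is planted by coincidence injection
#' with rate compensation, and population-synchrony epochs of 100-500 ms are
#' injected at `burst_rate_per_min`, inside which participating units fire at
#' `burst_rate_mult` times their rate.
#'
#' When `baseline_truth` (the ground truth returned by
#' [generate_baseline()]) is supplied, rate scaling distinguishes background
#' from planted-coincidence spikes: background spikes are thinned or
#' superposed per unit, while each coupled pair's shared parent events are
#' kept or dropped jointly with probability `sqrt(s_i * s_j)` (the geometric
#' mean of the two units' rate factors), or topped up when that factor
#' exceeds 1. Because the correlogram normalization is also the geometric
#' mean of the spike counts, planted correlation weights are then invariant
#' under rate changes — synchrony rides on shared drive rather than being
#' destroyed by independent spike deletion. Without `baseline_truth` all
#' spikes are thinned blindly, which attenuates planted weights by
#' `sqrt(s_i * s_j)`.
#'
#' @param base a [spike_train_set()] (the baseline condition).
#' @param effect a [condition_effect()].
#' @param seed integer seed fixing all randomness of the transformation.
#' @param baseline_truth optional `ground_truth` from [generate_baseline()]
#'   enabling parent-level synchrony scaling.
#' @return a list with elements `set` (treated `SpikeTrainSet`) and
#'   `ground_truth` (per-unit `true_change` direction, epoch table, the
#'   coupling delta applied).
#' @export
apply_condition <- function(base, effect, seed = 1L, baseline_truth = NULL) {
  .assert(inherits(base, "SpikeTrainSet"), "base must be a SpikeTrainSet")
  .assert(inherits(effect, "ConditionEffect"), "effect must be a ConditionEffect")
  n <- length(base$units)
  .assert(n > 0, "empty input set")
  span_ms <- base$duration_ms
  duration_s <- span_ms / 1000
  if (!is.null(effect$coupling_delta)) {
    .validate_coupling(effect$coupling_delta, n)
  }
  .with_seed(seed, {
    # largest-remainder apportionment of direction counts, then random assignment
    fr <- c(decrease = effect$frac_decrease, increase = effect$frac_increase,
            unchanged = effect$frac_unchanged)
    counts <- floor(fr * n)
    rem <- fr * n - counts
    short <- n - sum(counts)
    if (short > 0) {
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
    }
    direction <- sample(rep(names(counts), counts))
    emp_rate <- vapply(base$units, function(u)
      length(u$timestamps_ms) / duration_s, numeric(1))
    spikes <- lapply(base$units, `[[`, "timestamps_ms")
    touched <- rep(FALSE, n)
    s <- c(decrease = effect$decrease_scale, increase = effect$increase_scale,
           unchanged = 1)[direction]
    injections <- if (!is.null(baseline_truth)) baseline_truth$injections
                  else NULL
    coupled_times <- vector("list", n)
    if (!is.null(injections)) {
      for (rec in injections) {
        coupled_times[[rec$i]] <- c(coupled_times[[rec$i]], rec$t_i)
        coupled_times[[rec$j]] <- c(coupled_times[[rec$j]], rec$t_j)
      }
    }
    # per-unit background thinning / superposition
    for (i in seq_len(n)) {
      if (s[i] == 1) next
      is_bg <- if (is.null(coupled_times[[i]])) {
        rep(TRUE, length(spikes[[i]]))
      } else !(spikes[[i]] %in% coupled_times[[i]])
      if (s[i] < 1) {
        drop <- is_bg & stats::runif(length(spikes[[i]])) >= s[i]
        spikes[[i]] <- spikes[[i]][!drop]
      } else {
        bg_rate <- sum(is_bg) / duration_s
        spikes[[i]] <- c(spikes[[i]],
                         .rpoisson_train_ms(bg_rate * (s[i] - 1), duration_s))
      }
      touched[i] <- TRUE
    }
    # parent-level scaling of planted coincidences by sqrt(s_i * s_j)
    if (!is.null(injections)) {
      for (rec in injections) {
        f <- sqrt(s[rec$i] * s[rec$j])
        if (f == 1) next
        touched[rec$i] <- touched[rec$j] <- TRUE
        if (f < 1) {
          dropk <- stats::runif(length(rec$t_i)) >= f
          if (any(dropk)) {
            spikes[[rec$i]] <- spikes[[rec$i]][
              !(spikes[[rec$i]] %in% rec$t_i[dropk])]
            spikes[[rec$j]] <- spikes[[rec$j]][
              !(spikes[[rec$j]] %in% rec$t_j[dropk])]
          }
        } else {
          prate <- (f - 1) * rec$strength * min(emp_rate[rec$i], emp_rate[rec$j])
          parents <- .rpoisson_train_ms(prate, duration_s)
          if (length(parents)) {
            spikes[[rec$i]] <- c(spikes[[rec$i]],
                                 parents + stats::runif(length(parents), -1, 1))
            spikes[[rec$j]] <- c(spikes[[rec$j]],
                                 parents + stats::runif(length(parents), -1, 1))
          }
        }
      }
    }
    new_rate <- vapply(spikes, length, numeric(1)) / duration_s
    if (!is.null(effect$coupling_delta)) {
      # cap injected load, then compensate only the load beyond the free
      # allowance by thinning existing spikes: synchrony is added mostly by
      # converting independent spikes into near-coincident ones
      delta <- .cap_coupling_load(effect$coupling_delta, new_rate,
                                  frac = effect$load_cap_frac)
      effect$coupling_delta <- delta
      load <- rowSums(delta * outer(new_rate, new_rate, pmin))
      excess <- pmax(0, load - effect$comp_free_frac * new_rate)
      for (i in seq_len(n)) {
        if (excess[i] > 0 && length(spikes[[i]])) {
          keep_p <- max(0, 1 - excess[i] / pmax(new_rate[i], 1e-12))
          spikes[[i]] <- spikes[[i]][stats::runif(length(spikes[[i]])) < keep_p]
          touched[i] <- TRUE
        }
      }
      spikes <- .inject_coincidences(spikes, effect$coupling_delta,
                                     new_rate, duration_s)$spikes
      touched <- touched | (rowSums(effect$coupling_delta > 0) > 0)
    }
    # population-synchrony epochs: transient rate multiplication in a window;
    # the count is deterministic (rate * duration) so it is recoverable up to
    # detection error, only the placement is random
    n_epochs <- round(effect$burst_rate_per_min * duration_s / 60)
    epochs <- data.frame(start_ms = numeric(0), len_ms = numeric(0))
    if (n_epochs > 0 && effect$burst_participation > 0 &&
        effect$burst_rate_mult > 1) {
      starts <- sort(stats::runif(n_epochs, 0, span_ms))
      lens <- stats::runif(n_epochs, effect$burst_len_range_ms[1],
                           effect$burst_len_range_ms[2])
      epochs <- data.frame(start_ms = starts, len_ms = lens)
      for (e in seq_len(n_epochs)) {
        part <- which(stats::runif(n) < effect$burst_participation)
        for (i in part) {
          extra_rate <- new_rate[i] * (effect$burst_rate_mult - 1)
          n_extra <- stats::rpois(1, extra_rate * lens[e] / 1000)
          if (n_extra > 0) {
            spikes[[i]] <- c(spikes[[i]],
                             stats::runif(n_extra, starts[e],
                                          min(starts[e] + lens[e], span_ms)))
            touched[i] <- TRUE
          }
        }
      }
    }
    refr <- .infer_refractory(base)
    units <- lapply(seq_len(n), function(i) {
      u <- base$units[[i]]
      ts <- sort(spikes[[i]])
      ts <- ts[ts >= 0 & ts < span_ms]
      if (touched[i]) ts <- .enforce_refractory(ts, refr)
      u$timestamps_ms <- ts
      u
    })
    set <- spike_train_set(units, slice_id = base$slice_id,
                           condition = "treated", duration_ms = span_ms)
    list(set = set,
         ground_truth = list(true_change = direction, epochs = epochs,
                             coupling_delta = effect$coupling_delta))
  })
}

# The treated set must respect the same refractory period as its baseline;
# default to the conventional 2 ms used at sorting time.
.infer_refractory <- function(set) {
  attr(set, "refractory_ms") %||% 2
}

# Symmetrically rescale coupling rows whose total injected load would exceed
# frac * rate: the pair scale is the minimum of its endpoints' scales, so
# symmetry is preserved and no unit is overdriven by injection.
.cap_coupling_load <- function(C, rates_hz, frac = 0.6) {
  load <- rowSums(C * outer(rates_hz, rates_hz, pmin))
  sc <- ifelse(load > frac * pmax(rates_hz, 1e-12),
               frac * rates_hz / pmax(load, 1e-12), 1)
  C * outer(sc, sc, pmin)
}

#' Block-community coupling matrix
#'
#' Builds a symmetric coupling matrix with community structure: units are
#' split into `n_comm` contiguous communities; within-community pairs are
#' coupled with probability `p_within` at a strength drawn uniformly from
#' `strength_range`; between-community pairs with probability `p_between`.
#'
#' @param n number of units.
#' @param n_comm number of communities.
#' @param p_within,p_between coupling probabilities.
#' @param strength_range coupling strength range in `[0, 1]`.
#' @param seed integer seed.
#' @return a symmetric n x n matrix with zero diagonal.
#' @export
community_coupling <- function(n, n_comm = 4, p_within = 0.55, p_between = 0.01,
                               strength_range = c(0.12, 0.2), seed = 1L) {
  .with_seed(seed, {
    comm <- sort(rep_len(seq_len(n_comm), n))
    C <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p <- if (comm[i] == comm[j]) p_within else p_between
      if (stats::runif(1) < p) {
        C[i, j] <- C[j, i] <- stats::runif(1, strength_range[1], strength_range[2])
      }
    }
    C
  })
}

#' Treatment-signature coupling delta
#'
#' Builds the coupling change applied in the treated condition of the
#' simulated study: a mild global potentiation of every existing coupling,
#' a stronger potentiation inside the `n_core` communities that already
#' carry the largest total coupling (synchrony reorganizes around the
#' dominant assemblies), and hub units inside those cores that attach
#' densely to their own community and sparsely elsewhere (emergence of
#' hyperconnected nodes). Communities follow the same contiguous-block
#' convention as [community_coupling()].
#'
#' @param n number of units.
#' @param base_coupling the baseline coupling matrix being perturbed.
#' @param seed integer seed.
#' @param n_comm number of communities (must match the baseline layout).
#' @param n_core number of core communities (those with the largest total
#'   baseline coupling).
#' @param global_pot,core_pot potentiation added to existing couplings
#'   outside/inside core communities.
#' @param n_hubs hub units drawn evenly from the core communities.
#' @param hub_strength hub coupling strength.
#' @param p_hub_within,p_hub_between hub attachment probabilities inside and
#'   outside the hub's community.
#' @return a symmetric n x n coupling-delta matrix with zero diagonal.
#' @export
signature_coupling_delta <- function(n, base_coupling, seed = 1L, n_comm = 4,
                                     n_core = 2, global_pot = 0.03,
                                     core_pot = 0.25, n_hubs = 4,
                                     hub_strength = 0.22, p_hub_within = 0.8,
                                     p_hub_between = 0.05) {
  base_coupling <- .validate_coupling(base_coupling, n)
  .with_seed(seed, {
    comm <- sort(rep_len(seq_len(n_comm), n))
    mass <- vapply(seq_len(n_comm), function(c_)
      sum(base_coupling[comm == c_, comm == c_]), numeric(1))
    cores <- order(mass, decreasing = TRUE)[seq_len(n_core)]
    in_core <- outer(comm, comm, function(a, b) a == b & a %in% cores)
    D <- (base_coupling > 0) * ifelse(in_core, core_pot, global_pot)
    hubs <- unlist(lapply(cores, function(c_)
      sample(which(comm == c_), max(1, round(n_hubs / n_core)))))
    for (h in hubs) {
      p <- ifelse(comm == comm[h], p_hub_within, p_hub_between)
      targets <- setdiff(which(stats::runif(n) < p), h)
      D[h, targets] <- D[targets, h] <- pmax(D[h, targets], hub_strength)
    }
    diag(D) <- 0
    attr(D, "hubs") <- hubs
    D
  })
}

#' Hub-creation coupling delta
#'
#' Selects `n_hubs` units and couples each to a random `p_attach` fraction of
#' all other units at the given strength — the "hyperconnected node" scenario.
#'
#' @param n number of units.
#' @param n_hubs number of hub units.
#' @param p_attach probability that a hub couples to any given other unit.
#' @param strength coupling strength in `[0, 1]`.
#' @param seed integer seed.
#' @return a symmetric n x n matrix with zero diagonal, plus attribute
#'   `hubs` giving the hub indices.
#' @export
hub_coupling_delta <- function(n, n_hubs = 3, p_attach = 0.5, strength = 0.12,
                               seed = 1L) {
  .with_seed(seed, {
    hubs <- sample(n, n_hubs)
    D <- matrix(0, n, n)
    for (h in hubs) {
      targets <- setdiff(which(stats::runif(n) < p_attach), h)
      D[h, targets] <- D[targets, h] <- strength
    }
    attr(D, "hubs") <- hubs
    D
  })
}

#' Synthesize an LFP trace with a prescribed band-power profile
#'
#' Shapes Gaussian white noise in the frequency domain so that the relative
#' power in the Delta (0.5-4 Hz), Theta (4-10 Hz), Beta (10-25 Hz) and Gamma
#' (25-50 Hz) bands matches the requested weights; frequencies outside the
#' four bands carry no power.
#'
#' @param band_targets named numeric vector of non-negative relative weights
#'   with names `delta`, `theta`, `beta`, `gamma`.
#' @param fs sample rate in Hz (>= 200 so the Gamma band is resolvable).
#' @param duration_s trace length in seconds (>= 4, two cycles at 0.5 Hz).
#' @param seed integer seed.
#' @return an [lfp_trace()].
#' @export
generate_lfp <- function(band_targets = c(delta = 1, theta = 1, beta = 1,
                                          gamma = 1),
                         fs = 500, duration_s = 120, seed = 1L) {
  .assert(fs >= 200, "fs must be >= 200 Hz")
  .assert(duration_s >= 2 / 0.5, "duration too short: need >= 2 cycles at 0.5 Hz")
  .assert(all(band_targets >= 0), "band weights must be >= 0")
  .assert(all(c("delta", "theta", "beta", "gamma") %in% names(band_targets)),
          "band_targets must name delta, theta, beta, gamma")
  bands <- lfp_bands()
  n <- as.integer(round(fs * duration_s))
  if (all(band_targets == 0)) {
    return(lfp_trace(numeric(n), fs))
  }
  .with_seed(seed, {
    z <- stats::rnorm(n)
    Z <- stats::fft(z)
    freq <- seq(0, n - 1) / n * fs
    freq <- pmin(freq, fs - freq)   # two-sided spectrum folds at Nyquist
    gain <- numeric(n)
    for (b in names(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      sel <- freq >= lo & (if (b == "gamma") freq <= hi else freq < hi)
      bw <- hi - lo
      gain[sel] <- sqrt(band_targets[[b]] / bw)
    }
    x <- Re(stats::fft(Z * gain, inverse = TRUE)) / n
    lfp_trace(x, fs)
  })
}
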