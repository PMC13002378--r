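# Per-unit activity statistics, population-burst detection, cell typing,
# rate-change classification, LFP band power and the paired statistics used
# throughout the study-level comparisons.

#' Canonical LFP frequency bands
#'
#' Delta 0.5-4, Theta 4-10, Beta 10-25, Gamma 25-50 Hz. Intervals are
#' half-open `[lo, hi)` except Gamma, which is closed at 50 Hz; the 0-0.5 Hz
#' remainder belongs to the broadband total only.
#'
#' @return named list of `c(lo, hi)` pairs in Hz.
#' @export
lfp_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 10), beta = c(10, 25), gamma = c(25, 50))
}

#' Per-unit firing rates
#'
#' Rate = spike count inside the window divided by window length in seconds.
#'
#' @param set a [spike_train_set()].
#' @param window `c(start_ms, end_ms)`; defaults to the full recording span.
#' @return named numeric vector of rates (Hz), one per unit.
#' @export
unit_rates <- function(set, window = NULL) {
  window <- window %||% c(0, set$duration_ms)
  .assert(diff(window) > 0, "window must have positive length")
  len_s <- diff(window) / 1000
  r <- vapply(set$units, function(u) {
    sum(u$timestamps_ms >= window[1] & u$timestamps_ms < window[2]) / len_s
  }, numeric(1))
  stats::setNames(r, unit_ids(set))
}

#' Detect population bursts on the summed raster
#'
#' Re-aggregates a 1-ms binary raster into coarse bins (default 500 ms),
#' summing occupied 1-ms bins over all units ("popsum"). The noise level is
#' the root-mean-square of the mean-subtracted popsum over the whole record;
#' burst events are local maxima whose height exceeds the popsum mean by at
#' least `k_sd` times that RMS.
#'
#' @param raster a [bin_raster()] at 1-ms resolution.
#' @param bin_ms coarse bin width in ms (default 500).
#' @param k_sd threshold multiplier (default 5).
#' @return an object of class `BurstResult`: list with `bin_ms`, `popsum`,
#'   `noise_rms`, `threshold` (absolute popsum height that must be reached),
#'   `events` (data frame: bin, time_ms, height), `count`,
#'   `count_per_min`, and `mean_height` of the detected events (NA if none).
#' @export
detect_bursts <- function(raster, bin_ms = 500, k_sd = 5) {
  .assert(inherits(raster, "Raster"), "raster must be a Raster")
  .assert(all(raster$occupancy %in% c(0L, 1L)), "raster must be binary")
  factor <- bin_ms / raster$bin_ms
  .assert(factor >= 1 && abs(factor - round(factor)) < 1e-9,
          "bin_ms must be a multiple of the raster resolution")
  n_coarse <- floor(raster$bins / factor)
  .assert(n_coarse >= 1, "recording shorter than one %g-ms bin", bin_ms)
  per_unit <- colSums(raster$occupancy)   # spikes (occupied 1-ms bins) per fine bin
  idx <- rep(seq_len(n_coarse), each = factor)
  popsum <- as.numeric(tapply(per_unit[seq_along(idx)], idx, sum))
  mu <- mean(popsum)
  noise_rms <- sqrt(mean((popsum - mu)^2))
  threshold <- mu + k_sd * noise_rms
  # a constant popsum has no noise and no bursts
  is_peak <- if (noise_rms > 0) popsum >= threshold else rep(FALSE, n_coarse)
  if (n_coarse > 1) {
    left <- c(-Inf, popsum[-n_coarse])
    right <- c(popsum[-1], -Inf)
    is_peak <- is_peak & popsum >= left & popsum >= right &
      (popsum > left | popsum > right)   # strict on at least one side
  }
  ev <- which(is_peak)
  events <- data.frame(bin = ev,
                       time_ms = raster$t0_ms + (ev - 0.5) * bin_ms,
                       height = popsum[ev])
  minutes <- n_coarse * bin_ms / 60000
  structure(list(bin_ms = bin_ms, popsum = popsum, noise_rms = noise_rms,
                 threshold = threshold, events = events,
                 count = nrow(events), count_per_min = nrow(events) / minutes,
                 mean_height = if (nrow(events)) mean(events$height) else NA_real_),
            class = "BurstResult")
}

#' Classify per-unit rate changes between conditions
#'
#' A unit is `unchanged` when `|treated - baseline| / max(baseline, eps)` is
#' below `rel_tol`; otherwise the sign of the difference assigns `increase`
#' or `decrease`. Units present in only one condition are excluded with a
#' warning.
#'
#' @param baseline,treated named rate vectors (Hz) from [unit_rates()].
#' @param rel_tol relative tolerance for "unchanged" (default 0.01; near-exact
#'   equality, reflecting that genuinely unchanged units are rare).
#' @param eps floor protecting the relative change of silent units.
#' @return list with `direction` (named character vector) and `proportions`
#'   (named numeric: increase/decrease/unchanged, summing to 1).
#' @export
classify_rate_change <- function(baseline, treated, rel_tol = 0.01,
                                 eps = 1e-9) {
  common <- intersect(names(baseline), names(treated))
  dropped <- setdiff(union(names(baseline), names(treated)), common)
  if (length(dropped)) {
    warning(sprintf("%d unit(s) present in only one condition were excluded",
                    length(dropped)), call. = FALSE)
  }
  .assert(length(common) > 0, "no units common to both conditions")
  b <- baseline[common]; a <- treated[common]
  rel <- abs(a - b) / pmax(b, eps)
  dir <- ifelse(rel < rel_tol, "unchanged",
                ifelse(a > b, "increase", "decrease"))
  names(dir) <- common
  prop <- c(increase = mean(dir == "increase"),
            decrease = mean(dir == "decrease"),
            unchanged = mean(dir == "unchanged"))
  list(direction = dir, proportions = prop)
}

#' K-means classification of putative cell types
#'
#' Clusters single units in the (trough-to-peak width, firing rate) plane:
#' the rate is log10-transformed, both features are z-scored, and k-means
#' (k = 2, multiple restarts, fixed seed) partitions the units. The cluster
#' with the larger mean trough-to-peak width is labelled `PPyrN` (putative
#' pyramidal neurons), the other `PIN` (putative interneurons). Per-cluster
#' medians, Mann-Whitney comparisons and Cohen's d are reported for both
#' features.
#'
#' @param features data frame with columns `unit_id`, `trough_to_peak_ms`,
#'   `rate_hz` (SUA units only).
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @param restarts number of random restarts (default 50).
#' @return list with `labels` (named character vector, `PPyrN`/`PIN`),
#'   `proportions`, `cluster_stats` (per-class medians), and `tests`
#'   (Mann-Whitney p and Cohen's d for each feature).
#' @export
classify_cell_types <- function(features, k = 2, seed = 1L, restarts = 50) {
  need <- c("unit_id", "trough_to_peak_ms", "rate_hz")
  .assert(all(need %in% names(features)),
          "features must have columns %s", paste(need, collapse = ", "))
  features <- features[stats::complete.cases(features[, need]), ]
  .assert(nrow(features) >= 2 * k, "need at least %d units with features", 2 * k)
  X <- cbind(ttp = features$trough_to_peak_ms,
             lograte = log10(pmax(features$rate_hz, 1e-3)))
  sds <- apply(X, 2, stats::sd)
  .assert(all(sds > 0), "degenerate clustering: a feature has zero variance")
  Z <- scale(X)
  km <- .with_seed(seed, stats::kmeans(Z, centers = k, nstart = restarts))
  # anchor labels: the broader-waveform cluster is pyramidal-like
  mean_ttp <- tapply(X[, "ttp"], km$cluster, mean)
  pyr_cluster <- as.integer(names(which.max(mean_ttp)))
  labels <- ifelse(km$cluster == pyr_cluster, "PPyrN", "PIN")
  names(labels) <- features$unit_id
  grp <- split(seq_len(nrow(X)), labels)
  tests <- lapply(c(ttp = "ttp", lograte = "lograte"), function(f) {
    x <- X[grp$PPyrN, f]; y <- X[grp$PIN, f]
    list(mw_p = stats::wilcox.test(x, y, exact = FALSE)$p.value,
         cohens_d = cohens_d_stat(x, y))
  })
  cluster_stats <- do.call(rbind, lapply(names(grp), function(g) {
    data.frame(cell_class = g, n = length(grp[[g]]),
               median_ttp_ms = stats::median(X[grp[[g]], "ttp"]),
               median_rate_hz = stats::median(features$rate_hz[grp[[g]]]),
               median_log10_rate = stats::median(X[grp[[g]], "lograte"]))
  }))
  list(labels = labels,
       proportions = c(PPyrN = mean(labels == "PPyrN"),
                       PIN = mean(labels == "PIN")),
       cluster_stats = cluster_stats, tests = tests)
}

#' Association between cell class and rate-change direction
#'
#' Pearson chi-square (no continuity correction by default) on a contingency
#' table of counts, with Fisher's exact test as an option; warns when any
#' expected cell count falls below 1.
#'
#' @param tab contingency table (matrix of non-negative integers), e.g.
#'   cell class x change direction with the unchanged column excluded.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @param exact also run Fisher's exact test (default `FALSE`).
#' @return list with `chisq`, `df`, `p`, and optionally `fisher_p`.
#' @export
association_stats <- function(tab, correct = FALSE, exact = FALSE) {
  tab <- as.matrix(tab)
  .assert(all(tab >= 0) && all(tab == round(tab)),
          "table must contain non-negative integer counts")
  .assert(nrow(tab) >= 2 && ncol(tab) >= 2, "table must be at least 2 x 2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count < 1: consider the exact test", call. = FALSE)
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out <- list(chisq = unname(ch$statistic), df = unname(ch$parameter),
              p = ch$p.value)
  if (exact) out$fisher_p <- stats::fisher.test(tab)$p.value
  out
}

#' LFP band power from a Hann-tapered periodogram
#'
#' Computes the periodogram of the final `segment_s` seconds of the trace
#' with a Hann taper and sums the spectral estimates within each band.
#' `broadband` is the 0-50 Hz sum, which equals the four band powers plus the
#' 0-0.5 Hz remainder below the Delta band.
#'
#' @param trace an [lfp_trace()], or a list of traces (channels), in which
#'   case per-band powers are averaged across channels.
#' @param segment_s analysis segment length in seconds (default 60).
#' @param bands named list of `c(lo, hi)` band edges; see [lfp_bands()].
#' @return list with `band_power` (named numeric), `broadband`, `freq` and
#'   `power` (the periodogram over 0-50 Hz).
#' @export
band_power <- function(trace, segment_s = 60, bands = lfp_bands()) {
  if (!inherits(trace, "LfpTrace") && is.list(trace)) {
    parts <- lapply(trace, band_power, segment_s = segment_s, bands = bands)
    bp <- Reduce(`+`, lapply(parts, `[[`, "band_power")) / length(parts)
    return(list(band_power = bp,
                broadband = mean(vapply(parts, `[[`, numeric(1), "broadband")),
                freq = parts[[1]]$freq,
                power = Reduce(`+`, lapply(parts, `[[`, "power")) / length(parts)))
  }
  .assert(inherits(trace, "LfpTrace"), "trace must be an LfpTrace")
  .assert(trace$fs >= 100, "fs < 100 Hz: Gamma band unresolvable")
  n_seg <- as.integer(round(segment_s * trace$fs))
  .assert(length(trace$samples) >= n_seg,
          "trace shorter than the %g-s analysis segment", segment_s)
  x <- utils::tail(trace$samples, n_seg)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n_seg - 1) / n_seg))  # Hann taper
  xw <- (x - mean(x)) * w
  spec <- abs(stats::fft(xw))^2 / (sum(w^2) * trace$fs)
  freq <- seq(0, n_seg - 1) / n_seg * trace$fs
  half <- freq <= trace$fs / 2
  spec <- 2 * spec[half]; freq <- freq[half]
  keep <- freq <= 50
  spec <- spec[keep]; freq <- freq[keep]
  bp <- vapply(names(bands), function(b) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- if (b == "gamma") freq >= lo & freq <= hi else freq >= lo & freq < hi
    sum(spec[sel])
  }, numeric(1))
  list(band_power = bp, broadband = sum(spec), freq = freq, power = spec)
}

#' Paired comparison with normality-guided test choice
#'
#' Shapiro-Wilk on the paired differences selects between the paired
#' Student's t-test (normal differences) and the Wilcoxon matched-pairs
#' signed-rank test; both the choice and the result are returned. When all
#' differences are zero the comparison reports no change with p = 1 by
#' convention.
#'
#' @param a,b paired numeric vectors (n >= 3).
#' @param alpha significance level of the Shapiro-Wilk gate (default 0.05).
#' @return list with `test` (`"paired t"` or `"wilcoxon signed-rank"`),
#'   `statistic`, `p`, `shapiro_p`, `mean_diff`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  .assert(length(a) == length(b), "a and b must be paired (equal length)")
  .assert(length(a) >= 3, "need at least 3 pairs")
  d <- b - a
  if (all(d == 0)) {
    return(list(test = "none (no change)", statistic = 0, p = 1,
                shapiro_p = NA_real_, mean_diff = 0))
  }
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (is.na(sw)) sw <- 0
  if (sw >= alpha) {
    tt <- stats::t.test(b, a, paired = TRUE)
    list(test = "paired t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = sw, mean_diff = mean(d))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                              exact = FALSE))
    list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
         p = wt$p.value, shapiro_p = sw, mean_diff = mean(d))
  }
}

#' Kolmogorov-Smirnov comparison of two samples
#'
#' Convenience wrapper used for cumulative-distribution endpoints such as
#' degree distributions.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (D) and `p`.
#' @export
ks_compare <- function(a, b) {
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
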