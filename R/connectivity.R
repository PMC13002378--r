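# Cross-correlogram functional connectivity.
#
# Spike trains are binarized at 1 ms; the correlogram counts co-occupied bin
# pairs at each lag over an extended +/-noise_lag window and is normalized by
# sqrt(N_i * N_j) (geometric mean of the spike counts), which bounds weights
# by 1 and removes the first-order dependence on firing rate. "Correlation
# noise" is estimated deterministically from the flanking lags
# 10 < |lag| <= noise_lag; peaks/troughs are read within the +/-5 ms analysis
# window where only tight (putatively monosynaptic) synchrony lives.

#' Cross-correlogram between two spike trains
#'
#' @param train_i,train_j spike timestamp vectors (ms).
#' @param analysis_lag half-width (ms) of the window in which the peak and
#'   trough are extracted (default 5).
#' @param noise_lag half-width (ms) of the full correlogram; flank statistics
#'   use `10 < |lag| <= noise_lag` (default 50).
#' @param bin_ms lag bin width (default 1).
#' @param exclude_zero_lag drop the 0-lag bin from peak extraction (for pairs
#'   sorted from the same electrode, where 0-lag coincidences can be sorting
#'   artifacts). Default `FALSE`.
#' @param min_spikes minimum spikes per train; below it the pair is skipped
#'   with a warning and `NULL` is returned (unstable normalization).
#' @return object of class `Correlogram`: `lags`, `values` (normalized),
#'   `flank_mean`, `flank_sd`, `peak_lag`, `peak_value`, `trough_lag`,
#'   `trough_value`, `n_i`, `n_j`; or `NULL` if skipped.
#' @export
cross_correlogram <- function(train_i, train_j, analysis_lag = 5,
                              noise_lag = 50, bin_ms = 1,
                              exclude_zero_lag = FALSE, min_spikes = 10) {
  if (length(train_i) < min_spikes || length(train_j) < min_spikes) {
    warning("pair skipped: fewer than ", min_spikes, " spikes in a train",
            call. = FALSE)
    return(NULL)
  }
  L <- as.integer(round(noise_lag / bin_ms))
  A <- as.integer(round(analysis_lag / bin_ms))
  b_i <- unique(floor(train_i / bin_ms))
  b_j <- sort(unique(floor(train_j / bin_ms)))
  counts <- .lag_counts(b_i, b_j, L)
  lags <- (-L:L) * bin_ms
  norm <- sqrt(length(b_i) * length(b_j))
  values <- counts / norm
  flank <- abs(lags) > 10 & abs(lags) <= noise_lag
  flank_mean <- mean(values[flank])
  flank_sd <- stats::sd(values[flank])
  win <- abs(lags) <= analysis_lag
  if (exclude_zero_lag) win <- win & lags != 0
  wi <- which(win)
  pk <- wi[which.max(values[wi])]
  tr <- wi[which.min(values[wi])]
  structure(list(lags = lags, values = values,
                 flank_mean = flank_mean, flank_sd = flank_sd,
                 peak_lag = lags[pk], peak_value = values[pk],
                 trough_lag = lags[tr], trough_value = values[tr],
                 n_i = length(b_i), n_j = length(b_j)),
            class = "Correlogram")
}

# Count co-occupied bin pairs at each lag in -L..L between two sorted unique
# bin-index vectors, fully vectorized via findInterval.
.lag_counts <- function(b_i, b_j, L) {
  hi <- findInterval(b_i + L, b_j)
  lo <- findInterval(b_i - L - 1L, b_j)
  cnt <- hi - lo
  if (sum(cnt) == 0) return(integer(2L * L + 1L))
  idx <- sequence(cnt) + rep(lo, cnt)
  lag <- b_j[idx] - rep(b_i, cnt)
  tabulate(lag + L + 1L, nbins = 2L * L + 1L)
}

#' Cross-correlograms for all unit pairs of a recording
#'
#' @param set a [spike_train_set()].
#' @param ... passed to [cross_correlogram()].
#' @return object of class `CorrelogramSet`: list with `unit_ids`, `n`, and
#'   `pairs`, a list of `list(i, j, cc)` over all unordered pairs (`cc` may
#'   be `NULL` for skipped pairs).
#' @export
cross_correlogram_set <- function(set, ...) {
  .assert(inherits(set, "SpikeTrainSet"), "set must be a SpikeTrainSet")
  ids <- unit_ids(set)
  n <- length(ids)
  trains <- lapply(set$units, `[[`, "timestamps_ms")
  pairs <- list()
  k <- 0L
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      k <- k + 1L
      cc <- suppressWarnings(cross_correlogram(trains[[i]], trains[[j]], ...))
      pairs[[k]] <- list(i = i, j = j, cc = cc)
    }
  }
  structure(list(unit_ids = ids, n = n, pairs = pairs),
            class = "CorrelogramSet")
}

#' Build signed connectivity matrices from correlograms
#'
#' A pair is a positive link when its correlogram peak exceeds the flank mean
#' by more than `k_sd` flank standard deviations, with weight equal to the
#' normalized peak excess (`peak - flank_mean`, in `[0, 1]`); a negative link
#' when the trough falls below the flank mean by more than `k_sd` flank SDs,
#' with the (negative) normalized trough excess as weight. If both are
#' significant the larger absolute excess wins. Non-significant pairs are 0.
#'
#' @param ccset a [cross_correlogram_set()].
#' @param k_sd significance multiplier (default 5).
#' @return object of class `ConnectivityResult`: symmetric matrices `W_pos`
#'   (weights in `[0, 1]`), `W_neg` (weights `<= 0`), binary `A_pos`,
#'   `A_neg`, plus link counts and weight sums.
#' @export
build_connectivity <- function(ccset, k_sd = 5) {
  .assert(inherits(ccset, "CorrelogramSet"), "ccset must be a CorrelogramSet")
  n <- ccset$n
  ids <- ccset$unit_ids
  W_pos <- W_neg <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in ccset$pairs) {
    .assert(p$i >= 1 && p$j <= n, "pair indices outside the unit set")
    cc <- p$cc
    if (is.null(cc)) next
    pos_exc <- cc$peak_value - cc$flank_mean
    neg_exc <- cc$trough_value - cc$flank_mean
    sig_pos <- is.finite(cc$flank_sd) && pos_exc > k_sd * cc$flank_sd
    sig_neg <- is.finite(cc$flank_sd) && neg_exc < -k_sd * cc$flank_sd
    if (sig_pos && sig_neg) {
      if (pos_exc >= abs(neg_exc)) sig_neg <- FALSE else sig_pos <- FALSE
    }
    if (sig_pos) {
      W_pos[p$i, p$j] <- W_pos[p$j, p$i] <- min(pos_exc, 1)
    } else if (sig_neg) {
      W_neg[p$i, p$j] <- W_neg[p$j, p$i] <- max(neg_exc, -1)
    }
  }
  A_pos <- (W_pos > 0) + 0L
  A_neg <- (W_neg < 0) + 0L
  structure(list(W_pos = W_pos, W_neg = W_neg, A_pos = A_pos, A_neg = A_neg,
                 n_pos = sum(A_pos) / 2, n_neg = sum(A_neg) / 2,
                 sum_pos = sum(W_pos) / 2, sum_neg = sum(W_neg) / 2,
                 k_sd = k_sd),
            class = "ConnectivityResult")
}

#' Compare connectivity between two conditions
#'
#' Per-pair difference of the signed weighted matrices
#' (`Delta = W_treated - W_base`), split by sign into increases and
#' decreases; the absolute-difference distributions of the two groups are
#' compared with a two-sample Wilcoxon rank-sum test and Cohen's d. Binary
#' link counts and weight sums per sign per condition are also returned.
#'
#' @param base,treated [build_connectivity()] results on the same unit set.
#' @return list with `delta` (matrix), `n_increase`, `n_decrease`,
#'   `mean_abs_increase`, `mean_abs_decrease`, `wilcox_p`, `cohens_d`, and a
#'   `summary` data frame of per-condition counts and sums.
#' @export
compare_connectivity <- function(base, treated) {
  .assert(inherits(base, "ConnectivityResult") &&
            inherits(treated, "ConnectivityResult"),
          "inputs must be ConnectivityResult objects")
  .assert(all(dim(base$W_pos) == dim(treated$W_pos)),
          "dimension mismatch between conditions")
  Wb <- base$W_pos + base$W_neg
  Wt <- treated$W_pos + treated$W_neg
  delta <- Wt - Wb
  d_up <- delta[upper.tri(delta)]
  inc <- d_up[d_up > 0]
  dec <- -d_up[d_up < 0]
  wilcox_p <- if (length(inc) >= 2 && length(dec) >= 2) {
    suppressWarnings(stats::wilcox.test(inc, dec, exact = FALSE))$p.value
  } else NA_real_
  d <- if (length(inc) >= 2 && length(dec) >= 2) cohens_d_stat(inc, dec)
       else NA_real_
  summary <- data.frame(
    condition = c("base", "treated"),
    n_pos = c(base$n_pos, treated$n_pos),
    n_neg = c(base$n_neg, treated$n_neg),
    sum_pos = c(base$sum_pos, treated$sum_pos),
    sum_neg = c(base$sum_neg, treated$sum_neg))
  list(delta = delta, n_increase = length(inc), n_decrease = length(dec),
       mean_abs_increase = if (length(inc)) mean(inc) else NA_real_,
       mean_abs_decrease = if (length(dec)) mean(dec) else NA_real_,
       wilcox_p = wilcox_p, cohens_d = d, summary = summary)
}
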