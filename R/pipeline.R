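# End-to-end orchestration: simulate or load paired recordings, run every
# analysis stage per slice per condition, and aggregate study-level
# statistics with the slice as the statistical unit for network endpoints.

#' Analysis parameters for the pipeline
#'
#' @param bin_ms raster resolution in ms (default 1).
#' @param burst_bin_ms burst-detection bin in ms (default 500).
#' @param k_sd correlogram significance multiplier (default 5).
#' @param n_nulls small-world null-ensemble size per condition (default 100;
#'   raise towards 1000 for publication-grade estimates).
#' @param threshold_mode spectral-scaling threshold convention
#'   (`"sd"` or `"variance"`).
#' @param min_fraction minimum class fraction for the network class rule.
#' @param rel_tol relative tolerance of the "unchanged" rate category.
#' @param seed integer seed for all stochastic stages (null ensembles,
#'   k-means restarts).
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(bin_ms = 1, burst_bin_ms = 500, k_sd = 5,
                            n_nulls = 100, threshold_mode = "sd",
                            min_fraction = 0.05, rel_tol = 0.01, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Simulate a paired-condition study
#'
#' Generates `n_slices` independent slices: a baseline recording with
#' community-structured planted coupling, and a treated condition with the
#' configured effect (by default the signature perturbation: majority rate
#' decrease, injected synchrony epochs, and hub creation).
#'
#' @param n_slices number of slices (default 5).
#' @param seed study seed; per-slice seeds are derived from it.
#' @param n_sua,n_mua,duration_s forwarded to [population_config()].
#' @param effect a [condition_effect()]; by default the signature effect
#'   (majority rate decrease, synchrony epochs, and — when `with_signature`
#'   is `TRUE` — the [signature_coupling_delta()] reconfiguration).
#' @param with_signature apply the signature coupling delta per slice.
#' @param ... further arguments to [population_config()].
#' @return list of slices, each with `slice_id`, `baseline`, `treated`
#'   (SpikeTrainSets) and `ground_truth`.
#' @export
simulate_study <- function(n_slices = 5, seed = 1L, n_sua = 40, n_mua = 4,
                           duration_s = 600, effect = NULL,
                           with_signature = TRUE, ...) {
  lapply(seq_len(n_slices), function(s) {
    n <- n_sua + n_mua
    cfg <- population_config(n_sua = n_sua, n_mua = n_mua,
                             duration_s = duration_s,
                             seed = .child_seed(seed, "slice", s, "base"), ...)
    coup <- community_coupling(n, seed = .child_seed(seed, "slice", s, "coup"))
    base <- generate_baseline(cfg, coupling = coup)
    base$set$slice_id <- sprintf("slice%02d", s)
    eff <- effect
    if (is.null(eff)) {
      delta <- if (with_signature) {
        signature_coupling_delta(n, coup,
                                 seed = .child_seed(seed, "slice", s, "hub"))
      } else NULL
      eff <- condition_effect(coupling_delta = delta)
    }
    treated <- apply_condition(base$set, eff,
                               seed = .child_seed(seed, "slice", s, "cond"),
                               baseline_truth = base$ground_truth)
    list(slice_id = base$set$slice_id, baseline = base$set,
         treated = treated$set,
         ground_truth = list(baseline = base$ground_truth,
                             treated = treated$ground_truth))
  })
}

# Full single-condition analysis chain.
.analyze_condition <- function(set, params) {
  rates <- unit_rates(set)
  raster <- bin_raster(set, bin_ms = params$bin_ms)
  burst <- detect_bursts(raster, bin_ms = params$burst_bin_ms)
  ccset <- cross_correlogram_set(set)
  conn <- build_connectivity(ccset, k_sd = params$k_sd)
  G <- as_mea_graph(conn$A_pos)
  netm <- network_metrics(G)
  nodem <- node_metrics(G)
  sw <- if (G$m >= 2) {
    small_world_indices(G, n_nulls = params$n_nulls,
                        seed = .child_seed(params$seed, set$slice_id,
                                           set$condition, "nulls"))
  } else NULL
  spectral <- tryCatch(
    classify_nodes(conn$W_pos, threshold_mode = params$threshold_mode),
    error = function(e) structure(list(reason = conditionMessage(e)),
                                  class = "failed_classification"))
  netclass <- if (inherits(spectral, "SpectralClassification")) {
    classify_network(spectral, min_fraction = params$min_fraction)
  } else NULL
  list(rates = rates, burst = burst, connectivity = conn,
       network_metrics = netm, node_metrics = nodem, smallworld = sw,
       spectral = spectral, network_class = netclass)
}

#' Analyze one slice across both conditions
#'
#' Runs the full stage chain (activity, bursts, connectivity, graph metrics,
#' small-world, spectral classification) on each condition, classifies
#' per-unit rate changes, types cells from baseline features, and tests the
#' cell-type x change-direction association.
#'
#' @param baseline,treated [spike_train_set()] objects for the same slice.
#' @param params a [pipeline_params()].
#' @return a `SliceReport` list.
#' @export
analyze_slice <- function(baseline, treated, params = pipeline_params()) {
  .assert(inherits(baseline, "SpikeTrainSet") && inherits(treated, "SpikeTrainSet"),
          "both conditions must be SpikeTrainSets")
  base_res <- .analyze_condition(baseline, params)
  trt_res <- .analyze_condition(treated, params)
  change <- classify_rate_change(base_res$rates, trt_res$rates,
                                 rel_tol = params$rel_tol)
  sua <- unit_kinds(baseline) == "SUA"
  feat <- data.frame(
    unit_id = unit_ids(baseline)[sua],
    trough_to_peak_ms = vapply(baseline$units[sua], function(u)
      u$trough_to_peak_ms %||% NA_real_, numeric(1)),
    rate_hz = unname(base_res$rates[sua]))
  celltypes <- tryCatch(
    classify_cell_types(feat, seed = .child_seed(params$seed,
                                                 baseline$slice_id, "km")),
    error = function(e) NULL)
  assoc <- NULL
  if (!is.null(celltypes)) {
    dir <- change$direction[names(celltypes$labels)]
    keep <- dir %in% c("increase", "decrease")
    if (sum(keep) > 3) {
      tab <- table(class = celltypes$labels[keep], direction = dir[keep])
      if (all(dim(tab) == c(2, 2))) {
        assoc <- association_stats(unclass(tab), exact = TRUE)
      }
    }
  }
  comparison <- compare_connectivity(base_res$connectivity,
                                     trt_res$connectivity)
  list(slice_id = baseline$slice_id,
       baseline = base_res, treated = trt_res,
       rate_change = change, cell_types = celltypes,
       association = assoc, connectivity_comparison = comparison,
       params = params)
}

# Scalar endpoints of one analyzed condition, for study-level aggregation.
.condition_endpoints <- function(res) {
  nm <- res$node_metrics
  pct <- if (!is.null(res$network_class)) res$network_class$percentages
         else c(I = NA_real_, II = NA_real_, III = NA_real_)
  c(mean_rate_hz = mean(res$rates),
    burst_count = res$burst$count,
    burst_mean_height = res$burst$mean_height,
    n_pos_links = res$connectivity$n_pos,
    n_neg_links = res$connectivity$n_neg,
    sum_pos_weights = res$connectivity$sum_pos,
    sum_neg_weights = res$connectivity$sum_neg,
    avg_degree = res$network_metrics$avg_degree,
    density = res$network_metrics$density,
    components = res$network_metrics$components,
    char_path_length = res$network_metrics$char_path_length,
    avg_clustering = res$network_metrics$avg_clustering,
    mean_betweenness = mean(nm$betweenness),
    mean_closeness = mean(nm$closeness),
    mean_eigenvector = mean(nm$eigenvector),
    mean_eccentricity = mean(nm$eccentricity),
    count_deg_1_6 = res$network_metrics$count_deg_1_6,
    count_deg_ge7 = res$network_metrics$count_deg_ge7,
    max_degree = res$network_metrics$max_degree,
    sigma = if (!is.null(res$smallworld)) res$smallworld$sigma else NA_real_,
    omega = if (!is.null(res$smallworld)) res$smallworld$omega else NA_real_,
    pct_class_I = unname(pct["I"]),
    pct_class_II = unname(pct["II"]),
    pct_class_III = unname(pct["III"]))
}

#' Aggregate slice reports into study-level tables
#'
#' For every endpoint, reports per-condition mean and SEM (and median and
#' IQR) across slices and a paired comparison ([paired_compare()]); class IV
#' network counts per condition are compared with Fisher's exact test, and
#' the pooled degree distributions with a Kolmogorov-Smirnov test.
#'
#' @param reports list of [analyze_slice()] results.
#' @return list with `endpoints` (data frame), `class_iv` (counts +
#'   Fisher p), `degree_ks`.
#' @export
summarize_reports <- function(reports) {
  .assert(length(reports) >= 1, "need at least one report")
  eb <- t(vapply(reports, function(r) .condition_endpoints(r$baseline),
                 .condition_endpoints(reports[[1]]$baseline)))
  et <- t(vapply(reports, function(r) .condition_endpoints(r$treated),
                 .condition_endpoints(reports[[1]]$treated)))
  .assert(identical(colnames(eb), colnames(et)),
          "inconsistent endpoints across reports")
  rows <- lapply(colnames(eb), function(ep) {
    a <- eb[, ep]; b <- et[, ep]
    ok <- is.finite(a) & is.finite(b)
    if (!any(ok)) {
      return(data.frame(endpoint = ep, baseline_mean = NA_real_,
                        baseline_sem = NA_real_, treated_mean = NA_real_,
                        treated_sem = NA_real_, baseline_median = NA_real_,
                        treated_median = NA_real_, baseline_iqr = NA_real_,
                        treated_iqr = NA_real_, n = 0L,
                        test = "no finite values", p = NA_real_))
    }
    pc <- if (sum(ok) >= 3) paired_compare(a[ok], b[ok])
          else list(test = "insufficient n", statistic = NA_real_, p = NA_real_)
    data.frame(endpoint = ep,
               baseline_mean = mean(a[ok]), baseline_sem = .sem(a[ok]),
               treated_mean = mean(b[ok]), treated_sem = .sem(b[ok]),
               baseline_median = stats::median(a[ok]),
               treated_median = stats::median(b[ok]),
               baseline_iqr = stats::IQR(a[ok]), treated_iqr = stats::IQR(b[ok]),
               n = sum(ok), test = pc$test, p = pc$p)
  })
  endpoints <- do.call(rbind, rows)
  iv <- vapply(reports, function(r) c(
    base = !is.null(r$baseline$network_class) &&
      r$baseline$network_class$network_class == "IV",
    trt = !is.null(r$treated$network_class) &&
      r$treated$network_class$network_class == "IV"), logical(2))
  iv_tab <- rbind(baseline = c(iv_yes = sum(iv["base", ]),
                               iv_no = sum(!iv["base", ])),
                  treated = c(iv_yes = sum(iv["trt", ]),
                              iv_no = sum(!iv["trt", ])))
  fisher_p <- stats::fisher.test(iv_tab)$p.value
  deg_b <- unlist(lapply(reports, function(r) r$baseline$node_metrics$degree))
  deg_t <- unlist(lapply(reports, function(r) r$treated$node_metrics$degree))
  list(endpoints = endpoints,
       class_iv = list(table = iv_tab, fisher_p = fisher_p),
       degree_ks = ks_compare(deg_b, deg_t))
}

#' Run the full paired-condition pipeline
#'
#' `config` either contains a `simulate` block (arguments for
#' [simulate_study()]) or a `slices` list, each element naming `baseline`
#' and `treated` spike-table file paths (read with [read_spike_trains()]).
#' Slices missing a condition are skipped with an error record.
#'
#' @param config list with `simulate` or `slices`, and optionally `params`
#'   (a [pipeline_params()]) and `out_dir` for JSON/CSV/GEXF output.
#' @return list with `reports` (per slice), `summary`
#'   ([summarize_reports()]), `errors`, and `provenance` (seed, params).
#' @export
run_pipeline <- function(config) {
  params <- config$params %||% pipeline_params()
  slices <- list()
  errors <- list()
  if (!is.null(config$simulate)) {
    sim <- do.call(simulate_study, config$simulate)
    slices <- lapply(sim, function(s)
      list(slice_id = s$slice_id, baseline = s$baseline, treated = s$treated))
  } else {
    .assert(!is.null(config$slices), "config needs a simulate or slices block")
    for (s in config$slices) {
      if (is.null(s$baseline) || is.null(s$treated)) {
        errors[[length(errors) + 1]] <-
          list(slice_id = s$slice_id %||% "?",
               error = "missing condition: slice skipped")
        next
      }
      b <- if (inherits(s$baseline, "SpikeTrainSet")) s$baseline
           else read_spike_trains(s$baseline, slice_id = s$slice_id %||% "slice",
                                  condition = "baseline")
      tr <- if (inherits(s$treated, "SpikeTrainSet")) s$treated
            else read_spike_trains(s$treated, slice_id = s$slice_id %||% "slice",
                                   condition = "treated")
      slices[[length(slices) + 1]] <- list(slice_id = b$slice_id,
                                           baseline = b, treated = tr)
    }
  }
  reports <- lapply(slices, function(s)
    analyze_slice(s$baseline, s$treated, params))
  summary <- if (length(reports)) summarize_reports(reports) else NULL
  out <- list(reports = reports, summary = summary, errors = errors,
              provenance = list(seed = params$seed, params = unclass(params),
                                n_slices = length(reports),
                                version = as.character(
                                  utils::packageVersion("meanet"))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(out, file.path(config$out_dir, "report.json"))
    for (r in reports) {
      write_matrix(r$baseline$connectivity$W_pos,
                   file.path(config$out_dir,
                             sprintf("%s_baseline_Wpos.csv", r$slice_id)))
      write_matrix(r$treated$connectivity$W_pos,
                   file.path(config$out_dir,
                             sprintf("%s_treated_Wpos.csv", r$slice_id)))
      export_gexf(r$treated$connectivity$W_pos,
                  file.path(config$out_dir,
                            sprintf("%s_treated.gexf", r$slice_id)),
                  node_attributes = r$treated$node_metrics[, c("degree",
                                                               "component")])
    }
  }
  out
}

#' Write a machine-readable JSON report
#'
#' Serializes the study summary, per-slice endpoint values, and provenance;
#' bulky per-pair matrices are left to their CSV exports.
#'
#' @param result a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  slim_slice <- function(r) list(
    slice_id = r$slice_id,
    baseline = as.list(.condition_endpoints(r$baseline)),
    treated = as.list(.condition_endpoints(r$treated)),
    rate_change_proportions = as.list(r$rate_change$proportions),
    cell_type_proportions = if (!is.null(r$cell_types))
      as.list(r$cell_types$proportions) else NULL,
    association = r$association,
    delta_correlation = r$connectivity_comparison[
      c("n_increase", "n_decrease", "mean_abs_increase",
        "mean_abs_decrease", "wilcox_p", "cohens_d")])
  payload <- list(
    provenance = result$provenance,
    summary = if (!is.null(result$summary)) list(
      endpoints = result$summary$endpoints,
      class_iv = list(table = as.data.frame(result$summary$class_iv$table),
                      fisher_p = result$summary$class_iv$fisher_p),
      degree_ks = result$summary$degree_ks) else NULL,
    slices = lapply(result$reports, slim_slice),
    errors = result$errors)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
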