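# Spike-train containers, delimited-text I/O, rasterization and graph export.
# Time is in milliseconds end-to-end; raster bins are half-open [t, t + dt).

#' Construct a spike-train set
#'
#' A `SpikeTrainSet` holds the sorted spike timestamps of every unit recorded
#' from one slice in one condition, together with unit metadata (single- vs.
#' multi-unit kind and, for single units, the trough-to-peak waveform width
#' used for cell typing).
#'
#' @param units a list, one element per unit, each a list with fields
#'   `unit_id` (unique identifier), `kind` (`"SUA"` or `"MUA"`),
#'   `timestamps_ms` (strictly increasing, non-negative, in ms) and optional
#'   `trough_to_peak_ms`.
#' @param slice_id slice identifier.
#' @param condition condition label, typically `"baseline"` or `"treated"`.
#' @param duration_ms recording span in ms (defaults to the last spike time).
#' @return an object of class `SpikeTrainSet`.
#' @export
spike_train_set <- function(units, slice_id = "slice1", condition = "baseline",
                            duration_ms = NULL) {
  .assert(is.list(units), "units must be a list")
  ids <- vapply(units, function(u) as.character(u$unit_id), character(1))
  .assert(!anyDuplicated(ids), "unit_id values must be unique within a set")
  for (u in units) {
    .assert(u$kind %in% c("SUA", "MUA"),
            "unknown unit kind '%s' (unit %s)", u$kind, u$unit_id)
    ts <- u$timestamps_ms
    .assert(is.numeric(ts), "timestamps must be numeric (unit %s)", u$unit_id)
    if (length(ts)) {
      .assert(min(ts) >= 0, "negative timestamp in unit %s", u$unit_id)
      .assert(all(diff(ts) > 0),
              "timestamps must be strictly increasing (unit %s)", u$unit_id)
    }
  }
  if (is.null(duration_ms)) {
    duration_ms <- max(c(0, unlist(lapply(units, `[[`, "timestamps_ms"))))
  }
  structure(list(slice_id = slice_id, condition = condition,
                 units = units, duration_ms = duration_ms),
            class = "SpikeTrainSet")
}

#' @export
print.SpikeTrainSet <- function(x, ...) {
  n_spk <- sum(vapply(x$units, function(u) length(u$timestamps_ms), numeric(1)))
  cat(sprintf("SpikeTrainSet: slice %s, condition %s\n", x$slice_id, x$condition))
  cat(sprintf("  %d units (%d SUA, %d MUA), %d spikes, %.1f s span\n",
              length(x$units),
              sum(unit_kinds(x) == "SUA"), sum(unit_kinds(x) == "MUA"),
              n_spk, x$duration_ms / 1000))
  invisible(x)
}

#' @rdname spike_train_set
#' @param set a `SpikeTrainSet`.
#' @export
unit_ids <- function(set) vapply(set$units, function(u) as.character(u$unit_id),
                                 character(1))

#' @rdname spike_train_set
#' @export
unit_kinds <- function(set) vapply(set$units, `[[`, character(1), "kind")

#' Read and write spike trains as delimited text
#'
#' The interchange format is tidy delimited text, one spike per row, with a
#' header naming the columns `unit_id`, `time_ms`, `kind` and (optionally)
#' `ttp_ms`. Comma and tab delimiters are auto-detected on read. Unsorted
#' timestamps are sorted with a warning; exact duplicate (unit, timestamp)
#' rows are collapsed with a warning; negative timestamps and unknown kind
#' tokens are rejected with the offending line number.
#'
#' @param path file path.
#' @param slice_id,condition labels attached to the returned set.
#' @return `read_spike_trains` returns a [spike_train_set()];
#'   `write_spike_trains` returns `path` invisibly.
#' @export
read_spike_trains <- function(path, slice_id = "slice1", condition = "baseline") {
  .assert(file.exists(path), "file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("unit_id", "time_ms", "kind")
  .assert(all(need %in% names(df)),
          "header must declare columns %s", paste(need, collapse = ", "))
  df$time_ms <- as.numeric(df$time_ms)
  bad <- which(!is.finite(df$time_ms) | df$time_ms < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-numeric time_ms at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  badk <- which(!df$kind %in% c("SUA", "MUA"))
  if (length(badk)) {
    stop(sprintf("unknown kind token '%s' at line %d of %s",
                 df$kind[badk[1]], badk[1] + 1L, path), call. = FALSE)
  }
  units <- lapply(split(df, df$unit_id), function(d) {
    ts <- d$time_ms
    if (is.unsorted(ts, strictly = FALSE)) {
      warning(sprintf("unsorted timestamps for unit %s: sorting", d$unit_id[1]),
              call. = FALSE)
      ts <- sort(ts)
    }
    if (anyDuplicated(ts)) {
      warning(sprintf("duplicate timestamps for unit %s: collapsing",
                      d$unit_id[1]), call. = FALSE)
      ts <- unique(ts)
    }
    u <- list(unit_id = as.character(d$unit_id[1]), kind = d$kind[1],
              timestamps_ms = ts)
    if ("ttp_ms" %in% names(d) && is.finite(d$ttp_ms[1])) {
      u$trough_to_peak_ms <- as.numeric(d$ttp_ms[1])
    }
    u
  })
  names(units) <- NULL
  spike_train_set(units, slice_id = slice_id, condition = condition)
}

#' @rdname read_spike_trains
#' @param set a `SpikeTrainSet`.
#' @export
write_spike_trains <- function(set, path) {
  rows <- lapply(set$units, function(u) {
    if (!length(u$timestamps_ms)) return(NULL)
    data.frame(unit_id = u$unit_id, time_ms = u$timestamps_ms, kind = u$kind,
               ttp_ms = u$trough_to_peak_ms %||% NA_real_)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discretize spike trains into a binary raster
#'
#' Each unit's timestamps are mapped to half-open bins
#' `[t0 + b*bin_ms, t0 + (b+1)*bin_ms)`; a bin is 1 if the unit fired at
#' least once within it, regardless of spike count (binary occupancy).
#'
#' @param set a [spike_train_set()].
#' @param bin_ms bin width in ms (default 1, the resolution at which spikes
#'   are converted to binary times of occurrence).
#' @param t0_ms raster origin (default 0).
#' @param duration_ms span covered by the raster; defaults to the set's.
#' @return an object of class `Raster`: list with `bin_ms`, `bins`, `t0_ms`
#'   and `occupancy`, a units x bins binary matrix with unit ids as rownames.
#' @export
bin_raster <- function(set, bin_ms = 1, t0_ms = 0, duration_ms = NULL) {
  .assert(bin_ms > 0, "bin_ms must be > 0")
  duration_ms <- duration_ms %||% set$duration_ms
  nb <- max(1L, as.integer(ceiling((duration_ms - t0_ms) / bin_ms)))
  nu <- length(set$units)
  occ <- matrix(0L, nrow = nu, ncol = nb, dimnames = list(unit_ids(set), NULL))
  for (i in seq_len(nu)) {
    ts <- set$units[[i]]$timestamps_ms
    ts <- ts[ts >= t0_ms & ts < t0_ms + nb * bin_ms]
    if (length(ts)) {
      b <- floor((ts - t0_ms) / bin_ms) + 1L
      occ[i, unique(b)] <- 1L
    }
  }
  structure(list(bin_ms = bin_ms, bins = nb, t0_ms = t0_ms, occupancy = occ),
            class = "Raster")
}

#' Construct an LFP trace
#'
#' @param samples numeric vector of voltages (mV).
#' @param fs sample rate in Hz.
#' @param channel_id channel label.
#' @return an object of class `LfpTrace`.
#' @export
lfp_trace <- function(samples, fs, channel_id = "ch1") {
  .assert(fs > 0, "fs must be > 0")
  .assert(all(is.finite(samples)), "samples must be finite")
  structure(list(fs = fs, samples = as.numeric(samples),
                 channel_id = channel_id), class = "LfpTrace")
}

#' Read and write numeric matrices as CSV
#'
#' Matrices round-trip bit-exact at the declared precision (default 15
#' significant digits).
#'
#' @param M numeric matrix.
#' @param path file path.
#' @param digits significant digits written.
#' @return `read_matrix` returns a numeric matrix.
#' @export
write_matrix <- function(M, path, digits = 15) {
  .assert(is.matrix(M), "M must be a matrix")
  df <- as.data.frame(signif(M, digits))
  names(df) <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Export an undirected graph to GEXF
#'
#' Writes a GEXF 1.2 document listing each undirected edge once, with its
#' weight, and attaching per-node attributes (e.g. degree, topological class,
#' cell type) for use in external layout tools such as Gephi.
#'
#' @param M square symmetric adjacency or weight matrix; entries with
#'   `|M| > 0` become edges weighted by `M`.
#' @param path output file path.
#' @param node_attributes optional data frame with one row per node (in
#'   matrix order); every column becomes a GEXF node attribute.
#' @param tol asymmetry tolerance.
#' @return `path`, invisibly.
#' @export
export_gexf <- function(M, path, node_attributes = NULL, tol = 1e-8) {
  M <- .check_square_symmetric(M, tol = tol, what = "graph matrix")
  n <- nrow(M)
  ids <- rownames(M) %||% as.character(seq_len(n))
  if (!is.null(node_attributes)) {
    .assert(nrow(node_attributes) == n,
            "node_attributes must have one row per node")
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">')
  attr_names <- if (is.null(node_attributes)) character(0) else names(node_attributes)
  if (length(attr_names)) {
    lines <- c(lines, '    <attributes class="node">')
    for (k in seq_along(attr_names)) {
      type <- if (is.numeric(node_attributes[[k]])) "double" else "string"
      lines <- c(lines, sprintf('      <attribute id="%d" title="%s" type="%s"/>',
                                k - 1L, esc(attr_names[k]), type))
    }
    lines <- c(lines, "    </attributes>")
  }
  lines <- c(lines, "    <nodes>")
  for (i in seq_len(n)) {
    if (length(attr_names)) {
      vals <- vapply(seq_along(attr_names), function(k)
        sprintf('        <attvalue for="%d" value="%s"/>',
                k - 1L, esc(node_attributes[i, k])), character(1))
      lines <- c(lines,
                 sprintf('      <node id="%s" label="%s">', esc(ids[i]), esc(ids[i])),
                 "        <attvalues>", vals, "        </attvalues>",
                 "      </node>")
    } else {
      lines <- c(lines, sprintf('      <node id="%s" label="%s"/>',
                                esc(ids[i]), esc(ids[i])))
    }
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  eid <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && abs(M[i, j]) > 0) {
      lines <- c(lines, sprintf(
        '      <edge id="%d" source="%s" target="%s" weight="%.10g"/>',
        eid, esc(ids[i]), esc(ids[j]), M[i, j]))
      eid <- eid + 1L
    }
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}
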