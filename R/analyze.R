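#' Full LSCI response analysis for one recording
#'
#' Runs the whole perfusion pipeline on one stack: optional rigid
#' re-alignment, ROI-mean trace extraction, zero-phase drift filtering,
#' stimulation-epoch detection (Otsu on the filtered trace, or external
#' markers when provided — markers win), per-epoch baseline-normalized
#' response maps at native resolution, standardization to the common
#' 120 x 120 grid, within-recording averaging, and scalar
#' peak/slope/AUC metrics per epoch (computed on the drift-filtered
#' ROI-mean trace expressed as percent of the per-epoch baseline).
#'
#' @param frames Numeric array `time x rows x cols`.
#' @param metadata A [stack_metadata()].
#' @param roi A [roi_mask()].
#' @param markers Optional event-marker data.frame
#'   ([read_event_markers()]); when given, epochs come from the markers
#'   instead of automatic detection.
#' @param windows A [response_windows()].
#' @param filter A [drift_filter()]; default designed for the stack's
#'   sampling rate.
#' @param align Logical, run [align_frames()] first (default `FALSE`;
#'   enable for recordings with visible frame shifts).
#' @param min_duration_s,merge_gap_s Passed to [detect_stimulations()].
#' @param auc_recovery_s Recovery period appended to each epoch for the
#'   AUC integral (default 120 s).
#' @param grid_size Standardized map edge (default 120).
#' @return A list of class `"lsci_result"`: `epochs`, `native_maps`,
#'   `maps` (standardized, one per epoch), `avg_map` (within-recording
#'   average), `metrics` (one row per epoch), `trace_raw`,
#'   `trace_filtered`, `shifts` (or `NULL`), plus the inputs needed to
#'   reproduce the run.
#' @export
lsci_analyze <- function(frames, metadata, roi, markers = NULL,
                         windows = response_windows(), filter = NULL,
                         align = FALSE, min_duration_s = 5,
                         merge_gap_s = 2, auc_recovery_s = 120,
                         grid_size = 120L) {
  validate_stack_metadata(metadata)
  fs <- metadata$sampling_rate_hz
  t0 <- metadata$time_origin_s
  if (is.null(filter)) filter <- drift_filter(fs)
  shifts <- NULL
  if (align) {
    al <- align_frames(frames)
    frames <- al$frames
    shifts <- al$shifts
  }
  trace_raw <- roi_mean_trace(frames, roi)
  trace_f <- filter_trace(trace_raw, filter)
  epochs <- if (!is.null(markers)) {
    epochs_from_markers(markers, fs)
  } else {
    detect_stimulations(trace_f, fs, min_duration_s = min_duration_s,
                        merge_gap_s = merge_gap_s, time_origin_s = t0)
  }
  native_maps <- list(); maps <- list(); metrics <- list()
  for (i in seq_len(nrow(epochs))) {
    ep <- epochs[i, ]
    nm <- compute_response_map(frames, roi, ep, windows, fs,
                               time_origin_s = t0)
    native_maps[[i]] <- nm
    maps[[i]] <- standardize_map(nm, roi, size = grid_size)
    # percent-change trace for the metrics: drift-filtered ROI mean,
    # scaled by the raw per-epoch baseline level
    tvec <- t0 + (seq_along(trace_raw) - 1) / fs
    bi <- which(tvec >= ep$onset_s + windows$baseline_s[1] &
                tvec <= ep$onset_s + windows$baseline_s[2])
    B <- mean(trace_raw[bi])
    pct <- 100 * (trace_f - mean(trace_f[bi])) / B
    sm <- scalar_metrics(pct, fs, ep, windows,
                         auc_window_s = c(ep$onset_s,
                                          ep$offset_s + auc_recovery_s),
                         time_origin_s = t0)
    metrics[[i]] <- data.frame(epoch = i, onset_s = ep$onset_s,
                               offset_s = ep$offset_s,
                               source = ep$source,
                               peak_percent = sm$peak_percent,
                               time_to_peak_s = sm$time_to_peak_s,
                               slope_percent_per_s = sm$slope_percent_per_s,
                               auc_percent_s = sm$auc_percent_s)
  }
  avg_map <- if (length(maps)) average_maps(maps, "within_animal") else NULL
  metrics <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(epoch = integer(0), onset_s = numeric(0),
               offset_s = numeric(0), source = character(0),
               peak_percent = numeric(0), time_to_peak_s = numeric(0),
               slope_percent_per_s = numeric(0),
               auc_percent_s = numeric(0))
  structure(list(epochs = epochs, native_maps = native_maps,
                 maps = maps, avg_map = avg_map, metrics = metrics,
                 trace_raw = trace_raw, trace_filtered = trace_f,
                 shifts = shifts, roi = roi, windows = windows,
                 filter = filter, metadata = metadata),
            class = "lsci_result")
}

#' @export
print.lsci_result <- function(x, ...) {
  cat(sprintf("<lsci_result> %d epoch(s) (%s)\n", nrow(x$epochs),
              if (nrow(x$epochs)) x$epochs$source[1] else "none"))
  if (nrow(x$metrics)) {
    print(x$metrics, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.lsci_result <- function(x, which = c("map", "trace"), ...) {
  which <- match.arg(which)
  if (which == "map" && !is.null(x$avg_map)) {
    graphics::image(t(unclass(x$avg_map))[, nrow(x$avg_map):1],
                    col = grDevices::hcl.colors(64, "Viridis"),
                    axes = FALSE, asp = 1,
                    main = "average response map (% change)", ...)
  } else {
    t <- x$metadata$time_origin_s +
      (seq_along(x$trace_filtered) - 1) / x$metadata$sampling_rate_hz
    plot(t, x$trace_filtered, type = "l", xlab = "time (s)",
         ylab = "filtered perfusion (a.u.)", ...)
    if (nrow(x$epochs)) abline(v = x$epochs$onset_s, col = "red",
                               lty = 2)
  }
  invisible(x)
}

#' Full vessel-diametry analysis for one movie
#'
#' Binarizes the movie, measures a diameter trace per measurement line
#' (excluding user-listed plus automatically flagged artifact frames),
#' detects dilation peaks and aggregates them per vessel class.
#'
#' @param frames Numeric array `time x rows x cols`.
#' @param metadata A [stack_metadata()].
#' @param lines List of [measurement_line()] objects.
#' @param params A [peak_params()].
#' @param excluded_frames User-chosen artifact frames (always honored).
#' @param auto_flag Also run [flag_artifact_frames()] and union its
#'   suggestions in (default `TRUE`).
#' @param binarize_method,smoothing_sigma_px,fixed_threshold Passed to
#'   [binarize_movie()].
#' @param corr_threshold,snr_threshold Passed to
#'   [flag_artifact_frames()].
#' @return A list of class `"vessel_result"`: `traces` and `peaks`
#'   (named per line), `peak_table` (all peaks with line/class
#'   columns), `summary` (per vessel class), `excluded_frames`,
#'   `lines`, `binary` (the binarized movie).
#' @export
vessel_analyze <- function(frames, metadata, lines,
                           params = peak_params(),
                           excluded_frames = integer(),
                           auto_flag = TRUE,
                           binarize_method = "otsu_per_frame",
                           smoothing_sigma_px = 1,
                           fixed_threshold = NULL,
                           corr_threshold = 0.8, snr_threshold = 2) {
  validate_stack_metadata(metadata)
  stopifnot(length(lines) >= 1)
  excl <- as.integer(excluded_frames)
  if (auto_flag) {
    excl <- as.integer(flag_artifact_frames(
      frames, corr_threshold = corr_threshold,
      snr_threshold = snr_threshold, excluded_frames = excl))
  }
  bin <- binarize_movie(frames, method = binarize_method,
                        smoothing_sigma_px = smoothing_sigma_px,
                        fixed_threshold = fixed_threshold)
  labels <- vapply(lines, function(l) l$label, character(1))
  classes <- vapply(lines, function(l) l$vessel_class, character(1))
  traces <- list(); peaks <- list(); rows <- list()
  for (i in seq_along(lines)) {
    tr <- measure_diameter(bin, lines[[i]], metadata,
                           excluded_frames = excl)
    pk <- detect_peaks(tr, params)
    traces[[labels[i]]] <- tr
    peaks[[labels[i]]] <- pk
    if (nrow(pk)) {
      rows[[i]] <- cbind(data.frame(line = labels[i],
                                    vessel_class = classes[i]),
                         as.data.frame(pk))
    }
  }
  peak_table <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(line = character(0), vessel_class = character(0)),
          detect_peaks(data.frame(time_s = 0:20,
                                  diameter_um = rep(1, 21)),
                       params)[0, ])
  summary <- summarize_segments(peaks, classes)
  structure(list(traces = traces, peaks = peaks,
                 peak_table = peak_table, summary = summary,
                 excluded_frames = excl, lines = lines,
                 binary = bin, params = params, metadata = metadata),
            class = "vessel_result")
}

#' @export
print.vessel_result <- function(x, ...) {
  cat(sprintf("<vessel_result> %d line(s), %d peak(s), %d excluded frame(s)\n",
              length(x$lines), nrow(x$peak_table),
              length(x$excluded_frames)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
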