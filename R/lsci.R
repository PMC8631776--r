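#' Response and baseline windows relative to stimulation onset
#'
#' The perfusion response is averaged within 10--30 s after the
#' detected onset (skipping any ramp-like initial rise) and normalized
#' to the baseline defined 40--10 s before the onset.
#'
#' @param response_s Length-2 interval (seconds relative to onset),
#'   default `c(10, 30)`; must lie entirely after the onset.
#' @param baseline_s Length-2 interval, default `c(-40, -10)`; must lie
#'   entirely before the onset.
#' @return A list of class `"response_windows"`.
#' @export
response_windows <- function(response_s = c(10, 30),
                             baseline_s = c(-40, -10)) {
  stopifnot(length(response_s) == 2, length(baseline_s) == 2)
  if (!(baseline_s[1] < baseline_s[2] && baseline_s[2] <= 0)) {
    stop("baseline window must lie entirely before the onset",
         call. = FALSE)
  }
  if (!(0 <= response_s[1] && response_s[1] < response_s[2])) {
    stop("response window must lie entirely after the onset",
         call. = FALSE)
  }
  structure(list(response_s = as.numeric(response_s),
                 baseline_s = as.numeric(baseline_s)),
            class = "response_windows")
}

#' Detect stimulation epochs on a perfusion trace
#'
#' An Otsu threshold (256-bin histogram of the trace values) separates
#' baseline from stimulated perfusion; maximal supra-threshold runs
#' become epochs. Runs separated by sub-threshold gaps shorter than
#' `merge_gap_s` are merged, then runs shorter than `min_duration_s`
#' are discarded as noise. The onset is the time of the first
#' supra-threshold sample of each run. Detection is intended to run on
#' the drift-filtered ROI-mean trace (see [filter_trace()]); correct
#' detection should be verified visually via [plot_detection()].
#'
#' @param trace Numeric trace.
#' @param sampling_rate_hz Sampling rate of the trace.
#' @param min_duration_s Minimum epoch duration (default 5 s).
#' @param merge_gap_s Sub-threshold gaps shorter than this are bridged
#'   (default 2 s).
#' @param time_origin_s Time of the first sample.
#' @param n_bins Histogram bins for the Otsu threshold.
#' @return A data.frame of class `"stim_epochs"` with columns
#'   `onset_s`, `offset_s`, `source`, plus attributes `threshold` and
#'   `sampling_rate_hz`. Empty (with a warning) when the threshold is
#'   degenerate (constant or unimodal trace with near-zero
#'   between-class variance).
#' @export
detect_stimulations <- function(trace, sampling_rate_hz,
                                min_duration_s = 5, merge_gap_s = 2,
                                time_origin_s = 0, n_bins = 256L) {
  n <- length(trace)
  if (n <= 2 * min_duration_s * sampling_rate_hz) {
    stop("trace shorter than twice the minimum epoch duration",
         call. = FALSE)
  }
  thr <- otsu_threshold(trace, n_bins = n_bins)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      source = character(0))
  if (is.na(thr) ||
      attr(thr, "between_class_variance") < 1e-10 * var(trace)) {
    warning("degenerate Otsu threshold (unimodal or constant trace); ",
            "no epochs detected")
    return(structure(empty, class = c("stim_epochs", "data.frame"),
                     threshold = NA_real_,
                     sampling_rate_hz = sampling_rate_hz))
  }
  above <- trace > thr
  runs <- logical_runs(above)
  # bridge short sub-threshold gaps between consecutive runs
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs[i, 1] - merged[nrow(merged), 2] - 1) / sampling_rate_hz
      if (gap < merge_gap_s) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  dur <- (runs[, 2] - runs[, 1] + 1) / sampling_rate_hz
  runs <- runs[dur >= min_duration_s, , drop = FALSE]
  ep <- data.frame(
    onset_s = time_origin_s + (runs[, 1] - 1) / sampling_rate_hz,
    offset_s = time_origin_s + runs[, 2] / sampling_rate_hz,
    source = rep("otsu", nrow(runs)))
  structure(ep, class = c("stim_epochs", "data.frame"),
            threshold = as.numeric(thr),
            sampling_rate_hz = sampling_rate_hz)
}

# start/end indices of TRUE runs
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Epochs from external event markers
#'
#' Wraps externally defined stimulus intervals (e.g. the
#' capnograph-defined 5-min CO2 inhalation window) in the same epoch
#' container produced by [detect_stimulations()]. When markers are
#' available they take precedence over automatic detection.
#'
#' @param events Data.frame with `start_s`/`end_s` (and optionally
#'   `label`), as returned by [read_event_markers()].
#' @param sampling_rate_hz Sampling rate of the associated trace.
#' @return A `"stim_epochs"` data.frame with `source = "marker"`.
#' @export
epochs_from_markers <- function(events, sampling_rate_hz) {
  validate_event_markers(events)
  ep <- data.frame(onset_s = events$start_s, offset_s = events$end_s,
                   source = rep("marker", nrow(events)))
  structure(ep, class = c("stim_epochs", "data.frame"),
            threshold = NA_real_, sampling_rate_hz = sampling_rate_hz)
}

#' Per-pixel percent-change response map (native resolution)
#'
#' For every ROI pixel, the response is
#' `100 * (mean(response window) - mean(baseline window)) /
#' mean(baseline window)`, with both windows taken relative to the
#' epoch onset. Pixels outside the ROI, and pixels whose baseline mean
#' is not positive, are flagged missing (`NA`); the latter are counted
#' in the `n_bad_baseline` attribute.
#'
#' @param stack Numeric array `time x rows x cols` of raw perfusion
#'   values.
#' @param roi A [roi_mask()].
#' @param epoch One row of a `"stim_epochs"` data.frame (or a list with
#'   `onset_s`).
#' @param windows A [response_windows()].
#' @param sampling_rate_hz Acquisition rate of `stack`.
#' @param time_origin_s Time of frame 1.
#' @return Numeric matrix (native resolution) of percent changes with
#'   attribute `n_bad_baseline`.
#' @export
compute_response_map <- function(stack, roi, epoch,
                                 windows = response_windows(),
                                 sampling_rate_hz,
                                 time_origin_s = 0) {
  stopifnot(length(dim(stack)) == 3, inherits(roi, "roi_mask"))
  nt <- dim(stack)[1]
  t <- time_origin_s + (seq_len(nt) - 1) / sampling_rate_hz
  onset <- epoch$onset_s
  bi <- which(t >= onset + windows$baseline_s[1] &
              t <= onset + windows$baseline_s[2])
  ri <- which(t >= onset + windows$response_s[1] &
              t <= onset + windows$response_s[2])
  if (!length(bi) || !length(ri) ||
      min(bi) < 1 || max(ri) > nt) {
    stop("baseline/response windows fall outside the recording",
         call. = FALSE)
  }
  B <- colMeans(stack[bi, , , drop = FALSE], dims = 1)
  R <- colMeans(stack[ri, , , drop = FALSE], dims = 1)
  map <- 100 * (R - B) / B
  bad <- roi$mask & !is.na(B) & B <= 0
  map[bad] <- NA_real_
  map[!roi$mask] <- NA_real_
  structure(map, n_bad_baseline = sum(bad))
}

#' Standardize a native response map to the common 120 x 120 grid
#'
#' Crops the map to the square bounding box of the ROI (padding with
#' missing values where the box exceeds the frame) and resamples it to
#' exactly `size x size` pixels with bilinear interpolation
#' (half-pixel-center convention, [bilinear_resize()]); missing pixels
#' propagate. Standardized maps from different animals/windows are
#' directly comparable and can be averaged.
#'
#' @param map Native-resolution percent-change matrix.
#' @param roi The [roi_mask()] used to compute the map.
#' @param size Output grid edge (default 120).
#' @return A `size x size` matrix of class `"response_map"` with
#'   attributes `n_stimulations_averaged` (1) and `n_animals_averaged`
#'   (1).
#' @export
standardize_map <- function(map, roi, size = 120L) {
  stopifnot(is.matrix(map), inherits(roi, "roi_mask"))
  idx <- which(roi$mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI", call. = FALSE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  if ((r1 - r0 + 1) < 3 || (c1 - c0 + 1) < 3) {
    stop("ROI bounding box smaller than 3 x 3", call. = FALSE)
  }
  side <- max(r1 - r0 + 1, c1 - c0 + 1)
  crop <- matrix(NA_real_, side, side)
  # center the (possibly rectangular, possibly clipped) box in a square
  ro <- (side - (r1 - r0 + 1)) %/% 2
  co <- (side - (c1 - c0 + 1)) %/% 2
  crop[ro + seq_len(r1 - r0 + 1), co + seq_len(c1 - c0 + 1)] <-
    map[r0:r1, c0:c1]
  out <- bilinear_resize(crop, size, size)
  structure(out, class = c("response_map", "matrix"),
            n_stimulations_averaged = 1L, n_animals_averaged = 1L)
}

#' Average standardized response maps
#'
#' Pixelwise mean over maps, ignoring missing values (a pixel missing
#' in some maps is averaged over the maps where it is present; missing
#' everywhere stays missing). Averaging happens first across the
#' stimulation repetitions of one animal (`level = "within_animal"`),
#' then across the animals of a group (`level = "across_animals"`);
#' the corresponding counters are accumulated.
#'
#' @param maps List of `"response_map"` matrices of identical size.
#' @param level `"within_animal"` or `"across_animals"`.
#' @return A `"response_map"` with updated counters.
#' @export
average_maps <- function(maps,
                         level = c("within_animal", "across_animals")) {
  level <- match.arg(level)
  if (!length(maps)) stop("no maps to average", call. = FALSE)
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("maps differ in size", call. = FALSE)
  }
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (m in maps) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  n_stim <- sum(vapply(maps, function(m) {
    v <- attr(m, "n_stimulations_averaged"); if (is.null(v)) 1L else v
  }, integer(1)))
  n_anim <- if (level == "across_animals") {
    sum(vapply(maps, function(m) {
      v <- attr(m, "n_animals_averaged"); if (is.null(v)) 1L else v
    }, integer(1)))
  } else 1L
  structure(out, class = c("response_map", "matrix"),
            n_stimulations_averaged = n_stim,
            n_animals_averaged = n_anim)
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "<response_map> %d x %d, %d stimulation(s), %d animal(s), peak %.2f %%\n",
    nrow(x), ncol(x), attr(x, "n_stimulations_averaged"),
    attr(x, "n_animals_averaged"), suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Normalize a trace to its per-epoch baseline
#'
#' Converts a raw perfusion trace to percent change relative to the
#' baseline-window mean of the given epoch:
#' `100 * (x - B) / B`.
#'
#' @inheritParams scalar_metrics
#' @param trace Raw trace.
#' @return Percent-change trace (same length).
#' @export
normalize_trace <- function(trace, sampling_rate_hz, epoch,
                            windows = response_windows(),
                            time_origin_s = 0) {
  t <- time_origin_s + (seq_along(trace) - 1) / sampling_rate_hz
  bi <- which(t >= epoch$onset_s + windows$baseline_s[1] &
              t <= epoch$onset_s + windows$baseline_s[2])
  if (!length(bi)) stop("baseline window outside the recording",
                        call. = FALSE)
  B <- mean(trace[bi])
  if (!is.finite(B) || B <= 0) stop("non-positive baseline mean",
                                    call. = FALSE)
  100 * (trace - B) / B
}

#' Scalar response metrics: peak, slope, AUC
#'
#' Operates on a baseline-normalized percent-change trace (see
#' [normalize_trace()]). The peak is the maximum within the epoch; the
#' slope is the baseline-normalized rise rate
#' `(peak - baseline mean) / (t_peak - t_baseline_end)` with the
#' baseline mean taken over the baseline window (approximately 0 for a
#' normalized trace) and `t_baseline_end` the end of that window; the
#' AUC is the trapezoidal integral of the trace over `auc_window_s`
#' (default: onset to offset + 120 s recovery, clipped to the
#' recording).
#'
#' @param trace Normalized percent-change trace.
#' @param sampling_rate_hz Sampling rate.
#' @param epoch One epoch (needs `onset_s`, `offset_s`).
#' @param windows A [response_windows()].
#' @param auc_window_s Optional length-2 absolute time interval for the
#'   AUC.
#' @param time_origin_s Time of the first sample.
#' @return A list of class `"scalar_response"`: `peak_percent`,
#'   `time_to_peak_s`, `slope_percent_per_s` (`NA` with a warning when
#'   the peak does not follow the baseline window end),
#'   `auc_percent_s`, `auc_window_s`.
#' @export
scalar_metrics <- function(trace, sampling_rate_hz, epoch,
                           windows = response_windows(),
                           auc_window_s = NULL, time_origin_s = 0) {
  n <- length(trace)
  t <- time_origin_s + (seq_len(n) - 1) / sampling_rate_hz
  onset <- epoch$onset_s; offset <- epoch$offset_s
  ei <- which(t >= onset & t <= offset)
  if (!length(ei)) stop("epoch outside the recording", call. = FALSE)
  ipk <- ei[which.max(trace[ei])]
  peak <- trace[ipk]
  t_peak <- t[ipk]
  bi <- which(t >= onset + windows$baseline_s[1] &
              t <= onset + windows$baseline_s[2])
  if (!length(bi)) stop("baseline window outside the recording",
                        call. = FALSE)
  base_mean <- mean(trace[bi])
  t_base_end <- onset + windows$baseline_s[2]
  if (t_peak <= t_base_end) {
    warning("peak time does not follow the baseline window; ",
            "slope undefined")
    slope <- NA_real_
  } else {
    slope <- (peak - base_mean) / (t_peak - t_base_end)
  }
  if (is.null(auc_window_s)) auc_window_s <- c(onset, offset + 120)
  auc_window_s <- c(max(auc_window_s[1], t[1]),
                    min(auc_window_s[2], t[n]))
  ai <- which(t >= auc_window_s[1] & t <= auc_window_s[2])
  auc <- pracma::trapz(t[ai], trace[ai])
  structure(list(peak_percent = peak, time_to_peak_s = t_peak - onset,
                 slope_percent_per_s = slope, auc_percent_s = auc,
                 auc_window_s = auc_window_s),
            class = "scalar_response")
}

#' @export
print.scalar_response <- function(x, ...) {
  cat(sprintf(
    "<scalar_response> peak %.2f %% at +%.1f s, slope %.3f %%/s, AUC %.1f %%*s\n",
    x$peak_percent, x$time_to_peak_s, x$slope_percent_per_s,
    x$auc_percent_s))
  invisible(x)
}

#' Verification plot for automatic stimulation detection
#'
#' Writes a PNG of the (filtered) detection trace with the Otsu
#' threshold and the detected epochs shaded, mirroring the visual
#' verification step of the original analysis.
#'
#' @param trace Detection trace.
#' @param sampling_rate_hz Its sampling rate.
#' @param epochs A `"stim_epochs"` data.frame.
#' @param path Output PNG path.
#' @param time_origin_s Time of the first sample.
#' @return `path`, invisibly.
#' @export
plot_detection <- function(trace, sampling_rate_hz, epochs, path,
                           time_origin_s = 0) {
  t <- time_origin_s + (seq_along(trace) - 1) / sampling_rate_hz
  grDevices::png(path, width = 900, height = 300)
  on.exit(grDevices::dev.off())
  par(mar = c(4, 4, 2, 1))
  plot(t, trace, type = "l", xlab = "time (s)",
       ylab = "filtered perfusion (a.u.)",
       main = sprintf("detected stimulation epochs (n = %d)",
                      nrow(epochs)))
  if (nrow(epochs)) {
    usr <- par("usr")
    rect(epochs$onset_s, usr[3], epochs$offset_s, usr[4],
         col = grDevices::adjustcolor("orange", 0.25), border = NA)
  }
  thr <- attr(epochs, "threshold")
  if (!is.null(thr) && is.finite(thr)) abline(h = thr, lty = 2,
                                              col = "red")
  invisible(path)
}
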