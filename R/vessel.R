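#' Suggest artifact frames in a vessel movie
#'
#' Frames corrupted by heavy motion or low signal-to-noise should be
#' excluded before diametry. This helper suggests candidates; manual
#' inspection remains primary, so a user-supplied exclusion list is
#' always unioned in. Two rules are applied:
#'
#' * **motion**: a frame whose Pearson correlation with its preceding
#'   frame falls below `corr_threshold` *and* which also decorrelates
#'   from its following frame (so that a single jittered frame flags
#'   itself, not its innocent successor);
#' * **SNR**: a frame whose ratio mean(foreground)/sd(background) after
#'   a provisional Otsu split falls below `snr_threshold`, or which
#'   cannot be split at all.
#'
#' @param frames Numeric array `time x rows x cols` (>= 3 frames).
#' @param corr_threshold Motion rule threshold (default 0.8).
#' @param snr_threshold SNR rule threshold (default 2).
#' @param excluded_frames Integer indices the user already excluded.
#' @return Sorted integer vector of suggested frame indices, with a
#'   `details` attribute (per-frame correlation and SNR).
#' @export
flag_artifact_frames <- function(frames, corr_threshold = 0.8,
                                 snr_threshold = 2,
                                 excluded_frames = integer()) {
  stopifnot(length(dim(frames)) == 3)
  nt <- dim(frames)[1]
  if (nt < 3) stop("need at least 3 frames", call. = FALSE)
  flat <- matrix(frames, nrow = nt)
  cp <- rep(NA_real_, nt)  # correlation with preceding frame
  for (k in 2:nt) {
    sk <- stats::sd(flat[k, ]); sp <- stats::sd(flat[k - 1, ])
    cp[k] <- if (sk == 0 || sp == 0) 0 else cor(flat[k, ], flat[k - 1, ])
  }
  low <- !is.na(cp) & cp < corr_threshold
  motion <- vapply(seq_len(nt), function(k) {
    if (!low[k]) return(FALSE)
    if (k == nt) return(TRUE)
    low[k + 1]
  }, logical(1))
  snr <- vapply(seq_len(nt), function(k) {
    v <- flat[k, ]
    thr <- otsu_threshold(v)
    if (is.na(thr)) return(0)
    fg <- v[v > thr]; bg <- v[v <= thr]
    if (!length(fg) || length(bg) < 2) return(0)
    s <- stats::sd(bg)
    if (s == 0) return(Inf)
    mean(fg) / s
  }, numeric(1))
  flagged <- sort(unique(c(which(motion), which(snr < snr_threshold),
                           as.integer(excluded_frames))))
  structure(flagged,
            details = data.frame(frame = seq_len(nt), corr_prev = cp,
                                 snr = snr))
}

#' Binarize a vessel movie
#'
#' Each frame is lightly Gaussian-smoothed (default sigma 1 px) and
#' thresholded so that 1 marks vessel lumen (plasma fluorescence) and 0
#' background. The default per-frame Otsu threshold adapts to
#' photobleaching; a fixed threshold is available for strict
#' reproducibility across frames.
#'
#' @param frames Numeric array `time x rows x cols`.
#' @param method `"otsu_per_frame"` (default) or `"fixed"`.
#' @param smoothing_sigma_px Pre-threshold Gaussian sigma (0 disables).
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @return Integer 0/1 array of the same shape, with attribute
#'   `thresholds` (per frame). A constant frame under Otsu yields an
#'   all-zero frame with a warning.
#' @export
binarize_movie <- function(frames, method = c("otsu_per_frame", "fixed"),
                           smoothing_sigma_px = 1,
                           fixed_threshold = NULL) {
  method <- match.arg(method)
  stopifnot(length(dim(frames)) == 3)
  if (method == "fixed" && is.null(fixed_threshold)) {
    stop("method = 'fixed' requires fixed_threshold", call. = FALSE)
  }
  nt <- dim(frames)[1]
  out <- array(0L, dim(frames))
  thresholds <- rep(NA_real_, nt)
  degenerate <- FALSE
  for (k in seq_len(nt)) {
    f <- gaussian_smooth(frames[k, , ], smoothing_sigma_px)
    thr <- if (method == "fixed") fixed_threshold else otsu_threshold(f)
    if (is.na(thr)) {
      degenerate <- TRUE
      next  # frame stays all zero
    }
    thresholds[k] <- thr
    out[k, , ] <- (f > thr) * 1L
  }
  if (degenerate) {
    warning("constant frame(s): Otsu undefined, frame binarized to all zero")
  }
  structure(out, thresholds = thresholds)
}

# Sample points along a segment at unit (pixel) arc-length spacing and
# map them to nearest voxels. Sampling by arc length (rather than a
# per-axis pixel walk) keeps the count-times-voxel-size diameter
# estimate correct for oblique lines.
sample_line_voxels <- function(p0, p1, offset, dim_hw) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len
  nrm <- c(-u[2], u[1])
  tt <- seq(0, len, by = 1)
  if (tt[length(tt)] < len) tt <- c(tt, len)
  pts <- cbind(p0[1] + tt * u[1] + offset * nrm[1],
               p0[2] + tt * u[2] + offset * nrm[2])
  vox <- cbind(floor(pts[, 1] + 0.5), floor(pts[, 2] + 0.5))
  keep <- vox[, 1] >= 1 & vox[, 1] <= dim_hw[1] &
          vox[, 2] >= 1 & vox[, 2] <= dim_hw[2]
  vox[keep, , drop = FALSE]
}

#' Vessel diameter over time along a measurement line
#'
#' For every frame, the drawn line plus its parallel companions
#' (`thickness_voxels` lines offset perpendicular at unit spacing;
#' for the default thickness 4 the offsets are -1.5, -0.5, +0.5,
#' +1.5 voxels) are rasterized at unit arc-length spacing, the voxels
#' with value 1 on each line are counted and multiplied by the voxel
#' size, and the frame diameter is the mean over the parallel lines. A
#' line lying fully outside the vessel gives diameter 0 (a valid
#' measurement, not an error). Excluded frames are flagged missing.
#'
#' @param binary Integer 0/1 array `time x rows x cols` (see
#'   [binarize_movie()]).
#' @param line A [measurement_line()].
#' @param metadata A [stack_metadata()] providing `pixel_size_um` and
#'   the frame interval.
#' @param excluded_frames Integer frame indices to flag missing.
#' @return A data.frame of class `"diameter_trace"` with columns
#'   `frame`, `time_s`, `diameter_um`; the line is kept in the `line`
#'   attribute.
#' @export
measure_diameter <- function(binary, line, metadata,
                             excluded_frames = integer()) {
  stopifnot(length(dim(binary)) == 3, inherits(line, "measurement_line"))
  nt <- dim(binary)[1]; h <- dim(binary)[2]; w <- dim(binary)[3]
  if (any(line$p0 < 1) || any(line$p1 < 1) ||
      line$p0[1] > h || line$p1[1] > h ||
      line$p0[2] > w || line$p1[2] > w) {
    stop("line endpoints fall outside the image", call. = FALSE)
  }
  k <- line$thickness_voxels
  offsets <- seq(-(k - 1) / 2, (k - 1) / 2, by = 1)
  flat <- matrix(binary, nrow = nt)
  per_line <- matrix(0, nt, k)
  for (j in seq_len(k)) {
    vox <- sample_line_voxels(line$p0, line$p1, offsets[j], c(h, w))
    if (!nrow(vox)) next
    idx <- (vox[, 2] - 1L) * h + vox[, 1]
    per_line[, j] <- rowSums(flat[, idx, drop = FALSE])
  }
  diam <- rowMeans(per_line) * metadata$pixel_size_um
  excluded_frames <- as.integer(excluded_frames)
  diam[excluded_frames[excluded_frames >= 1 & excluded_frames <= nt]] <-
    NA_real_
  structure(data.frame(frame = seq_len(nt),
                       time_s = frame_times(nt, metadata),
                       diameter_um = diam),
            class = c("diameter_trace", "data.frame"),
            line = line)
}

#' Peak-detection parameters for the dilation detector
#'
#' The three user-tunable quantities of the baseline-tracking detector:
#' how many initial (unstimulated) frames form the baseline, how far
#' above baseline a peak must rise to open, and the closing criterion
#' (percent threshold plus a debounce count to avoid chatter on noisy
#' plateaus).
#'
#' @param n_baseline_frames Frames averaged for each baseline
#'   (default 10).
#' @param start_threshold_percent Percent above baseline opening a peak
#'   (default 5).
#' @param end_threshold_percent Percent above baseline under which a
#'   peak may close (default 2; must be < start).
#' @param min_end_frames Consecutive sub-end-threshold frames required
#'   to close (default 3).
#' @return A list of class `"peak_params"`.
#' @export
peak_params <- function(n_baseline_frames = 10L,
                        start_threshold_percent = 5,
                        end_threshold_percent = 2,
                        min_end_frames = 3L) {
  if (n_baseline_frames < 1) stop("n_baseline_frames must be >= 1",
                                  call. = FALSE)
  if (!(start_threshold_percent > end_threshold_percent &&
        end_threshold_percent >= 0)) {
    stop("need start_threshold_percent > end_threshold_percent >= 0",
         call. = FALSE)
  }
  if (min_end_frames < 1) stop("min_end_frames must be >= 1",
                               call. = FALSE)
  structure(list(n_baseline_frames = as.integer(n_baseline_frames),
                 start_threshold_percent = start_threshold_percent,
                 end_threshold_percent = end_threshold_percent,
                 min_end_frames = as.integer(min_end_frames)),
            class = "peak_params")
}

#' Baseline-tracking dilation peak detection
#'
#' State machine over a diameter trace:
#'
#' 1. the baseline is the mean of the next `n_baseline_frames` valid
#'    frames; its timestamp is the last frame entering that mean (the
#'    last timepoint before peak detection resumes);
#' 2. a peak opens at the first later frame exceeding
#'    `baseline * (1 + start_threshold/100)`;
#' 3. it closes once `min_end_frames` consecutive valid frames fall
#'    below `baseline * (1 + end_threshold/100)` (or at the end of the
#'    trace);
#' 4. the peak maximum and its time are taken within the open..close
#'    span, and
#'    `percent_change = 100 * (d_max - d_base) / d_base`,
#'    `slope = ((d_max - d_base) / (t_max - t_base)) / d_base`
#'    (the rise rate normalized by the baseline diameter, in 1/s);
#' 5. a new baseline is computed from the frames after the close and
#'    detection continues.
#'
#' Flagged (missing) frames are skipped throughout. A non-positive
#' baseline skips that segment with a warning. A peak whose maximum
#' falls exactly on the baseline timestamp has an undefined slope
#' (`NA`, with a warning).
#'
#' @param trace A `"diameter_trace"` data.frame (or any data.frame with
#'   `time_s` and `diameter_um`).
#' @param params A [peak_params()].
#' @return A data.frame of class `"vessel_peaks"`, one row per peak:
#'   `t_start_s`, `t_end_s`, `time_baseline_s`, `diameter_baseline_um`,
#'   `time_max_s`, `diameter_max_um`, `slope_per_s`, `percent_change`.
#' @export
detect_peaks <- function(trace, params = peak_params()) {
  stopifnot(all(c("time_s", "diameter_um") %in% names(trace)))
  d <- trace$diameter_um
  t <- trace$time_s
  nb <- params$n_baseline_frames
  valid <- which(!is.na(d))
  if (length(valid) <= nb) {
    stop("trace has too few valid frames for the baseline", call. = FALSE)
  }
  peaks <- list()
  pos <- 1L  # position within `valid`
  repeat {
    if (pos + nb - 1L > length(valid)) break
    bidx <- valid[pos:(pos + nb - 1L)]
    base <- mean(d[bidx])
    t_base <- t[bidx[nb]]
    if (!is.finite(base) || base <= 0) {
      warning("non-positive baseline; segment skipped")
      pos <- pos + nb
      next
    }
    open_lvl <- base * (1 + params$start_threshold_percent / 100)
    end_lvl <- base * (1 + params$end_threshold_percent / 100)
    scan <- valid[valid > bidx[nb]]
    open_at <- scan[which(d[scan] > open_lvl)[1]]
    if (is.na(open_at)) break
    after <- scan[scan >= open_at]
    below <- d[after] < end_lvl
    close_run <- consecutive_run_start(below, params$min_end_frames)
    if (is.na(close_run)) {
      close_at <- after[length(after)]
      resume <- length(valid) + 1L  # trace exhausted
    } else {
      close_at <- if (close_run == 1) open_at else after[close_run - 1L]
      resume <- match(after[close_run + params$min_end_frames - 1L],
                      valid) + 1L
    }
    span <- valid[valid >= open_at & valid <= close_at]
    imax <- span[which.max(d[span])]
    d_max <- d[imax]; t_max <- t[imax]
    pct <- 100 * (d_max - base) / base
    if (t_max <= t_base) {
      warning("peak maximum at the baseline timestamp; slope undefined")
      slope <- NA_real_
    } else {
      slope <- ((d_max - base) / (t_max - t_base)) / base
    }
    peaks[[length(peaks) + 1L]] <- data.frame(
      t_start_s = t[open_at], t_end_s = t[close_at],
      time_baseline_s = t_base, diameter_baseline_um = base,
      time_max_s = t_max, diameter_max_um = d_max,
      slope_per_s = slope, percent_change = pct)
    pos <- resume
    if (pos > length(valid)) break
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
               time_baseline_s = numeric(0),
               diameter_baseline_um = numeric(0),
               time_max_s = numeric(0), diameter_max_um = numeric(0),
               slope_per_s = numeric(0), percent_change = numeric(0))
  structure(out, class = c("vessel_peaks", "data.frame"),
            params = params)
}

# index (within x) of the first element of the first run of `len`
# consecutive TRUEs, or NA
consecutive_run_start <- function(x, len) {
  if (!length(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]]
}

#' Summarize dilation peaks per vessel class
#'
#' Aggregates the per-peak percent change and slope across measurement
#' lines of the same vessel class (pial, penetrating arteriole,
#' capillary). Classes with no detected peaks yield a row with zero
#' count and missing means.
#'
#' @param peaks_by_line Named list: one `"vessel_peaks"` data.frame per
#'   measurement line.
#' @param classes Character vector, the vessel class of each line (same
#'   order/length as `peaks_by_line`).
#' @return A data.frame, one row per class present: `vessel_class`,
#'   `n_lines`, `n_peaks`, `mean_percent_change`, `max_percent_change`,
#'   `mean_slope_per_s`, `max_slope_per_s`.
#' @export
summarize_segments <- function(peaks_by_line, classes) {
  stopifnot(length(peaks_by_line) == length(classes))
  out <- lapply(unique(classes), function(cl) {
    sel <- which(classes == cl)
    pk <- do.call(rbind, lapply(peaks_by_line[sel], as.data.frame))
    n <- if (is.null(pk)) 0L else nrow(pk)
    if (n == 0) {
      data.frame(vessel_class = cl, n_lines = length(sel), n_peaks = 0L,
                 mean_percent_change = NA_real_,
                 max_percent_change = NA_real_,
                 mean_slope_per_s = NA_real_, max_slope_per_s = NA_real_)
    } else {
      data.frame(vessel_class = cl, n_lines = length(sel), n_peaks = n,
                 mean_percent_change = mean(pk$percent_change),
                 max_percent_change = max(pk$percent_change),
                 mean_slope_per_s = mean(pk$slope_per_s, na.rm = TRUE),
                 max_slope_per_s = suppressWarnings(
                   max(pk$slope_per_s, na.rm = TRUE)))
    }
  })
  do.call(rbind, out)
}
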