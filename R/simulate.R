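#' Configuration for a synthetic LSCI recording
#'
#' The defaults emulate the standard whisker-stimulation protocol:
#' three 60-s stimulations separated by 120-s rest intervals (onsets at
#' 120, 300, 480 s), imaged at 4.4 Hz, with a Gaussian response blob
#' (the activated somatosensory area), slow multiplicative drift and
#' speckle-like multiplicative noise.
#'
#' @param shape `(T, rows, cols)`. Default covers the full protocol
#'   (660 s at 4.4 Hz) on a 96 x 96 field.
#' @param sampling_rate_hz Default 4.4.
#' @param baseline_level Baseline perfusion in arbitrary units.
#' @param drift List `(type, magnitude_percent_per_10min)`; `type` is
#'   `"linear"` or `"sinusoid"` (period 10 min).
#' @param stimulations Data.frame with `onset_s`, `duration_s`,
#'   `amplitude_percent`, `ramp_s`. Onsets must be spaced by at least
#'   `duration_s + 60` s. The default ramp is 0 s (an effectively
#'   instantaneous perfusion rise at stimulus onset).
#' @param blob List `(center, sigma_px)`; `center = NULL` means the
#'   field center.
#' @param noise_sigma_percent Multiplicative Gaussian noise sd, percent
#'   of the local signal.
#' @param seed RNG seed; generation is a pure function of the config.
#' @return A list of class `"lsci_sim_config"`.
#' @export
lsci_sim_config <- function(shape = c(2904L, 96L, 96L),
                            sampling_rate_hz = 4.4,
                            baseline_level = 500,
                            drift = list(type = "linear",
                                         magnitude_percent_per_10min = 5),
                            stimulations = data.frame(
                              onset_s = c(120, 300, 480),
                              duration_s = 60,
                              amplitude_percent = 10,
                              ramp_s = 0),
                            blob = list(center = NULL, sigma_px = 15),
                            noise_sigma_percent = 3,
                            seed = 1L) {
  stopifnot(length(shape) == 3, all(shape > 0))
  if (!drift$type %in% c("linear", "sinusoid")) {
    stop("drift type must be 'linear' or 'sinusoid'", call. = FALSE)
  }
  st <- stimulations
  if (nrow(st)) {
    if (any(st$amplitude_percent < 0)) {
      stop("stimulation amplitudes must be >= 0", call. = FALSE)
    }
    if (nrow(st) > 1) {
      gaps <- diff(st$onset_s)
      if (any(gaps < st$duration_s[-nrow(st)] + 60)) {
        stop("stimulation onsets must be spaced >= duration + 60 s",
             call. = FALSE)
      }
    }
  }
  if (is.null(blob$center)) {
    blob$center <- c((shape[2] + 1) / 2, (shape[3] + 1) / 2)
  }
  structure(list(shape = as.integer(shape),
                 sampling_rate_hz = sampling_rate_hz,
                 baseline_level = baseline_level, drift = drift,
                 stimulations = st, blob = blob,
                 noise_sigma_percent = noise_sigma_percent,
                 seed = as.integer(seed)),
            class = "lsci_sim_config")
}

#' Simulate an LSCI perfusion stack with known ground truth
#'
#' Per-pixel model:
#' `baseline * (1 + drift(t) + blob(x, y) * response(t)) * (1 + eps)`,
#' with `eps ~ N(0, noise_sigma/100)` i.i.d. per voxel. The response
#' time course ramps linearly to the stimulation amplitude over
#' `ramp_s` and stays there (boxcar) until the offset; the spatial blob
#' is a Gaussian with maximum 1 at its center, so the true response-map
#' amplitude at the blob center equals the configured
#' `amplitude_percent`.
#'
#' @param config An [lsci_sim_config()].
#' @return A list: `frames` (array `T x rows x cols`), `metadata`
#'   ([stack_metadata()]), `truth` (onsets/offsets/amplitudes, blob
#'   center and sigma, and `amplitude_map`, the noise- and drift-free
#'   percent-change map).
#' @export
simulate_lsci <- function(config = lsci_sim_config()) {
  stopifnot(inherits(config, "lsci_sim_config"))
  nt <- config$shape[1]; h <- config$shape[2]; w <- config$shape[3]
  fs <- config$sampling_rate_hz
  t <- (seq_len(nt) - 1) / fs
  resp <- numeric(nt)
  st <- config$stimulations
  for (i in seq_len(nrow(st))) {
    a <- st$amplitude_percent[i] / 100
    on <- st$onset_s[i]; off <- on + st$duration_s[i]
    ramp <- st$ramp_s[i]
    s <- numeric(nt)
    inside <- t >= on & t < off
    s[inside] <- if (ramp > 0) pmin((t[inside] - on) / ramp, 1) else 1
    resp <- resp + a * s
  }
  drift_mag <- config$drift$magnitude_percent_per_10min / 100
  dr <- switch(config$drift$type,
               linear = drift_mag * t / 600,
               sinusoid = drift_mag * sin(2 * pi * t / 600))
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- exp(-((rr - config$blob$center[1])^2 +
                (cc - config$blob$center[2])^2) /
              (2 * config$blob$sigma_px^2))
  V <- outer(resp, as.vector(blob))     # T x (h*w)
  V <- V + (1 + dr)                     # recycled down columns
  set.seed(config$seed)
  eps <- matrix(rnorm(nt * h * w, sd = config$noise_sigma_percent / 100),
                nt, h * w)
  V <- config$baseline_level * V * (1 + eps)
  frames <- array(V, c(nt, h, w))
  md <- stack_metadata(sampling_rate_hz = fs, modality = "lsci")
  truth <- list(onsets_s = st$onset_s,
                offsets_s = st$onset_s + st$duration_s,
                amplitudes_percent = st$amplitude_percent,
                blob_center = config$blob$center,
                blob_sigma_px = config$blob$sigma_px,
                amplitude_map = if (nrow(st))
                  max(st$amplitude_percent) * blob else 0 * blob)
  list(frames = frames, metadata = md, truth = truth)
}

#' Configuration for a synthetic two-photon vessel movie
#'
#' The defaults emulate a 2-PM time series of 270 frames at one frame
#' per 2 s (540 s, covering three 60-s stimulations with 120-s rests,
#' i.e. dilation onsets at frames 30/120/210) showing a straight
#' fluorescent vessel of 40-voxel baseline width whose width dilates
#' transiently. The tube axis passes through the image center, which
#' for an even field size lies on a pixel boundary, so even plateau
#' widths map to exact voxel counts and the configured dilation
#' amplitude is recovered exactly by an ideal measurement.
#'
#' @param shape `(T, rows, cols)`.
#' @param frame_interval_s Seconds per frame (default 2).
#' @param tube List `(orientation_deg, width_voxels, intensity,
#'   background)`.
#' @param dilations Data.frame with `onset_frame`, `duration_frames`,
#'   `amplitude_percent`, `rise_frames` (linear rise/fall ramps).
#' @param erythrocyte_rate Expected number of dark intraluminal blobs
#'   per frame (Poisson), emulating passing red blood cells.
#' @param jitter_frames Frame indices translated by `jitter_shift_px`
#'   (motion artifacts).
#' @param jitter_shift_px Integer translation applied to jittered
#'   frames.
#' @param noise_sigma Additive Gaussian noise sd as a fraction of the
#'   tube-background dynamic range (default 0.05).
#' @param pixel_size_um Voxel edge in micrometers.
#' @param seed RNG seed.
#' @return A list of class `"vessel_sim_config"`.
#' @export
vessel_sim_config <- function(shape = c(270L, 128L, 128L),
                              frame_interval_s = 2,
                              tube = list(orientation_deg = 0,
                                          width_voxels = 40,
                                          intensity = 200,
                                          background = 10),
                              dilations = data.frame(
                                onset_frame = c(30, 120, 210),
                                duration_frames = 30,
                                amplitude_percent = 10,
                                rise_frames = 5),
                              erythrocyte_rate = 0.1,
                              jitter_frames = integer(),
                              jitter_shift_px = 8L,
                              noise_sigma = 0.05,
                              pixel_size_um = 1,
                              seed = 1L) {
  stopifnot(length(shape) == 3, all(shape > 0))
  wmax <- tube$width_voxels *
    (1 + max(c(0, dilations$amplitude_percent)) / 100)
  if (wmax >= min(shape[2], shape[3]) / 2) {
    stop("tube (incl. dilation) too wide for the field of view",
         call. = FALSE)
  }
  structure(list(shape = as.integer(shape),
                 frame_interval_s = frame_interval_s, tube = tube,
                 dilations = dilations,
                 erythrocyte_rate = erythrocyte_rate,
                 jitter_frames = as.integer(jitter_frames),
                 jitter_shift_px = as.integer(jitter_shift_px),
                 noise_sigma = noise_sigma,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "vessel_sim_config")
}

#' Simulate a two-photon vessel movie with known ground truth
#'
#' Renders an anti-aliased bright tube of time-varying width
#' `w(t) = w0 * (1 + dilation(t) / 100)` on a dark background
#' (coverage-weighted edges), optionally adds dark intraluminal
#' erythrocyte-like discs, translates jittered frames, and adds
#' Gaussian noise. Deterministic per seed.
#'
#' @param config A [vessel_sim_config()].
#' @return A list: `frames`, `metadata` (modality `"tpm"`), `truth`
#'   (`width_voxels_t`, the true width per frame; `dilations`; tube
#'   geometry).
#' @export
simulate_vessel <- function(config = vessel_sim_config()) {
  stopifnot(inherits(config, "vessel_sim_config"))
  nt <- config$shape[1]; h <- config$shape[2]; w <- config$shape[3]
  tube <- config$tube
  dil <- numeric(nt)
  for (i in seq_len(nrow(config$dilations))) {
    d <- config$dilations[i, ]
    prof <- numeric(nt)
    f <- seq_len(nt)
    rise <- pmax(d$rise_frames, 1e-9)
    up <- f >= d$onset_frame & f < d$onset_frame + d$duration_frames
    prof[up] <- pmin((f[up] - d$onset_frame) / rise, 1)
    down <- f >= d$onset_frame + d$duration_frames &
            f < d$onset_frame + d$duration_frames + d$rise_frames
    prof[down] <- pmax(1 - (f[down] - d$onset_frame - d$duration_frames) /
                         rise, 0)
    dil <- pmax(dil, d$amplitude_percent * prof)
  }
  w_t <- tube$width_voxels * (1 + dil / 100)
  th <- tube$orientation_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # signed distance from pixel center to the tube axis
  dist <- abs(-sin(th) * (cc - cx) + cos(th) * (rr - cy))
  set.seed(config$seed)
  frames <- array(0, c(nt, h, w))
  rng <- tube$intensity - tube$background
  clamp01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  for (k in seq_len(nt)) {
    cov <- clamp01(w_t[k] / 2 - dist + 0.5)
    f <- tube$background + rng * cov
    n_ery <- rpois(1, config$erythrocyte_rate)
    if (n_ery > 0) {
      for (e in seq_len(n_ery)) {
        # a dark disc centered on the axis at a random position
        s <- runif(1, -0.45, 0.45) * max(h, w)
        ey <- cy + s * sin(th); ex <- cx + s * cos(th)
        drad <- runif(1, 1.5, 3)
        dcov <- clamp01(drad - sqrt((rr - ey)^2 + (cc - ex)^2) + 0.5)
        f <- f - 0.7 * rng * cov * dcov
      }
    }
    if (k %in% config$jitter_frames) {
      sh <- shift_frame(f, config$jitter_shift_px, config$jitter_shift_px)
      sh[is.na(sh)] <- tube$background
      f <- sh
    }
    frames[k, , ] <- f + rng * config$noise_sigma * rnorm(h * w)
  }
  md <- stack_metadata(sampling_rate_hz = 1 / config$frame_interval_s,
                       pixel_size_um = config$pixel_size_um,
                       modality = "tpm")
  truth <- list(width_voxels_t = w_t,
                dilations = config$dilations,
                tube = tube, center = c(cy, cx))
  list(frames = frames, metadata = md, truth = truth)
}
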