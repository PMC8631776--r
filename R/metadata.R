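#' Acquisition metadata for an image stack
#'
#' Describes how a time-ordered image stack was acquired. The defaults
#' correspond to the two supported modalities: LSCI perfusion imaging at
#' 4.4 Hz and two-photon (2-PM) time series at one frame per 2 s
#' (0.5 Hz).
#'
#' @param sampling_rate_hz Acquisitions per second. Must be positive.
#' @param pixel_size_um Physical edge length of one pixel/voxel in
#'   micrometers. Must be positive.
#' @param time_origin_s Timestamp of frame 0 in seconds.
#' @param modality Either `"lsci"` or `"tpm"`.
#' @return A list of class `"stack_metadata"`.
#' @export
#' @examples
#' stack_metadata(modality = "tpm")  # 0.5 Hz default
stack_metadata <- function(sampling_rate_hz = NULL,
                           pixel_size_um = 1,
                           time_origin_s = 0,
                           modality = c("lsci", "tpm")) {
  modality <- match.arg(modality)
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- if (modality == "lsci") 4.4 else 0.5
  }
  md <- list(sampling_rate_hz = as.numeric(sampling_rate_hz),
             pixel_size_um = as.numeric(pixel_size_um),
             time_origin_s = as.numeric(time_origin_s),
             modality = modality)
  validate_stack_metadata(md)
  class(md) <- "stack_metadata"
  md
}

validate_stack_metadata <- function(md) {
  if (!is.finite(md$sampling_rate_hz) || md$sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  }
  if (!is.finite(md$pixel_size_um) || md$pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  if (!md$modality %in% c("lsci", "tpm")) {
    stop("modality must be 'lsci' or 'tpm'", call. = FALSE)
  }
  invisible(md)
}

#' @export
print.stack_metadata <- function(x, ...) {
  cat(sprintf("<stack_metadata> %s, %.4g Hz, %.4g um/px, t0 = %.4g s\n",
              x$modality, x$sampling_rate_hz, x$pixel_size_um,
              x$time_origin_s))
  invisible(x)
}

#' Frame times of a stack
#'
#' @param n_frames Number of frames.
#' @param metadata A [stack_metadata()] object.
#' @return Numeric vector of timestamps in seconds (frame 0 at
#'   `time_origin_s`).
#' @export
frame_times <- function(n_frames, metadata) {
  metadata$time_origin_s + (seq_len(n_frames) - 1) / metadata$sampling_rate_hz
}
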