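#' Circular region of interest
#'
#' The analysis region is the exposed cortex inside the cranial window,
#' modeled as a disc: a pixel belongs to the ROI when the distance from
#' its center to `center_px` is at most `radius_px`.
#'
#' @param center_px Numeric length-2 `(row, col)` center in pixel
#'   coordinates (1-based, pixel centers at integers).
#' @param radius_px Radius in pixels.
#' @param dim_hw Integer length-2 frame size `(rows, cols)`.
#' @return A list of class `"roi_mask"` with `center_px`, `radius_px`
#'   and a logical `mask` matrix.
#' @export
roi_mask <- function(center_px, radius_px, dim_hw) {
  stopifnot(length(center_px) == 2, radius_px > 0, length(dim_hw) == 2)
  rr <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  cc <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  mask <- (rr - center_px[1])^2 + (cc - center_px[2])^2 <= radius_px^2
  if (sum(mask) < 9) {
    stop("ROI covers fewer than 9 pixels; enlarge the radius",
         call. = FALSE)
  }
  structure(list(center_px = as.numeric(center_px),
                 radius_px = as.numeric(radius_px), mask = mask),
            class = "roi_mask")
}

#' ROI-mean time course of a stack
#'
#' @param stack Numeric array `time x rows x cols`.
#' @param roi A [roi_mask()].
#' @return Numeric vector, mean over ROI pixels per frame (`NA` pixels
#'   ignored).
#' @export
roi_mean_trace <- function(stack, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  flat <- matrix(stack, nrow = dim(stack)[1])
  rowMeans(flat[, as.vector(roi$mask), drop = FALSE], na.rm = TRUE)
}
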