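# Image resampling and smoothing primitives.
#
# These are written in-package (rather than delegated to a generic
# image library) because the pipeline needs explicit missing-value
# semantics: NA marks pixels outside the ROI or exposed by alignment,
# and both operations must propagate NA deterministically instead of
# smearing arbitrary fill values into valid data.

#' Bilinear resampling with missing-value propagation
#'
#' Resamples a matrix to a new size using bilinear interpolation under
#' the half-pixel-center convention (output pixel center `i - 0.5` in
#' output units maps to `(i - 0.5) * nrow_in / nrow_out` in input
#' units). An output pixel whose four input neighbors include an `NA`
#' becomes `NA`.
#'
#' @param m Numeric matrix.
#' @param out_rows,out_cols Output size.
#' @return Resampled `out_rows x out_cols` matrix.
#' @export
bilinear_resize <- function(m, out_rows, out_cols) {
  h <- nrow(m); w <- ncol(m)
  # input coordinate (1-based pixel centers) of each output pixel center
  yc <- (seq_len(out_rows) - 0.5) * h / out_rows + 0.5
  xc <- (seq_len(out_cols) - 0.5) * w / out_cols + 0.5
  yc <- pmin(pmax(yc, 1), h)
  xc <- pmin(pmax(xc, 1), w)
  y0 <- pmin(floor(yc), h - 1); fy <- yc - y0
  x0 <- pmin(floor(xc), w - 1); fx <- xc - x0
  if (h < 2 || w < 2) stop("input must be at least 2 x 2", call. = FALSE)
  m00 <- m[y0, x0, drop = FALSE];     m01 <- m[y0, x0 + 1, drop = FALSE]
  m10 <- m[y0 + 1, x0, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
  # nested lerp form: exact for constant inputs (weights collapse)
  fxm <- matrix(fx, out_rows, out_cols, byrow = TRUE)
  fym <- matrix(fy, out_rows, out_cols)
  v0 <- m00 + fxm * (m01 - m00)
  v1 <- m10 + fxm * (m11 - m10)
  v0 + fym * (v1 - v0)
}

#' Gaussian smoothing of a single frame
#'
#' Separable Gaussian convolution with edge replication, used to
#' suppress pixel noise before per-frame Otsu binarization. `sigma_px
#' <= 0` returns the input unchanged.
#'
#' @param m Numeric matrix.
#' @param sigma_px Standard deviation in pixels.
#' @return Smoothed matrix.
#' @export
gaussian_smooth <- function(m, sigma_px = 1) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  m <- conv_rows(m, k, r)
  t(conv_rows(t(m), k, r))
}

# 1-D convolution along columns (i.e. down each column) with edge
# replication, vectorized over the other dimension
conv_rows <- function(m, k, r) {
  h <- nrow(m)
  padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                  m[rep(h, r), , drop = FALSE])
  out <- matrix(0, h, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[(j - 1) + seq_len(h), , drop = FALSE]
  }
  out
}
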