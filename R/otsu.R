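#' Otsu threshold of a numeric sample
#'
#' Computes the classic Otsu threshold: the sample is binned into
#' `n_bins` equal-width bins and the bin edge maximizing the
#' between-class variance
#' \deqn{\sigma_B^2(k) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}
#' is returned. Used both to detect stimulation periods on perfusion
#' traces and to binarize two-photon frames.
#'
#' @param x Numeric vector or matrix (`NA` dropped).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value, with attribute
#'   `between_class_variance`. Values strictly greater than the
#'   threshold belong to the upper class. Returns `NA` (with a zero
#'   attribute) for degenerate inputs (constant, or fewer than two
#'   distinct values), which callers should treat as "no foreground".
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  x <- x[!is.na(x)]
  if (length(x) < 2 || diff(range(x)) == 0) {
    return(structure(NA_real_, between_class_variance = 0))
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(cnt)
  m0 <- cumsum(cnt * mids)
  tot <- w0[n_bins]
  mtot <- m0[n_bins]
  k <- seq_len(n_bins - 1L)
  wa <- w0[k]; wb <- tot - wa
  bcv <- rep(-Inf, n_bins - 1L)
  ok <- wa > 0 & wb > 0
  mu0 <- m0[k][ok] / wa[ok]
  mu1 <- (mtot - m0[k][ok]) / wb[ok]
  bcv[ok] <- (wa[ok] / tot) * (wb[ok] / tot) * (mu0 - mu1)^2
  best <- which.max(bcv)
  if (!is.finite(bcv[best]) || bcv[best] <= 0) {
    return(structure(NA_real_, between_class_variance = 0))
  }
  structure(edges[best + 1L], between_class_variance = bcv[best])
}
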