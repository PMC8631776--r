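# Independent brute-force reference implementations used to validate
# the package's optimized code paths, plus small fixture builders.
# These deliberately share no code with the package internals.

# Exhaustive Otsu: assign samples to 256 equal-width bins (represented
# by their midpoints), then loop over every bin edge and compute the
# between-class variance directly with mean() on the split sample.
otsu_bruteforce <- function(x, n_bins = 256L) {
  x <- x[!is.na(x)]
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  v <- mids[bin]
  best_bcv <- -Inf
  best_edge <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    lo <- v[bin <= k]
    hi <- v[bin > k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    w1 <- length(hi) / length(v)
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_edge <- edges[k + 1L]
    }
  }
  best_edge
}

# Naive frame-by-frame dilation peak scan. Walks valid frames with
# plain loops; mirrors the documented state machine, not the package
# code.
peaks_bruteforce <- function(time_s, d, nb = 10L, start_pct = 5,
                             end_pct = 2, min_end = 3L) {
  v <- which(!is.na(d))
  res <- list()
  repeat {
    if (length(v) < nb + 1L) break
    bas <- v[1:nb]
    base <- mean(d[bas])
    tb <- time_s[bas[nb]]
    rest <- v[-(1:nb)]
    if (!is.finite(base) || base <= 0) {
      v <- rest
      next
    }
    open_lvl <- base * (1 + start_pct / 100)
    end_lvl <- base * (1 + end_pct / 100)
    open <- NA_integer_
    for (j in seq_along(rest)) {
      if (d[rest[j]] > open_lvl) { open <- j; break }
    }
    if (is.na(open)) break
    cnt <- 0L
    close_pos <- NA_integer_
    jj <- open
    while (jj <= length(rest)) {
      if (d[rest[jj]] < end_lvl) {
        cnt <- cnt + 1L
        if (cnt == min_end) { close_pos <- jj - min_end; break }
      } else {
        cnt <- 0L
      }
      jj <- jj + 1L
    }
    if (is.na(close_pos)) {
      span <- rest[open:length(rest)]
      nxt <- integer(0)
    } else {
      span <- rest[open:max(close_pos, open)]
      nxt <- if (jj < length(rest)) rest[(jj + 1L):length(rest)] else
        integer(0)
    }
    dmax <- max(d[span])
    imax <- span[which(d[span] == dmax)[1]]
    tm <- time_s[imax]
    res[[length(res) + 1L]] <- data.frame(
      t_start_s = time_s[span[1]], t_end_s = time_s[span[length(span)]],
      time_baseline_s = tb, diameter_baseline_um = base,
      time_max_s = tm, diameter_max_um = dmax,
      slope_per_s = if (tm > tb) ((dmax - base) / (tm - tb)) / base
                    else NA_real_,
      percent_change = 100 * (dmax - base) / base)
    v <- nxt
    if (!length(v)) break
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
               time_baseline_s = numeric(0),
               diameter_baseline_um = numeric(0),
               time_max_s = numeric(0), diameter_max_um = numeric(0),
               slope_per_s = numeric(0), percent_change = numeric(0))
}

# Binary movie of a horizontal tube of the given width, centered so
# that the width maps to exact full rows.
make_tube_binary <- function(n_frames, h, w, width) {
  r0 <- floor((h - width) / 2)
  bin <- array(0L, c(n_frames, h, w))
  bin[, (r0 + 1):(r0 + width), ] <- 1L
  bin
}

# Random diameter-like traces for the peak-detector oracle: baseline
# segments with occasional boxcar/triangular dilations, noise, and
# optional missing frames.
random_diameter_trace <- function(n, seed) {
  set.seed(seed)
  base <- runif(1, 5, 30)
  d <- rep(base, n)
  n_ev <- sample(0:3, 1)
  for (e in seq_len(n_ev)) {
    on <- sample(seq(12, max(13, n - 20)), 1)
    len <- sample(5:25, 1)
    amp <- runif(1, 0.02, 0.4) * base
    shape <- sample(c("box", "tri"), 1)
    idx <- on:min(n, on + len)
    prof <- if (shape == "box") 1 else {
      m <- length(idx)
      1 - abs(seq_len(m) - (m + 1) / 2) / ((m + 1) / 2)
    }
    d[idx] <- d[idx] + amp * prof
  }
  d <- d + rnorm(n, sd = 0.01 * base)
  if (runif(1) < 0.3) d[sample(n, sample(1:3, 1))] <- NA
  data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) * 2,
             diameter_um = d)
}

expect_peaks_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  for (cl in c("t_start_s", "t_end_s", "time_baseline_s",
               "diameter_baseline_um", "time_max_s", "diameter_max_um",
               "slope_per_s", "percent_change")) {
    expect_equal(unname(a[[cl]]), unname(b[[cl]]), tolerance = 1e-12,
                 label = cl)
  }
}
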