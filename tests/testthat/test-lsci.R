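# a small stack where every pixel follows the given trace
trace_stack <- function(trace, h = 8, w = 8) {
  array(rep(trace, h * w), c(length(trace), h, w))
}

test_that("window containers validate their geometry", {
  w <- response_windows()
  expect_equal(w$response_s, c(10, 30))
  expect_equal(w$baseline_s, c(-40, -10))
  expect_error(response_windows(baseline_s = c(-10, 5)), "before")
  expect_error(response_windows(response_s = c(-5, 30)), "after")
})

test_that("stimulation detection finds boxcar epochs at the right onsets", {
  fs <- 4.4
  t <- (0:(660 * fs)) / fs
  onsets <- c(120, 300, 480)
  set.seed(9)
  trace <- 10 * ((t >= 120 & t < 180) + (t >= 300 & t < 360) +
                 (t >= 480 & t < 540)) + rnorm(length(t), sd = 0.3)
  ep <- detect_stimulations(trace, fs)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$source, rep("otsu", 3))
  expect_true(all(abs(ep$onset_s - onsets) * fs <= 2))
  expect_true(all(ep$offset_s - ep$onset_s > 50))
})

test_that("constant and unimodal traces produce no epochs, with a warning", {
  expect_warning(ep <- detect_stimulations(rep(5, 500), 4.4),
                 "degenerate")
  expect_equal(nrow(ep), 0)
})

test_that("short blips are suppressed and short gaps bridged", {
  fs <- 1
  trace <- rep(0, 400)
  trace[100:160] <- 10        # real epoch, 61 s
  trace[125] <- -1            # 1-s dropout inside: bridged
  trace[300:302] <- 10        # 3-s blip: below min duration
  ep <- detect_stimulations(trace, fs, min_duration_s = 5, merge_gap_s = 2)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_s, 99)
  expect_equal(ep$offset_s, 160)
})

test_that("response maps implement the baseline-normalized percent change", {
  fs <- 1
  n <- 200
  roi <- roi_mask(c(4.5, 4.5), 3, c(8, 8))
  ep <- data.frame(onset_s = 100, offset_s = 160)
  w <- response_windows()
  # constant stack: 0 % everywhere inside the ROI
  m <- compute_response_map(trace_stack(rep(7, n)), roi, ep, w, fs)
  expect_true(all(m[roi$mask] == 0))
  expect_true(all(is.na(m[!roi$mask])))
  # step 100 -> 110 over the whole response window: exactly +10 %
  tr <- rep(100, n); tr[111:141] <- 110
  m <- compute_response_map(trace_stack(tr), roi, ep, w, fs)
  expect_equal(unique(m[roi$mask]), 10)
  # ramp reaching its plateau within 10 s: the response window only
  # sees the plateau
  tr <- rep(100, n)
  ramp_idx <- 101:111
  tr[ramp_idx] <- 100 + 12 * (seq_along(ramp_idx) - 1) / 10
  tr[112:n] <- 112
  m <- compute_response_map(trace_stack(tr), roi, ep, w, fs)
  expect_equal(unique(m[roi$mask]), 12)
})

test_that("non-positive baselines flag the pixel missing", {
  fs <- 1
  roi <- roi_mask(c(4.5, 4.5), 3, c(8, 8))
  ep <- data.frame(onset_s = 100, offset_s = 160)
  stk <- trace_stack(rep(5, 200))
  stk[, 4, 4] <- -1
  m <- compute_response_map(stk, roi, ep, response_windows(), fs)
  expect_true(is.na(m[4, 4]))
  expect_equal(attr(m, "n_bad_baseline"), 1L)
})

test_that("standardized maps are exactly 120 x 120 under any valid ROI", {
  for (spec in list(c(20.5, 20.5, 12), c(15, 25, 9.3), c(21, 19, 14))) {
    roi <- roi_mask(spec[1:2], spec[3], c(40, 40))
    m <- matrix(rnorm(1600), 40, 40)
    m[!roi$mask] <- NA
    s <- standardize_map(m, roi)
    expect_identical(dim(s), c(120L, 120L))
    expect_s3_class(s, "response_map")
  }
})

test_that("a constant map standardizes to the same constant", {
  roi <- roi_mask(c(20, 20), 10, c(40, 40))
  m <- matrix(3.25, 40, 40)
  s <- standardize_map(m, roi)
  vals <- unique(as.vector(s))
  vals <- vals[!is.na(vals)]
  expect_identical(vals, 3.25)
})

test_that("resampling preserves a smooth blob's peak location", {
  h <- 61
  ctr <- c(22, 41)
  rr <- matrix(seq_len(h), h, h)
  cc <- t(rr)
  blob <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * 8^2))
  up <- bilinear_resize(blob, 120, 120)
  back <- bilinear_resize(up, h, h)
  peak <- arrayInd(which.max(back), dim(back))
  expect_true(all(abs(peak - ctr) <= 1))
  # and in the upscaled map the peak sits at the mapped coordinates
  peak_up <- arrayInd(which.max(up), dim(up))
  mapped <- (ctr - 0.5) * 120 / h + 0.5
  expect_true(all(abs(peak_up - mapped) <= 1.5))
})

test_that("map averaging is an identity for one map and unbiased for pairs", {
  roi <- roi_mask(c(20, 20), 10, c(40, 40))
  base <- matrix(rnorm(1600), 40, 40)
  m1 <- standardize_map(base, roi)
  expect_equal(unclass(average_maps(list(m1))), unclass(m1))
  m_plus <- standardize_map(matrix(5, 40, 40), roi)
  m_minus <- standardize_map(matrix(-5, 40, 40), roi)
  avg <- average_maps(list(m_plus, m_minus))
  vals <- unique(as.vector(avg)); vals <- vals[!is.na(vals)]
  expect_equal(vals, 0)
  expect_equal(attr(avg, "n_stimulations_averaged"), 2L)
})

test_that("map averaging is order-invariant and NA-aware", {
  roi <- roi_mask(c(10, 10), 6, c(20, 20))
  maps <- lapply(c(2, 4, 9), function(v) {
    standardize_map(matrix(v, 20, 20), roi)
  })
  # poke a missing pixel into one map
  maps[[2]][5, 5] <- NA
  a <- average_maps(maps)
  b <- average_maps(rev(maps))
  expect_identical(unclass(a), unclass(b))
  expect_equal(a[5, 5], mean(c(2, 9)))  # mean over available values
  n_anim <- attr(average_maps(maps, "across_animals"),
                 "n_animals_averaged")
  expect_equal(n_anim, 3L)
  expect_error(average_maps(list()), "no maps")
})

test_that("scalar metrics reproduce closed-form cases", {
  fs <- 1
  n <- 400
  t <- 0:(n - 1)
  ep <- data.frame(onset_s = 100, offset_s = 160)
  w <- response_windows()
  # instantaneous +10 % boxcar; baseline window ends 10 s before onset
  tr <- numeric(n); tr[t >= 100 & t < 160] <- 10
  sm <- scalar_metrics(tr, fs, ep, w)
  expect_equal(sm$peak_percent, 10)
  expect_equal(sm$slope_percent_per_s, 10 / 10)  # peak at onset, 1.0 %/s
  # triangular bump height 8, base 40: AUC = 8 * 40 / 2
  tr2 <- numeric(n)
  bump <- 110:150
  tr2[bump + 1] <- 8 * (1 - abs(bump - 130) / 20)
  sm2 <- scalar_metrics(tr2, fs, ep, w, auc_window_s = c(110, 150))
  expect_equal(sm2$auc_percent_s, 8 * 40 / 2, tolerance = 1e-10)
  # linear ramp 0 -> a across the epoch
  a <- 14
  tr3 <- numeric(n)
  idx <- t >= 100 & t <= 160
  tr3[idx] <- a * (t[idx] - 100) / 60
  tr3[t > 160] <- 0
  sm3 <- scalar_metrics(tr3, fs, ep, w)
  expect_equal(sm3$peak_percent, a)
  expect_equal(sm3$slope_percent_per_s, a / (160 - 90))
})

test_that("a peak at the baseline end leaves the slope undefined", {
  fs <- 1
  tr <- c(rep(10, 100), rep(0, 100))
  ep <- data.frame(onset_s = 90, offset_s = 99)
  expect_warning(
    sm <- scalar_metrics(tr, fs, ep,
                         response_windows(baseline_s = c(-40, 0))),
    "slope undefined")
  expect_true(is.na(sm$slope_percent_per_s))
})

test_that("trace normalization divides by the baseline-window mean", {
  fs <- 1
  tr <- c(rep(200, 100), rep(220, 100))
  ep <- data.frame(onset_s = 100, offset_s = 160)
  z <- normalize_trace(tr, fs, ep)
  expect_equal(z[1], 0)
  expect_equal(z[150], 10)
})
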