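tpm_md <- function(px = 1) stack_metadata(pixel_size_um = px,
                                          modality = "tpm")

test_that("binarization labels a clean tube exactly", {
  h <- 64; w <- 64
  frames <- array(10, c(2, h, w))
  frames[, 25:40, ] <- 200
  bin <- binarize_movie(frames, smoothing_sigma_px = 0)
  expect_true(all(bin[, 25:40, ] == 1L))
  expect_true(all(bin[, c(1:24, 41:h), ] == 0L))
  # all-background frame binarizes to all zeros under a fixed threshold
  flat <- array(10, c(1, h, w))
  b0 <- binarize_movie(flat, method = "fixed", fixed_threshold = 100)
  expect_true(all(b0 == 0L))
  # constant frame under Otsu: all zero with a warning
  expect_warning(b1 <- binarize_movie(flat), "constant")
  expect_true(all(b1 == 0L))
})

test_that("per-frame Otsu binarization matches the exhaustive search", {
  set.seed(21)
  for (rep in 1:5) {
    f <- matrix(c(rnorm(600, 20, 5), rnorm(424, 180, 20)), 32, 32)
    bin <- binarize_movie(array(f, c(1, 32, 32)), smoothing_sigma_px = 0)
    thr <- attr(bin, "thresholds")[1]
    expect_equal(thr, otsu_bruteforce(as.vector(f)), tolerance = 1e-12)
  }
})

test_that("diameters of axis-aligned tubes are exact, and scale with voxel size", {
  h <- 101; w <- 101
  ln <- measurement_line(c(10, 51), c(92, 51))
  for (width in c(3, 7, 10, 17, 24, 30)) {
    bin <- make_tube_binary(2, h, w, width)
    tr <- measure_diameter(bin, ln, tpm_md())
    expect_equal(tr$diameter_um, rep(width, 2))
    tr08 <- measure_diameter(bin, ln, tpm_md(0.8))
    expect_equal(tr08$diameter_um, rep(width * 0.8, 2))
  }
})

test_that("45-degree tubes are recovered within the rasterization bound", {
  h <- 101; w <- 101
  ln <- measurement_line(c(30, 72), c(72, 30))  # perpendicular to axis
  for (width in c(6, 10, 20, 30)) {
    mask <- abs(outer(1:h, 1:w, "-")) <= width * sqrt(2) / 2
    bin <- array(0L, c(1, h, w)); bin[1, , ] <- mask * 1L
    tr <- measure_diameter(bin, ln, tpm_md())
    expect_lt(abs(tr$diameter_um[1] - width), 1.5)
  }
})

test_that("4-line averaging damps a single-voxel erythrocyte gap", {
  h <- 101; w <- 101
  width <- 12
  bin <- make_tube_binary(1, h, w, width)
  # dark voxel on the central line only
  r0 <- floor((h - width) / 2)
  bin[1, r0 + 5, 51] <- 0L
  thick <- measurement_line(c(10, 51), c(92, 51), thickness_voxels = 4)
  thin <- measurement_line(c(10, 51), c(92, 51), thickness_voxels = 1)
  d4 <- measure_diameter(bin, thick, tpm_md())$diameter_um[1]
  d1 <- measure_diameter(bin, thin, tpm_md())$diameter_um[1]
  expect_equal(d1, width - 1)             # full 1-voxel error at k = 1
  expect_equal(d4, width - 1 / 4)         # (1/k) voxel error at k = 4
})

test_that("a line outside the vessel reports diameter 0", {
  bin <- make_tube_binary(1, 101, 101, 8)
  ln <- measurement_line(c(2, 5), c(20, 5))
  # tube occupies central rows; this line crosses only background rows?
  # rows 2..20 include tube rows, so use columns far away instead
  ln <- measurement_line(c(2, 5), c(2, 60))
  tr <- measure_diameter(bin, ln, tpm_md())
  expect_equal(tr$diameter_um[1], 0)
  expect_error(measure_diameter(bin, measurement_line(c(0, 5), c(5, 5)),
                                tpm_md()), "outside")
})

test_that("excluded frames are flagged missing in the trace", {
  bin <- make_tube_binary(5, 51, 51, 10)
  ln <- measurement_line(c(5, 26), c(46, 26))
  tr <- measure_diameter(bin, ln, tpm_md(), excluded_frames = c(2, 4))
  expect_true(all(is.na(tr$diameter_um[c(2, 4)])))
  expect_true(all(tr$diameter_um[c(1, 3, 5)] == 10))
})

test_that("peak parameters validate their ordering", {
  expect_error(peak_params(start_threshold_percent = 2,
                           end_threshold_percent = 5), "start_threshold")
  expect_error(peak_params(n_baseline_frames = 0), "n_baseline")
})

test_that("a constant trace contains no peaks", {
  tr <- data.frame(time_s = (0:99) * 2, diameter_um = rep(12, 100))
  expect_equal(nrow(detect_peaks(tr)), 0)
})

test_that("the worked dilation example gives percent 20 and slope 0.02", {
  # 10 um baseline over frames 0-9, linear rise to 12 um at t = 28 s
  # (frame 14), back to 10 um; one frame per 2 s
  d <- c(rep(10, 10), 10.4, 10.8, 11.2, 11.6, 12, rep(10, 10))
  tr <- data.frame(time_s = (seq_along(d) - 1) * 2, diameter_um = d)
  pk <- detect_peaks(tr, peak_params())
  expect_equal(nrow(pk), 1)
  expect_equal(pk$diameter_baseline_um, 10)
  expect_equal(pk$time_baseline_s, 18)
  expect_equal(pk$diameter_max_um, 12)
  expect_equal(pk$time_max_s, 28)
  expect_equal(pk$percent_change, 20.0)
  expect_equal(pk$slope_per_s, ((12 - 10) / (28 - 18)) / 10)  # 0.02
})

test_that("the baseline is re-tracked between separated dilations", {
  # two boxcar dilations with a baseline step in between
  d <- c(rep(10, 12), rep(12, 8), rep(10, 6),
         rep(11, 12),               # drifted baseline
         rep(13.5, 8), rep(11, 10))
  tr <- data.frame(time_s = (seq_along(d) - 1) * 2, diameter_um = d)
  pk <- detect_peaks(tr, peak_params())
  expect_equal(nrow(pk), 2)
  expect_equal(pk$diameter_baseline_um[1], 10)
  expect_gt(pk$diameter_baseline_um[2], 10)  # recomputed after peak 1
  oracle <- peaks_bruteforce(tr$time_s, tr$diameter_um)
  expect_peaks_equal(as.data.frame(pk), oracle)
})

test_that("the peak detector matches the brute-force scan on random traces", {
  grids <- expand.grid(seed = 1:15, n = c(80, 200, 300))
  for (g in seq_len(nrow(grids))) {
    tr <- random_diameter_trace(grids$n[g], seed = 1000 + g)
    for (p in list(peak_params(),
                   peak_params(n_baseline_frames = 5,
                               start_threshold_percent = 3,
                               end_threshold_percent = 1,
                               min_end_frames = 2))) {
      got <- suppressWarnings(detect_peaks(tr, p))
      ora <- suppressWarnings(peaks_bruteforce(
        tr$time_s, tr$diameter_um, nb = p$n_baseline_frames,
        start_pct = p$start_threshold_percent,
        end_pct = p$end_threshold_percent,
        min_end = p$min_end_frames))
      expect_peaks_equal(as.data.frame(got), ora)
    }
  }
})

test_that("emitted peaks satisfy the percent-change and slope identities", {
  for (seed in 1:10) {
    tr <- random_diameter_trace(150, seed = seed)
    pk <- suppressWarnings(detect_peaks(tr))
    if (!nrow(pk)) next
    expect_equal(pk$percent_change,
                 100 * (pk$diameter_max_um - pk$diameter_baseline_um) /
                   pk$diameter_baseline_um)
    def <- !is.na(pk$slope_per_s)
    expect_equal(pk$slope_per_s[def],
                 ((pk$diameter_max_um - pk$diameter_baseline_um) /
                    (pk$time_max_s - pk$time_baseline_s) /
                    pk$diameter_baseline_um)[def])
    expect_true(all(pk$t_start_s <= pk$time_max_s &
                    pk$time_max_s <= pk$t_end_s))
  }
})

test_that("artifact frames are suggested by motion and SNR rules", {
  cfg <- vessel_sim_config(shape = c(20L, 96L, 96L),
                           tube = list(orientation_deg = 0,
                                       width_voxels = 20, intensity = 200,
                                       background = 10),
                           dilations = data.frame(onset_frame = integer(0),
                                                  duration_frames = integer(0),
                                                  amplitude_percent = numeric(0),
                                                  rise_frames = integer(0)),
                           erythrocyte_rate = 0, noise_sigma = 0.02,
                           jitter_frames = 11L, seed = 4)
  sim <- simulate_vessel(cfg)
  flagged <- flag_artifact_frames(sim$frames)
  expect_true(11 %in% flagged)
  expect_false(12 %in% flagged)   # the successor is innocent
  # clean movie: nothing suggested
  cfg0 <- cfg; cfg0$jitter_frames <- integer(0)
  clean <- simulate_vessel(cfg0)
  expect_length(flag_artifact_frames(clean$frames), 0)
  # a pure-noise frame is caught by the SNR rule
  noisy <- clean$frames
  noisy[7, , ] <- rnorm(96 * 96, 0, 30)
  fl <- flag_artifact_frames(noisy)
  expect_true(7 %in% fl)
  det <- attr(fl, "details")
  expect_lt(det$snr[7], 2)
  # user-supplied exclusions are always unioned in
  expect_true(3 %in% flag_artifact_frames(clean$frames,
                                          excluded_frames = 3L))
})

test_that("per-class summaries aggregate peaks and handle empty classes", {
  pk1 <- data.frame(percent_change = 20, slope_per_s = 0.02)
  pk2 <- data.frame(percent_change = c(10, 30),
                    slope_per_s = c(0.01, 0.03))
  none <- pk1[0, ]
  s <- summarize_segments(list(pk1, pk2, none),
                          c("capillary", "capillary", "pial"))
  cap <- s[s$vessel_class == "capillary", ]
  expect_equal(cap$n_peaks, 3L)
  expect_equal(cap$mean_percent_change, 20)
  expect_equal(cap$max_percent_change, 30)
  pial <- s[s$vessel_class == "pial", ]
  expect_equal(pial$n_peaks, 0L)
  expect_true(is.na(pial$mean_percent_change))
  # permutation invariance
  s2 <- summarize_segments(list(pk2, none, pk1),
                           c("capillary", "pial", "capillary"))
  expect_equal(s2[s2$vessel_class == "capillary", "mean_percent_change"],
               20)
})
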