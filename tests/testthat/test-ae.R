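test_that("FFT spectrum localises tones and conserves energy", {
  rate <- 1e6
  n <- 1e5
  t <- (0:(n - 1)) / rate
  rec <- ae_recording(sin(2 * pi * 140e3 * t), rate = rate)
  sp <- compute_fft_spectrum(rec)
  expect_equal(sp$freqs[which.max(sp$magnitudes)], 140e3)
  expect_equal(max(sp$magnitudes), 1, tolerance = 1e-6)

  zero <- compute_fft_spectrum(ae_recording(rep(0, 1000), rate = rate))
  expect_equal(zero$magnitudes, rep(0, 501))

  # Parseval: time-domain energy equals spectral energy
  set.seed(1)
  x <- rnorm(4096)
  X <- fft(x)
  expect_equal(sum(x^2), sum(Mod(X)^2) / length(x), tolerance = 1e-9)
  expect_error(compute_fft_spectrum(ae_recording(1, rate = rate)), "2 samples")
})

test_that("windowed RMS equals the defining equation", {
  # constant signal
  rec <- ae_recording(rep(-0.3, 5000), rate = 1e5)
  expect_equal(compute_rms_profile(rec, 1000)$values, rep(0.3, 5))

  # sinusoid with integer cycles per window -> A/sqrt(2)
  rate <- 2e5
  t <- (0:(2e4 - 1)) / rate
  A <- 1.7
  rec2 <- ae_recording(A * sin(2 * pi * 500 * t), rate = rate)
  p <- compute_rms_profile(rec2, 2000)   # 5 cycles per window
  expect_equal(p$values, rep(A / sqrt(2), 10), tolerance = 1e-6)

  # brute-force oracle on random waveforms
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3000:9000, 1))
    w <- sample(c(250, 500, 1000), 1)
    rec3 <- ae_recording(x, rate = 1e5)
    expect_equal(compute_rms_profile(rec3, w)$values, oracle_rms(x, w),
                 tolerance = 1e-12)
  }
  # trailing partial window dropped and reported
  p4 <- compute_rms_profile(ae_recording(rnorm(1050), 1e5), 500)
  expect_length(p4$values, 2)
  expect_equal(attr(p4, "n_dropped_samples"), 50)
  expect_error(compute_rms_profile(ae_recording(rnorm(10), 1e5), 0), ">= 1")
})

test_that("windowing conserves the analysed prefix", {
  set.seed(6)
  x <- rnorm(2750)
  w <- 500
  nw <- length(x) %/% w
  # full windows concatenated reconstruct the analysed prefix exactly
  prefix <- as.vector(matrix(x[1:(nw * w)], nrow = w))
  expect_identical(prefix, x[1:(nw * w)])
})

test_that("RMS features scale homogeneously with waveform amplitude", {
  m <- fab(band = 0.4, oob = 0.05)
  plan <- quick_plan(seed = 12, duration = 2, n_strokes = 4, ae_rate = 4e5)
  rec <- synthesize_ae_recording(m, plan)
  k <- 3.7
  rec2 <- ae_recording(k * rec$samples, rec$rate, rec$meta)
  p1 <- compute_rms_profile(rec, 4000)
  p2 <- compute_rms_profile(rec2, 4000)
  expect_equal(p2$values, k * p1$values, tolerance = 1e-12)
  b1 <- band_percentile(compute_fft_spectrum(rec))
  b2 <- band_percentile(compute_fft_spectrum(rec2))
  expect_equal(b2, k * b1, tolerance = 1e-9)
  # both stroke statistics double when the waveform doubles
  st <- segment_rms_strokes(p1, mode = "self")
  f1 <- extract_stroke_rms(st, p1)
  f2 <- extract_stroke_rms(st, p2)
  expect_equal(f2$static_rms, 2 / 2 * k * f1$static_rms, tolerance = 1e-12)
  expect_equal(f2$dynamic_rms, k * f1$dynamic_rms, tolerance = 1e-12)
})

test_that("band percentile matches the order-statistic oracle and band position matters", {
  freqs <- seq(0, 250e3, by = 100)
  mags <- rep(0.2, length(freqs))
  sp <- structure(list(freqs = freqs, magnitudes = mags,
                       normalization = "amplitude", smoothed = FALSE,
                       segmented = FALSE, rate = 5e5, meta = list()),
                  class = "spectral_profile")
  expect_equal(band_percentile(sp), 0.2)   # constant in band -> the constant

  in_band <- sp$freqs >= 120e3 & sp$freqs <= 160e3
  sp$magnitudes[in_band] <- seq(0, 1, length.out = sum(in_band))
  expect_equal(band_percentile(sp),
               oracle_percentile(seq(0, 1, length.out = sum(in_band)), 90),
               tolerance = 1e-12)
  expect_error(band_percentile(sp, band = c(300e3, 400e3)), "band")

  # an in-band tone raises the feature above the same tone out of band
  rate <- 1e6; n <- 5e5
  t <- (0:(n - 1)) / rate
  set.seed(9)
  noise <- rnorm(n, sd = 0.01)
  p140 <- band_percentile(compute_fft_spectrum(
    ae_recording(sin(2 * pi * 140e3 * t) + noise, rate)))
  p200 <- band_percentile(compute_fft_spectrum(
    ae_recording(sin(2 * pi * 200e3 * t) + noise, rate)))
  expect_gt(p140, p200)
})

test_that("spectrum smoothing removes singular peaks and nothing else", {
  n <- 2001
  freqs <- seq(0, 2e5, length.out = n)
  base <- rep(0.001, n)
  base[1000] <- 0.02                       # singular one-bin spike
  bump <- exp(-((seq_len(n) - 1600)^2) / (2 * 30^2)) * 0.5
  mags <- base + bump                      # broad peak, prominence ~0.5
  mags[200] <- 1                           # normalization anchor (peak = 1)
  sp <- structure(list(freqs = freqs, magnitudes = mags,
                       normalization = "amplitude", smoothed = FALSE,
                       segmented = FALSE, rate = 4e5, meta = list()),
                  class = "spectral_profile")
  out <- smooth_spectrum(sp, min_distance_bins = 100)
  expect_true(out$smoothed)
  expect_equal(attr(out, "n_removed"), 1)
  expect_lt(out$magnitudes[1000], 0.0011)          # spike replaced by baseline
  expect_equal(out$magnitudes[1001], mags[1001])   # neighbour untouched
  expect_equal(out$magnitudes[1600], mags[1600])   # broad peak retained
  # bins far from the removed spike are bit-identical
  far <- c(1:890, 1110:n)
  expect_identical(out$magnitudes[far], mags[far])
  # no magnitude ever increases
  expect_true(all(out$magnitudes <= mags + 1e-15))

  flat <- sp; flat$magnitudes <- rep(0.5, n)
  out2 <- smooth_spectrum(flat, min_distance_bins = 100)
  expect_equal(out2$magnitudes, flat$magnitudes)   # flat spectrum unchanged

  expect_error(smooth_spectrum(sp, min_distance_bins = n), "distance")
})

test_that("stroke transfer from the force domain matches friction segmentation", {
  m <- fab()
  plan <- quick_plan(seed = 21, duration = 4, n_strokes = 6, ae_rate = 4e5)
  sim <- simulate_trial(m, plan)
  ff <- friction_features(sim$force$recording)
  rms <- compute_rms_profile(sim$ae, window_samples = 4000)
  st <- segment_rms_strokes(rms, mode = "transfer", strokes = ff$strokes,
                            force_rate = plan$force_rate)
  expect_equal(nrow(st), nrow(ff$strokes))
  # self mode finds the same number of envelope cycles on fabric-like data
  st_self <- segment_rms_strokes(rms, mode = "self")
  expect_equal(nrow(st_self), plan$n_strokes)
  expect_error(segment_rms_strokes(rms, mode = "transfer"), "stroke table")
})

test_that("profiles without valley structure raise a not-segmentable error", {
  set.seed(14)
  flat <- compute_rms_profile(ae_recording(rnorm(1e5), rate = 4e5), 4000)
  expect_error(segment_rms_strokes(flat, mode = "self"), "not segmentable")
})

test_that("AE band percentile orders materials inversely to dynamic COF", {
  mats <- default_materials()
  mu <- vapply(mats, function(m) m$mu_dynamic, numeric(1))
  p90 <- vapply(mats, function(m) {
    plan <- quick_plan(seed = 17, duration = 1, n_strokes = 2, ae_rate = 4e5)
    rec <- synthesize_ae_recording(m, plan)
    band_percentile(compute_fft_spectrum(rec))
  }, numeric(1))
  expect_equal(order(p90), rev(order(mu)))
})
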