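test_that("zero-variability specs give perfectly regular intervals", {
  ibis <- generate_ibi_series(synthetic_spec(60, 0, duration_s = 30, seed = 1))
  expect_true(all(ibis == 1000))
})

test_that("interval means track the requested heart rate", {
  for (seed in 1:20) {
    ibis <- generate_ibi_series(synthetic_spec(60, 40, duration_s = 300,
                                               seed = seed))
    expect_lt(abs(mean(ibis) - 1000), 10)  # within 1%
  }
})

test_that("realized RMSSD concentrates around the target (Monte Carlo)", {
  realized <- vapply(1:100, function(seed) {
    ibis <- generate_ibi_series(synthetic_spec(60, 50, duration_s = 300,
                                               seed = 7000 + seed))
    compute_time_domain(ibis)$rmssd
  }, numeric(1))
  expect_true(all(abs(realized - 50) < 10))
  expect_lt(abs(mean(realized) - 50), 2)
})

test_that("infeasible RMSSD/BPM combinations error", {
  expect_error(generate_ibi_series(synthetic_spec(200, 160, seed = 1)),
               "infeasible")
})

test_that("noiseless PPG local maxima sit on the labelled beats", {
  rec <- simulate_recording(synthetic_spec(75, 40, duration_s = 60, seed = 2))
  x <- rec$signal$samples
  n <- length(x)
  locmax <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  locmax <- locmax[x[locmax] > 0.5]  # systolic crests only
  tmax <- (locmax - 1) / 1000
  expect_equal(length(tmax), length(rec$beat_times))
  expect_lt(max(abs(tmax - rec$beat_times)), 0.005)
})

test_that("ECG beats render three maxima with a dominant R wave", {
  beats <- c(1, 1.8, 2.6, 3.4)
  sig <- render_waveform(beats, 4.5, 1000, "ecg")
  x <- sig$samples
  n <- length(x)
  locmax <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  locmax <- locmax[x[locmax] > 0.05]
  expect_equal(length(locmax), 3 * length(beats))
  for (b in beats) {
    idx <- locmax[abs((locmax - 1) / 1000 - b) < 0.4]
    r <- max(x[idx])
    others <- sort(x[idx], decreasing = TRUE)[-1]
    expect_true(all(r >= 3 * others))
  }
})

test_that("full pipeline with clustering recovers only the R events", {
  rec <- simulate_recording(synthetic_spec(65, 25, duration_s = 30,
                                           modality = "ecg", seed = 12))
  st <- analysis_settings(
    detection = detection_settings(ecg_prt_clustering = TRUE),
    outliers = resolve_preset("liberal"))
  res <- analyze(preprocess(rec$signal), st)
  # every window's beat count matches the labelled beats inside it
  for (i in seq_len(nrow(res))) {
    o <- res$onset_s[i]
    truth <- sum(rec$beat_times >= o & rec$beat_times < o + 10)
    expect_lte(abs(res$n_peaks[i] - truth), 1)
  }
  expect_true(all(abs(uncleaned(res)$bpm - rec$true_bpm) < 3))
})

test_that("added noise realizes the requested SNR", {
  rec <- simulate_recording(synthetic_spec(70, 30, duration_s = 300, seed = 4))
  x <- rec$signal$samples
  for (snr in c(0.01, 10, 30)) {
    noisy <- add_white_noise(rec$signal, snr, seed = 9)
    noise <- noisy$samples - x
    p_sig <- mean((x - mean(x))^2)
    realized <- 10 * log10(p_sig / mean(noise^2))
    expect_lt(abs(realized - snr), 0.1)
  }
  # near-zero dB: noise power ~ signal power
  noisy <- add_white_noise(rec$signal, 0.01, seed = 9)
  noise <- noisy$samples - x
  expect_equal(mean(noise^2) / mean((x - mean(x))^2), 1, tolerance = 0.02)

  expect_identical(add_white_noise(rec$signal, 20, seed = 3)$samples,
                   add_white_noise(rec$signal, 20, seed = 3)$samples)
})

test_that("identical specs reproduce identical recordings", {
  a <- simulate_recording(synthetic_spec(80, 40, duration_s = 20,
                                         snr_db = 15, seed = 101))
  b <- simulate_recording(synthetic_spec(80, 40, duration_s = 20,
                                         snr_db = 15, seed = 101))
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$beat_times, b$beat_times)
})

test_that("stored truth is self-consistent with the metrics formulas", {
  rec <- simulate_recording(synthetic_spec(90, 60, duration_s = 120, seed = 6))
  expect_equal(rec$true_bpm, compute_bpm(rec$beat_times))
  expect_equal(rec$true_rmssd_ms,
               compute_time_domain(ibi_ms(rec$beat_times))$rmssd)
})

test_that("downsampling preserves constants, sines, and grid length", {
  const <- raw_signal(rep(2.5, 300000), 1000)
  ds <- downsample(const, 250)
  expect_equal(length(ds$samples), ceiling(300 * 250))
  expect_equal(ds$samples, rep(2.5, length(ds$samples)), tolerance = 1e-6)

  sine <- make_sine(1, 1000, 30)
  ds <- downsample(sine, 250)
  t1 <- (seq_along(ds$samples) - 1) / 250
  expect_lt(max(abs(ds$samples - sin(2 * pi * t1))), 1e-3)

  # broadband noise keeps its power through decimation (aliasing, by design)
  noisy <- add_white_noise(make_sine(1, 1000, 30), 0.01, seed = 2)
  noise_hi <- noisy$samples - sine$samples
  noise_lo <- downsample(noisy, 250)$samples - ds$samples
  expect_equal(mean(noise_lo^2), mean(noise_hi^2), tolerance = 0.1)

  expect_error(downsample(sine, 2000), "below the current rate")
})
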