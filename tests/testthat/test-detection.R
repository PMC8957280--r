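test_that("window scaling maps min to 0 and max to 100", {
  expect_equal(scale_window(c(0, 5, 10)), c(0, 50, 100))
  expect_equal(scale_window(c(2, 4, 3, 8)),
               100 * (c(2, 4, 3, 8) - 2) / 6, tolerance = 1e-12)
  expect_error(scale_window(c(-3, -3, -3)), "degenerate window",
               class = "pulseline_degenerate_window")
})

test_that("scaling is idempotent and absorbs positive affine transforms", {
  withr::with_seed(4, x <- rnorm(200))
  s1 <- scale_window(x)
  expect_equal(scale_window(s1), s1, tolerance = 1e-12)
  expect_equal(scale_window(3.2 * x + 17), s1, tolerance = 1e-9)
})

test_that("a raised 1 Hz sine yields one peak per second", {
  x <- make_raised_sine(10, 100)
  pk <- detect_peaks(x, 100)
  expect_equal(nrow(pk), 10)
  expect_equal(diff(pk$time), rep(1, 9), tolerance = 0.02)
  expect_true(all(diff(pk$time) >= 0.25))
})

test_that("minimum distance keeps only the taller of two close crests", {
  # two crests 100 ms apart, heights 100 and 80, on a flat floor
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)
  x <- 100 * exp(-(t - 1.0)^2 / (2 * 0.02^2)) +
        80 * exp(-(t - 1.1)^2 / (2 * 0.02^2))
  pk <- detect_peaks(scale_window(x), rate,
                     settings = detection_settings(min_distance_ms = 250))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time, 1.0, tolerance = 0.01)
})

test_that("amplitude threshold gates peaks at the configured height", {
  rate <- 500
  t <- seq(0, 4, by = 1 / rate)
  # crest of scaled height 40 next to a full-height crest
  x <- 100 * exp(-(t - 1)^2 / (2 * 0.03^2)) + 40 * exp(-(t - 2.5)^2 / (2 * 0.03^2))
  sc <- scale_window(x)
  at50 <- detect_peaks(sc, rate, settings = detection_settings(min_amplitude = 50))
  at30 <- detect_peaks(sc, rate, settings = detection_settings(min_amplitude = 30))
  expect_equal(nrow(at50), 1)
  expect_equal(nrow(at30), 2)
})

test_that("peak properties satisfy their invariants on noisy windows", {
  for (seed in 1:5) {
    rec <- simulate_recording(synthetic_spec(75, 40, duration_s = 10,
                                             snr_db = 25, seed = seed))
    prep <- preprocess(rec$signal)
    pk <- detect_peaks(scale_window(prep$samples), 1000)
    expect_true(all(diff(pk$time) > 0))
    expect_true(all(pk$prominence >= 0))
    expect_true(all(pk$prominence <= pk$height + 1e-9))
    expect_true(all(pk$height <= 100))
    expect_true(all(diff(pk$time) >= 0.25))
  }
})

test_that("detected peaks recover labelled beats at high SNR", {
  # parameter-recovery property: >= 99% of beats within +/- 10 ms
  hits <- 0; total <- 0
  for (seed in 1:3) {
    rec <- simulate_recording(synthetic_spec(80, 30, duration_s = 60,
                                             sampling_rate_hz = 100,
                                             snr_db = 30, seed = 100 + seed))
    prep <- preprocess(rec$signal)
    res_times <- c()
    for (onset in seq(0, 40, by = 10)) {
      i0 <- round(onset * 1000) + 1
      seg <- prep$samples[i0:(i0 + 9999)]
      pk <- detect_peaks(scale_window(seg), 1000, onset = onset)
      res_times <- c(res_times, pk$time)
    }
    for (b in rec$beat_times[rec$beat_times < 49.5]) {
      total <- total + 1
      if (any(abs(res_times - b) <= 0.010)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("k-means clustering isolates the narrow high-prominence group", {
  # three synthetic feature groups; oracle = exhaustive best 3-partition
  make_group <- function(n, width, prom, t0) {
    tibble::tibble(time = t0 + seq_len(n) * 0.9,
                   height = prom + 5, prominence = prom, width = width)
  }
  peaks <- rbind(make_group(3, 0.03, 90, 0),
                 make_group(3, 0.12, 20, 0.3),
                 make_group(3, 0.10, 15, 0.6))
  peaks <- peaks[order(peaks$time), ]
  class(peaks) <- c("peak_set", class(peaks))

  out <- classify_ecg_peaks(peaks)
  expect_false(attr(out, "clustering_fallback"))
  expect_equal(nrow(out), 3)
  expect_true(all(out$width < 0.05))

  # exhaustive oracle: minimize within-cluster SS over all 3-label assignments
  z <- scale(cbind(peaks$width, peaks$height, peaks$prominence))
  n <- nrow(z)
  best_ss <- Inf; best_lab <- NULL
  grid <- expand.grid(rep(list(1:3), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < 3) next
    ss <- sum(sapply(1:3, function(cl) {
      pts <- z[lab == cl, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }))
    if (ss < best_ss) { best_ss <- ss; best_lab <- lab }
  }
  centers <- sapply(1:3, function(cl) colMeans(z[best_lab == cl, , drop = FALSE]))
  oracle_cluster <- which.max(centers[3, ] - centers[1, ])
  oracle_times <- peaks$time[best_lab == oracle_cluster]
  expect_equal(sort(out$time), sort(oracle_times))
})

test_that("clustering falls back gracefully on degenerate features", {
  peaks <- tibble::tibble(time = seq(0, 5, by = 0.8), height = 60,
                          prominence = 55, width = 0.05)
  class(peaks) <- c("peak_set", class(peaks))
  out <- classify_ecg_peaks(peaks)
  expect_true(attr(out, "clustering_fallback"))
  expect_equal(nrow(out), nrow(peaks))  # all above the default threshold

  few <- peaks[1:4, ]
  class(few) <- c("peak_set", class(few))
  expect_true(attr(classify_ecg_peaks(few), "clustering_fallback"))
})

test_that("end-to-end ECG clustering returns only R waves", {
  rec <- simulate_recording(synthetic_spec(70, 20, duration_s = 12,
                                           modality = "ecg", seed = 21))
  prep <- preprocess(rec$signal)
  sc <- scale_window(prep$samples[1:10000])
  st <- detection_settings(ecg_prt_clustering = TRUE)
  cand <- detect_peaks(sc, 1000, settings = st)
  expect_gt(nrow(cand), sum(rec$beat_times < 10))  # P/T waves detected too
  rw <- classify_ecg_peaks(cand, st)
  truth <- rec$beat_times[rec$beat_times < 10]
  expect_equal(nrow(rw), length(truth))
  expect_true(all(abs(rw$time - truth) < 0.02))
})

test_that("edge-amplitude re-imputation touches only the first and last peaks", {
  peaks <- tibble::tibble(
    time = c(0.5, 1.5, 2.5, 3.5),
    height = c(90, 95, 92, 88),
    prominence = c(40, 85, 83, 30),  # truncated bases at the edges
    width = rep(0.1, 4))
  class(peaks) <- c("peak_set", class(peaks))
  out <- reimpute_edge_amplitudes(peaks)
  expect_equal(out$prominence[2:3], peaks$prominence[2:3])
  # neighbor baselines: 95 - 85 = 10 and 92 - 83 = 9
  expect_equal(out$prominence[1], 90 - 10)
  expect_equal(out$prominence[4], 88 - 9)

  # idempotent on already-consistent edges
  again <- reimpute_edge_amplitudes(out)
  expect_equal(again$prominence, out$prominence, tolerance = 1e-9)

  one <- peaks[1, ]
  expect_equal(reimpute_edge_amplitudes(one), one)
})
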