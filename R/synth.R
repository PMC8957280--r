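#' Specification of one synthetic cardiac recording
#'
#' Ground-truth parameters for a simulated PPG or ECG recording: mean heart
#' rate, target RMSSD, duration, sampling rate, optional additive-noise SNR,
#' and the seed from which all of the recording's randomness flows.
#'
#' @param mean_bpm Mean heart rate in BPM, in (20, 220).
#' @param target_rmssd_ms Target RMSSD of the interbeat intervals (ms, >= 0).
#' @param duration_s Recording duration in seconds (default 300, i.e. the
#'   5-minute blocks of the validation study).
#' @param sampling_rate_hz Rendering sampling rate in Hz (default 1000).
#' @param snr_db Signal-to-noise ratio of added white Gaussian noise in dB,
#'   or `NULL` for a noiseless recording.
#' @param modality `"ppg"` (systolic + dicrotic bumps) or `"ecg"`
#'   (P-QRS-T Gaussians).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mean_bpm, target_rmssd_ms, duration_s = 300,
                           sampling_rate_hz = 1000, snr_db = NULL,
                           modality = c("ppg", "ecg"), seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(mean_bpm > 20, mean_bpm < 220, target_rmssd_ms >= 0,
            duration_s > 0, sampling_rate_hz > 0)
  structure(list(mean_bpm = mean_bpm, target_rmssd_ms = target_rmssd_ms,
                 duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
                 snr_db = snr_db, modality = modality, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a ground-truth interbeat-interval series
#'
#' Intervals are i.i.d. Gaussian with mean `60000 / mean_bpm` ms and standard
#' deviation `target_rmssd_ms / sqrt(2)`: for i.i.d. intervals the expected
#' squared successive difference is twice the variance, so the expected RMSSD
#' equals the target. Draws are clamped at +/- 3 SD and floored at 250 ms
#' (the refractory limit of the detector).
#'
#' @param spec A [synthetic_spec()].
#' @return Interbeat intervals in ms covering `duration_s`.
#' @export
generate_ibi_series <- function(spec) {
  mu <- 60000 / spec$mean_bpm
  sigma <- spec$target_rmssd_ms / sqrt(2)
  if (mu - 3 * sigma <= 0) {
    stop(sprintf(
      "infeasible spec: target RMSSD %g ms forces non-positive intervals at %g BPM",
      spec$target_rmssd_ms, spec$mean_bpm), call. = FALSE)
  }
  n <- ceiling(spec$duration_s * 1000 / mu * 1.2) + 10L
  ibis <- withr::with_seed(spec$seed, stats::rnorm(n, mu, sigma))
  ibis <- pmin(pmax(ibis, mu - 3 * sigma), mu + 3 * sigma)
  ibis <- pmax(ibis, 250)
  cum <- cumsum(ibis) / 1000
  ibis[cum <= spec$duration_s]
}

# Add one Gaussian bump to `samples` in place-ish (returns updated vector).
# Only touches the +/- 4 sigma neighbourhood for speed.
add_bump <- function(samples, rate, center_s, amplitude, sigma_s) {
  n <- length(samples)
  i0 <- max(1L, floor((center_s - 4 * sigma_s) * rate) + 1L)
  i1 <- min(n, ceiling((center_s + 4 * sigma_s) * rate) + 1L)
  if (i0 > n || i1 < 1L || i0 > i1) return(samples)
  tt <- (i0:i1 - 1L) / rate
  samples[i0:i1] <- samples[i0:i1] +
    amplitude * exp(-(tt - center_s)^2 / (2 * sigma_s^2))
  samples
}

#' Render a labelled beat series as a PPG or ECG waveform
#'
#' PPG beats are a unit-amplitude systolic Gaussian at the beat time
#' (SD = 6% of the local interbeat interval) plus a dicrotic bump at +30% of
#' the interval (amplitude 0.4, SD = 12%). ECG beats are a narrow tall R
#' Gaussian at the beat time (amplitude 1, SD 10 ms) flanked by a wide low P
#' wave before (-18% of the interval, amplitude 0.2, SD 30 ms) and T wave
#' after (+30%, amplitude 0.3, SD 50 ms); the R maximum is at least 3 times
#' the P and T maxima, and the near-zero detection floor plus clustering can
#' separate the three. Constants are deliberate morphology choices, not fits
#' to any particular sensor.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param duration_s Recording duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param modality `"ppg"` or `"ecg"`.
#' @return A [raw_signal()].
#' @export
render_waveform <- function(beat_times, duration_s, sampling_rate,
                            modality = c("ppg", "ecg")) {
  modality <- match.arg(modality)
  n <- ceiling(duration_s * sampling_rate)
  x <- numeric(n)
  k <- length(beat_times)
  if (k == 0L) return(raw_signal(x + 1e-12, sampling_rate))
  local_ibi <- if (k >= 2L) {
    d <- diff(beat_times)
    c(d, d[length(d)])
  } else {
    rep(0.8, k)
  }
  for (i in seq_len(k)) {
    tb <- beat_times[i]
    ibi <- local_ibi[i]
    if (modality == "ppg") {
      x <- add_bump(x, sampling_rate, tb, 1.0, 0.06 * ibi)
      x <- add_bump(x, sampling_rate, tb + 0.30 * ibi, 0.4, 0.12 * ibi)
    } else {
      x <- add_bump(x, sampling_rate, tb - 0.18 * ibi, 0.2, 0.030)
      x <- add_bump(x, sampling_rate, tb, 1.0, 0.010)
      x <- add_bump(x, sampling_rate, tb + 0.30 * ibi, 0.3, 0.050)
    }
  }
  raw_signal(x, sampling_rate)
}

#' Add white Gaussian noise at a specified SNR
#'
#' Noise variance is `P_signal / 10^(snr_db / 10)` with `P_signal` the
#' mean-removed signal power (a DC offset must not inflate the "signal"
#' power). Seeded and reproducible.
#'
#' @param signal A [raw_signal()].
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Integer seed.
#' @return A [raw_signal()] with noise added.
#' @export
add_white_noise <- function(signal, snr_db, seed = 1L) {
  stopifnot(is.finite(snr_db))
  x <- signal$samples
  p_signal <- mean((x - mean(x))^2)
  sd_noise <- sqrt(p_signal / 10^(snr_db / 10))
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(x), 0, sd_noise))
  raw_signal(x + noise, signal$sampling_rate, start_time = signal$start_time)
}

#' Downsample a waveform onto a coarser uniform grid
#'
#' Emulates acquisition at a lower sampling rate: the series is re-sampled
#' onto the coarse grid by cubic-spline evaluation, which reduces to exact
#' decimation whenever the rate ratio is an integer (as for all the
#' validation rates). Deliberately *no* anti-alias filter is applied: a
#' low-rate sensor sampling a noisy process aliases the broadband noise into
#' its band, and removing that noise beforehand would make low sampling
#' rates spuriously clean in the degradation experiments.
#'
#' @param signal A [raw_signal()].
#' @param target_rate Target rate in Hz, strictly below the current rate.
#' @return A [raw_signal()] at `target_rate`.
#' @export
downsample <- function(signal, target_rate) {
  rate <- signal$sampling_rate
  if (target_rate >= rate) {
    stop("target rate must be below the current rate; see `upsample()`",
         call. = FALSE)
  }
  y <- signal$samples
  n <- length(y)
  t0 <- (seq_len(n) - 1L) / rate
  m <- floor((n - 1L) * target_rate / rate) + 1L
  step <- rate / target_rate
  if (abs(step - round(step)) < 1e-9) {
    out <- y[seq(1L, by = as.integer(round(step)), length.out = m)]
  } else {
    t1 <- (seq_len(m) - 1L) / target_rate
    out <- stats::spline(t0, y, xout = t1, method = "fmm")$y
  }
  raw_signal(out, target_rate, start_time = signal$start_time)
}

#' Simulate one labelled cardiac recording
#'
#' Draws the ground-truth interbeat intervals, renders the waveform, and
#' optionally adds white noise, all derived from the one seed in the
#' [synthetic_spec()]. The stored
#' `true_bpm` and `true_rmssd_ms` are computed from the beat series with the
#' package's own metric formulas, so generator and estimator share one
#' definition of truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `labelled_recording`: `signal` ([raw_signal()]),
#'   `beat_times` (s), `true_bpm`, `true_rmssd_ms`, `spec`.
#' @export
simulate_recording <- function(spec) {
  ibis <- generate_ibi_series(spec)
  first <- min(0.3, ibis[1] / 2000)
  beat_times <- first + c(0, cumsum(ibis[-length(ibis)] / 1000))
  beat_times <- beat_times[beat_times <= spec$duration_s - 0.1]
  sig <- render_waveform(beat_times, spec$duration_s, spec$sampling_rate_hz,
                         spec$modality)
  if (!is.null(spec$snr_db)) {
    sig <- add_white_noise(sig, spec$snr_db, seed = spec$seed + 104729L)
  }
  td <- compute_time_domain(ibi_ms(beat_times))
  structure(list(signal = sig, beat_times = beat_times,
                 true_bpm = compute_bpm(beat_times),
                 true_rmssd_ms = td$rmssd, spec = spec),
            class = "labelled_recording")
}

# Per-recording summary of a pipeline run against the recording's truth.
summarize_recording <- function(rec, res) {
  cl <- cleaned(res)
  un <- uncleaned(res)
  data.frame(
    true_bpm = rec$true_bpm, true_rmssd = rec$true_rmssd_ms,
    bpm_cleaned = if (nrow(cl)) mean(cl$bpm) else NA_real_,
    rmssd_cleaned = if (nrow(cl)) mean(cl$rmssd) else NA_real_,
    bpm_uncleaned = if (nrow(un)) mean(un$bpm) else NA_real_,
    rmssd_uncleaned = if (nrow(un)) mean(un$rmssd) else NA_real_,
    n_windows = nrow(res), n_cleaned = nrow(cl), n_uncleaned = nrow(un))
}

#' Parameter-recovery grid over noise and sampling-rate conditions
#'
#' Simulates one recording per (BPM, RMSSD) grid point at `base_rate_hz`,
#' then for every (SNR, rate) condition adds white noise, downsamples, runs
#' the full pipeline, and records the per-recording mean cleaned and
#' uncleaned BPM and RMSSD against the ground truth. The default grids
#' (BPM 60-120 step 5 crossed with RMSSD 0-100 step 5) give the 273
#' recordings of the validation design.
#'
#' @param bpm_grid,rmssd_grid Ground-truth grids (defaults 60-120 by 5 and
#'   0-100 by 5).
#' @param snr_db_list SNR conditions in dB.
#' @param rate_list Downsampled rates in Hz.
#' @param preset Outlier preset name (default `"moderate"`).
#' @param duration_s Recording length in seconds (default 300).
#' @param base_rate_hz Rendering rate before downsampling (default 1000).
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param settings Optional [analysis_settings()] override (preset ignored
#'   if supplied).
#' @return Tibble with one row per recording x condition: truth, estimates,
#'   window counts.
#' @export
run_recovery_grid <- function(bpm_grid = seq(60, 120, by = 5),
                              rmssd_grid = seq(0, 100, by = 5),
                              snr_db_list = 20, rate_list = 250,
                              preset = "moderate", duration_s = 300,
                              base_rate_hz = 1000, seed = 1L,
                              settings = NULL) {
  if (is.null(settings)) {
    settings <- analysis_settings(outliers = resolve_preset(preset))
  }
  combos <- expand.grid(bpm = bpm_grid, rmssd = rmssd_grid)
  out <- vector("list", nrow(combos) * length(snr_db_list) * length(rate_list))
  slot <- 0L
  for (i in seq_len(nrow(combos))) {
    rec_seed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    spec <- synthetic_spec(combos$bpm[i], combos$rmssd[i],
                           duration_s = duration_s,
                           sampling_rate_hz = base_rate_hz, seed = rec_seed)
    rec <- simulate_recording(spec)
    for (snr in snr_db_list) {
      noisy <- add_white_noise(rec$signal, snr, seed = rec_seed + 1L)
      for (rate in rate_list) {
        ds <- if (rate < base_rate_hz) downsample(noisy, rate) else noisy
        res <- analyze(preprocess(ds), settings)
        slot <- slot + 1L
        out[[slot]] <- cbind(
          data.frame(bpm_set = combos$bpm[i], rmssd_set = combos$rmssd[i],
                     snr_db = snr, rate_hz = rate),
          summarize_recording(rec, res))
      }
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Agreement summary of a recovery grid
#'
#' Per (SNR, rate) condition: ICC(A,1) and RMSE between truth and estimate
#' for BPM and RMSSD, cleaned and uncleaned. Recordings without a valid
#' estimate (all windows rejected) are excluded pairwise and counted.
#'
#' @param grid Output of [run_recovery_grid()].
#' @return Tibble, one row per condition.
#' @export
summarize_recovery_grid <- function(grid) {
  conds <- unique(grid[, c("snr_db", "rate_hz")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    g <- grid[grid$snr_db == conds$snr_db[i] & grid$rate_hz == conds$rate_hz[i], ]
    pair_stats <- function(truth, est) {
      ok <- !is.na(truth) & !is.na(est)
      if (sum(ok) < 3L) {
        return(c(icc = NA_real_, rmse = NA_real_, n_missing = sum(!ok)))
      }
      c(icc = icc_a1(truth[ok], est[ok]), rmse = rmse(truth[ok], est[ok]),
        n_missing = sum(!ok))
    }
    bc <- pair_stats(g$true_bpm, g$bpm_cleaned)
    bu <- pair_stats(g$true_bpm, g$bpm_uncleaned)
    rc <- pair_stats(g$true_rmssd, g$rmssd_cleaned)
    ru <- pair_stats(g$true_rmssd, g$rmssd_uncleaned)
    data.frame(snr_db = conds$snr_db[i], rate_hz = conds$rate_hz[i],
               n = nrow(g),
               icc_bpm_cleaned = bc["icc"], rmse_bpm_cleaned = bc["rmse"],
               icc_bpm_uncleaned = bu["icc"], rmse_bpm_uncleaned = bu["rmse"],
               icc_rmssd_cleaned = rc["icc"], rmse_rmssd_cleaned = rc["rmse"],
               icc_rmssd_uncleaned = ru["icc"], rmse_rmssd_uncleaned = ru["rmse"],
               n_missing_cleaned = rc["n_missing"], row.names = NULL)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Simulated within-subject "anxiety" experiment
#'
#' Each simulated subject contributes a "safe" recording (RMSSD drawn from a
#' resting population, N(rmssd_mu, rmssd_sd) truncated to
#' `[5, 262]` ms; heart rate N(bpm_mu, bpm_sd)) and a "threat" recording with
#' the same heart rate but RMSSD reduced by a per-subject difference drawn
#' from N(d_effect * rmssd_sd, rmssd_sd) — so the true paired Cohen's d
#' (mean difference over SD of differences) equals `d_effect` in
#' expectation. Both recordings are rendered, degraded (noise, downsampling)
#' and analyzed; the per-repeat estimated effect size is the paired d of the
#' per-subject mean RMSSD, for the cleaned and uncleaned series and for the
#' realized ground truth.
#'
#' @param n_subjects Subjects per repeat (the validation design uses 171,
#'   from a power calculation at d = 0.384, alpha = 0.001, power = 0.95).
#' @param d_effect True paired effect size (default 0.384).
#' @param snr_db Noise level in dB (`NULL` = noiseless).
#' @param rate_hz Downsampled rate in Hz (equal to `base_rate_hz` = none).
#' @param repeats Number of simulated experiments (default 10).
#' @param seed Master seed.
#' @param duration_s Recording length (default 300).
#' @param base_rate_hz Rendering rate (default 1000).
#' @param bpm_mu,bpm_sd,rmssd_mu,rmssd_sd Population parameters of the
#'   resting state (defaults 74/13 BPM, 23/7 ms).
#' @param preset Outlier preset (default `"moderate"`).
#' @return Tibble with one row per repeat: `d_true`, `d_cleaned`,
#'   `d_uncleaned`, `n_complete_pairs`; attribute `"summary"` holds the mean
#'   d and its 95% CI over repeats for each series.
#' @export
run_anxiety_experiment <- function(n_subjects = 171, d_effect = 0.384,
                                   snr_db = NULL, rate_hz = 1000,
                                   repeats = 10, seed = 1L, duration_s = 300,
                                   base_rate_hz = 1000,
                                   bpm_mu = 74, bpm_sd = 13,
                                   rmssd_mu = 23, rmssd_sd = 7,
                                   preset = "moderate") {
  stopifnot(n_subjects >= 2)
  settings <- analysis_settings(outliers = resolve_preset(preset))
  draw_trunc <- function(n, mu, sd, lo, hi) {
    x <- stats::rnorm(n, mu, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mu, sd)
    x
  }
  estimate_subject <- function(bpm, rmssd, sub_seed) {
    spec <- synthetic_spec(bpm, rmssd, duration_s = duration_s,
                           sampling_rate_hz = base_rate_hz, seed = sub_seed)
    rec <- simulate_recording(spec)
    sig <- rec$signal
    if (!is.null(snr_db)) sig <- add_white_noise(sig, snr_db, sub_seed + 1L)
    if (rate_hz < base_rate_hz) sig <- downsample(sig, rate_hz)
    res <- analyze(preprocess(sig), settings)
    s <- summarize_recording(rec, res)
    c(true = rec$true_rmssd_ms, cl = s$rmssd_cleaned, un = s$rmssd_uncleaned)
  }
  rows <- lapply(seq_len(repeats), function(r) {
    rep_seed <- (as.integer(seed) + 15485863L * r) %% 2147483647L
    params <- withr::with_seed(rep_seed, {
      bpm <- pmin(pmax(stats::rnorm(n_subjects, bpm_mu, bpm_sd), 40), 140)
      safe <- draw_trunc(n_subjects, rmssd_mu, rmssd_sd, 5, 262)
      delta <- stats::rnorm(n_subjects, d_effect * rmssd_sd, rmssd_sd)
      list(bpm = bpm, safe = safe,
           threat = pmin(pmax(safe - delta, 5), 262))
    })
    est <- vapply(seq_len(n_subjects), function(i) {
      s_seed <- (rep_seed + 2L * i) %% 2147483647L
      c(estimate_subject(params$bpm[i], params$safe[i], s_seed),
        estimate_subject(params$bpm[i], params$threat[i], s_seed + 1L))
    }, numeric(6))
    d_of <- function(a, b) {
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3L) return(NA_real_)
      cohens_d_paired(a[ok], b[ok])
    }
    data.frame(
      repeat_id = r,
      d_true = d_of(est[1, ], est[4, ]),
      d_cleaned = d_of(est[2, ], est[5, ]),
      d_uncleaned = d_of(est[3, ], est[6, ]),
      n_complete_pairs = sum(!is.na(est[2, ]) & !is.na(est[5, ])))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(c(mean = mean(x), lo = NA_real_, hi = NA_real_))
    se <- stats::sd(x) / sqrt(length(x))
    tq <- stats::qt(0.975, length(x) - 1L)
    c(mean = mean(x), lo = mean(x) - tq * se, hi = mean(x) + tq * se)
  }
  attr(out, "summary") <- list(d_true = ci(out$d_true),
                               d_cleaned = ci(out$d_cleaned),
                               d_uncleaned = ci(out$d_uncleaned))
  out
}
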