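#' Heart rate (BPM) from peak times
#'
#' With k peaks spanning from the first peak time i to the last peak time j
#' (seconds), BPM = (k - 1) * 60 / (j - i): the number of complete beats in
#' the spanned interval, per minute.
#'
#' @param peak_times Strictly increasing peak times in seconds (>= 2).
#' @return Beats per minute, or `NA_real_` with fewer than 2 peaks.
#' @examples
#' compute_bpm(c(0, 0.8, 1.7, 2.5))  # 72
#' @export
compute_bpm <- function(peak_times) {
  k <- length(peak_times)
  if (k < 2L) return(NA_real_)
  (k - 1) * 60 / (peak_times[k] - peak_times[1])
}

#' Interbeat intervals in milliseconds
#'
#' @param peak_times Peak times in seconds.
#' @return Intervals between neighbouring peaks, in ms.
#' @export
ibi_ms <- function(peak_times) {
  diff(peak_times) * 1000
}

#' Time-domain HRV metrics from an interbeat-interval series
#'
#' Given N intervals IBI_1..IBI_N (ms):
#' \itemize{
#'   \item RMSSD = sqrt( sum (IBI_i - IBI_(i+1))^2 / (N - 1) ), the root mean
#'     square of the N - 1 successive differences;
#'   \item SDNN = sample SD of the intervals; SDSD = sample SD of the
#'     successive differences;
#'   \item PNN20 / PNN50 = proportion of |successive differences| strictly
#'     greater than 20 / 50 ms.
#' }
#' RMSSD/SDSD/PNN need at least 2 intervals (3 peaks); short series return
#' `NA` for the undefined entries.
#'
#' @param intervals_ms Interbeat intervals in milliseconds.
#' @return Named list: `rmssd`, `sdnn`, `sdsd`, `pnn20`, `pnn50` (proportions
#'   in `[0, 1]`).
#' @examples
#' compute_time_domain(c(800, 750, 820, 790))
#' @export
compute_time_domain <- function(intervals_ms) {
  n <- length(intervals_ms)
  out <- list(rmssd = NA_real_, sdnn = NA_real_, sdsd = NA_real_,
              pnn20 = NA_real_, pnn50 = NA_real_)
  if (n >= 2L) {
    out$sdnn <- stats::sd(intervals_ms)
    d <- diff(intervals_ms)
    out$rmssd <- sqrt(sum(d^2) / (n - 1))
    out$pnn20 <- mean(abs(d) > 20)
    out$pnn50 <- mean(abs(d) > 50)
    out$sdsd <- if (n >= 3L) stats::sd(d) else NA_real_
  }
  out
}

#' High-frequency power of the interbeat-interval tachogram
#'
#' The tachogram (interval against beat time) is cubic-spline interpolated
#' onto a uniform 4 Hz grid, a mean-detrended periodogram is taken, and the
#' power in the 0.15-0.4 Hz band is reported as that band's share of the
#' tachogram variance (ms^2). Frequency analysis needs more data than the
#' time-domain metrics: with fewer than `min_intervals` intervals, or a beat
#' span shorter than `min_span_s` (one period of 0.15 Hz), `NaN` is returned.
#'
#' @param peak_times Peak times in seconds.
#' @param band Frequency band in Hz (default `c(0.15, 0.4)`).
#' @param fs_interp Tachogram interpolation rate in Hz (default 4).
#' @param min_intervals Minimum interval count (default 4).
#' @param min_span_s Minimum first-to-last-peak span in s (default 6.7).
#' @return HF power in ms^2, or `NaN` when there is insufficient data.
#' @export
compute_hf_power <- function(peak_times, band = c(0.15, 0.4), fs_interp = 4,
                             min_intervals = 4, min_span_s = 6.7) {
  k <- length(peak_times)
  if (k - 1L < min_intervals) return(NaN)
  span <- peak_times[k] - peak_times[1]
  if (span < min_span_s) return(NaN)
  ibi <- ibi_ms(peak_times)
  tt <- peak_times[-1]                      # interval ends
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs_interp)
  if (length(grid) < 8L) return(NaN)
  x <- stats::spline(tt, ibi, xout = grid, method = "fmm")$y
  v <- stats::var(x)
  if (v == 0) return(0)
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = fs_interp),
                          taper = 0, plot = FALSE, detrend = FALSE)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  v * sum(sp$spec[sel]) / sum(sp$spec)
}
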