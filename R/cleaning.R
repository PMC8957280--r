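#' Resolve an outlier-screening preset
#'
#' Three semantically labelled presets bundle the biological and statistical
#' screening thresholds:
#' \tabular{lccc}{
#'   \tab liberal \tab moderate (default) \tab conservative \cr
#'   BPM range (exclusive) \tab 20-200 \tab 30-190 \tab 40-180 \cr
#'   RMSSD range (ms, exclusive) \tab 0-300 \tab 5-262 \tab 10-200 \cr
#'   MAD threshold (units) \tab 7 \tab 5 \tab 4 \cr
#' }
#' The BPM bounds reflect plausible resting-to-exercise heart rates, the
#' RMSSD bounds the 2nd/98th percentiles of resting RMSSD across adulthood.
#' All presets require peaks spanning at least `min_span_fraction` of the
#' window and at least `min_peaks` peaks (3, the minimum for RMSSD).
#'
#' @param name One of `"liberal"`, `"moderate"`, `"conservative"`.
#' @param min_peaks Minimum number of peaks per window (default 3).
#' @param min_span_fraction Minimum first-to-last-peak span as a fraction of
#'   the window width (default 0.5).
#' @return A list of class `outlier_settings` with fields `preset_name`,
#'   `bpm_min`, `bpm_max`, `rmssd_min`, `rmssd_max`, `mad_threshold_peaks`,
#'   `mad_threshold_ibi`, `min_span_fraction`, `min_peaks`.
#' @export
resolve_preset <- function(name = c("moderate", "liberal", "conservative"),
                           min_peaks = 3L, min_span_fraction = 0.5) {
  if (!is.character(name) || !name[1] %in% c("liberal", "moderate", "conservative")) {
    stop("unknown outlier preset; valid presets: liberal, moderate, conservative",
         call. = FALSE)
  }
  name <- name[1]
  p <- switch(name,
    liberal      = list(bpm = c(20, 200), rmssd = c(0, 300), mad = 7),
    moderate     = list(bpm = c(30, 190), rmssd = c(5, 262), mad = 5),
    conservative = list(bpm = c(40, 180), rmssd = c(10, 200), mad = 4))
  structure(
    list(preset_name = name,
         bpm_min = p$bpm[1], bpm_max = p$bpm[2],
         rmssd_min = p$rmssd[1], rmssd_max = p$rmssd[2],
         mad_threshold_peaks = p$mad, mad_threshold_ibi = p$mad,
         min_span_fraction = min_span_fraction,
         min_peaks = max(3L, as.integer(min_peaks))),
    class = "outlier_settings")
}

#' Deviations in median-absolute-deviation units
#'
#' For each value, `|x - median| / MAD` with MAD the unscaled median absolute
#' deviation (no normal-consistency factor): a robust analogue of the z-score
#' that a single artifact cannot inflate. When the MAD degenerates to 0 (over
#' half the values identical), any value differing from the median by more
#' than a relative epsilon is reported as `Inf` — a spike among identical
#' values is exactly the artifact the screen targets — and the rest as 0.
#'
#' @param values Numeric vector, length >= 3.
#' @return Deviations in MAD units, same length as `values`.
#' @examples
#' mad_units(c(2, 4, 6, 8, 100))  # 2 1 0 1 47
#' @export
mad_units <- function(values) {
  if (length(values) < 3L) {
    stop("need >= 3 values to assess MAD deviations", call. = FALSE)
  }
  med <- stats::median(values)
  dev <- abs(values - med)
  mad0 <- stats::median(dev)
  if (mad0 == 0) {
    eps <- 1e-9 * max(1, abs(med))
    return(ifelse(dev > eps, Inf, 0))
  }
  dev / mad0
}

#' Biological screen of a window's metrics
#'
#' Rejects windows whose estimates are implausible for human physiology:
#' too few peaks to compute RMSSD, BPM outside the preset's (exclusive)
#' range, or RMSSD outside the preset's (exclusive) range.
#'
#' @param bpm,rmssd Window estimates (`NA` allowed).
#' @param n_peaks Number of detected peaks in the window.
#' @param settings An [resolve_preset()] `outlier_settings`.
#' @return Character vector of rejection reasons (empty when clean), drawn
#'   from `too_few_peaks`, `bpm_range`, `rmssd_range`.
#' @export
biological_screen <- function(bpm, rmssd, n_peaks, settings) {
  reasons <- character(0)
  if (n_peaks < settings$min_peaks) reasons <- c(reasons, "too_few_peaks")
  if (!is.na(bpm) && !(bpm > settings$bpm_min && bpm < settings$bpm_max)) {
    reasons <- c(reasons, "bpm_range")
  }
  if (!is.na(rmssd) &&
      !(rmssd > settings$rmssd_min && rmssd < settings$rmssd_max)) {
    reasons <- c(reasons, "rmssd_range")
  }
  reasons
}

#' Statistical screen of a window's peaks and intervals
#'
#' Rejects windows containing peak heights, prominences, or interbeat
#' intervals deviating from the window median by more than the preset's MAD
#' threshold (see [mad_units()]; each rule needs >= 3 values, else it is
#' skipped), and windows whose first-to-last-peak span covers less than
#' `min_span_fraction` of the window width.
#'
#' @param heights,prominences Peak properties (scaled units).
#' @param intervals_ms Interbeat intervals (ms).
#' @param span_s First-to-last-peak span (s).
#' @param window_width_s Window width (s).
#' @param settings An [resolve_preset()] `outlier_settings`.
#' @return Character vector of rejection reasons, drawn from `mad_height`,
#'   `mad_prominence`, `mad_ibi`, `span_too_short`.
#' @export
statistical_screen <- function(heights, prominences, intervals_ms, span_s,
                               window_width_s, settings) {
  reasons <- character(0)
  if (length(heights) >= 3L &&
      any(mad_units(heights) > settings$mad_threshold_peaks)) {
    reasons <- c(reasons, "mad_height")
  }
  if (length(prominences) >= 3L &&
      any(mad_units(prominences) > settings$mad_threshold_peaks)) {
    reasons <- c(reasons, "mad_prominence")
  }
  if (length(intervals_ms) >= 3L &&
      any(mad_units(intervals_ms) > settings$mad_threshold_ibi)) {
    reasons <- c(reasons, "mad_ibi")
  }
  if (length(heights) >= 2L &&
      span_s < settings$min_span_fraction * window_width_s) {
    reasons <- c(reasons, "span_too_short")
  }
  reasons
}

#' Full outlier screen of one analysis window
#'
#' Combines the biological and statistical screens into a verdict. A window
#' enters the *uncleaned* series whenever it has enough peaks to compute the
#' metrics at all (the only screen the uncleaned series receives); it enters
#' the *cleaned* series only when every rule passes. Informational flags
#' (e.g. `clustering_fallback`) are carried alongside but never reject.
#'
#' @inheritParams biological_screen
#' @inheritParams statistical_screen
#' @param flags Informational flags to carry through (character).
#' @return A list of class `window_verdict`: `accepted` (all rules pass),
#'   `sufficient_peaks` (uncleaned-series membership), `reasons`, `flags`.
#' @export
screen_window <- function(bpm, rmssd, n_peaks, heights, prominences,
                          intervals_ms, span_s, window_width_s, settings,
                          flags = character(0)) {
  reasons <- c(
    biological_screen(bpm, rmssd, n_peaks, settings),
    if (n_peaks >= 2L) {
      statistical_screen(heights, prominences, intervals_ms, span_s,
                         window_width_s, settings)
    }
  )
  structure(list(accepted = length(reasons) == 0L,
                 sufficient_peaks = n_peaks >= settings$min_peaks,
                 reasons = reasons, flags = flags),
            class = "window_verdict")
}
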