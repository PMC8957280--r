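#' Sliding-window analysis settings
#'
#' `window_movement_s` and `window_overlap_s` are two views of the same
#' parameter (`overlap = width - movement`); supply at most one.
#'
#' @param window_width_s Window width in seconds (default 10; ultra-short
#'   windows of this length are an established compromise for RMSSD).
#' @param window_movement_s Step between window onsets in seconds (default =
#'   width, i.e. non-overlapping windows).
#' @param window_overlap_s Alternative parameterization; e.g. overlap 9 with
#'   width 10 gives movement 1.
#' @param detection A [detection_settings()].
#' @param outliers An [resolve_preset()] `outlier_settings`.
#' @return A list of class `analysis_settings`.
#' @export
analysis_settings <- function(window_width_s = 10, window_movement_s = NULL,
                              window_overlap_s = NULL,
                              detection = detection_settings(),
                              outliers = resolve_preset("moderate")) {
  if (!is.null(window_movement_s) && !is.null(window_overlap_s)) {
    stop("supply either `window_movement_s` or `window_overlap_s`, not both",
         call. = FALSE)
  }
  movement <- if (!is.null(window_overlap_s)) {
    window_width_s - window_overlap_s
  } else if (!is.null(window_movement_s)) {
    window_movement_s
  } else {
    window_width_s
  }
  if (movement <= 0 || movement > window_width_s) {
    stop("need 0 < movement <= window width", call. = FALSE)
  }
  structure(list(window_width_s = window_width_s,
                 window_movement_s = movement,
                 detection = detection, outliers = outliers),
            class = "analysis_settings")
}

# Analyze one window slice; returns a one-row data.frame.
analyze_one_window <- function(samples, sampling_rate, onset, settings) {
  det <- settings$detection
  width <- settings$window_width_s
  empty <- function(reasons, flags = character(0)) {
    data.frame(onset_s = onset, bpm = NA_real_, rmssd = NA_real_,
               sdnn = NA_real_, sdsd = NA_real_, pnn20 = NA_real_,
               pnn50 = NA_real_, hf = NA_real_, n_peaks = 0L,
               sufficient_peaks = FALSE, accepted = FALSE,
               reasons = paste(reasons, collapse = ";"),
               flags = paste(flags, collapse = ";"))
  }
  if (max(samples) == min(samples)) return(empty("degenerate_window"))
  scaled <- scale_window(samples)
  peaks <- detect_peaks(scaled, sampling_rate, onset = onset, settings = det)
  flags <- character(0)
  if (det$ecg_prt_clustering) {
    peaks <- classify_ecg_peaks(peaks, det)
    if (isTRUE(attr(peaks, "clustering_fallback"))) {
      flags <- "clustering_fallback"
    }
  }
  peaks <- reimpute_edge_amplitudes(peaks)
  k <- nrow(peaks)
  bpm <- compute_bpm(peaks$time)
  ibis <- ibi_ms(peaks$time)
  td <- compute_time_domain(ibis)
  hf <- compute_hf_power(peaks$time)
  span <- if (k >= 2L) peaks$time[k] - peaks$time[1] else 0
  verdict <- screen_window(bpm, td$rmssd, k, peaks$height, peaks$prominence,
                           ibis, span, width, settings$outliers, flags)
  data.frame(onset_s = onset, bpm = bpm, rmssd = td$rmssd, sdnn = td$sdnn,
             sdsd = td$sdsd, pnn20 = td$pnn20, pnn50 = td$pnn50, hf = hf,
             n_peaks = k, sufficient_peaks = verdict$sufficient_peaks,
             accepted = verdict$accepted,
             reasons = paste(verdict$reasons, collapse = ";"),
             flags = paste(verdict$flags, collapse = ";"))
}

#' Sliding-window extraction of heart rate and HRV
#'
#' Slides a fixed-width window across the prepared signal (onsets 0, m, 2m,
#' ... while onset + width fits in the recording; a trailing partial window
#' is dropped). Within each window the samples are scaled to 0-100, peaks
#' are detected (optionally k-means-filtered to ECG R waves), edge-peak
#' amplitudes are re-imputed, BPM and time-domain HRV metrics are computed,
#' and the outlier screen is applied. One row per window is returned; the
#' uncleaned series is the rows with `sufficient_peaks`, the cleaned series
#' the rows with `accepted` (see [cleaned()] / [uncleaned()]).
#'
#' @param signal A `prepared_signal` from [preprocess()] (any `raw_signal`
#'   is accepted).
#' @param settings An [analysis_settings()].
#' @return A tibble (`result_table`) with columns `onset_s`, `bpm`, `rmssd`,
#'   `sdnn`, `sdsd`, `pnn20`, `pnn50`, `hf`, `n_peaks`, `sufficient_peaks`,
#'   `accepted`, `reasons`, `flags`. Onsets are relative to the signal start.
#' @examples
#' rec <- simulate_recording(synthetic_spec(65, 40, duration_s = 60, seed = 3))
#' res <- analyze(preprocess(rec$signal))
#' cleaned(res)[, c("onset_s", "bpm", "rmssd")]
#' @export
analyze <- function(signal, settings = analysis_settings()) {
  rate <- signal$sampling_rate
  dur <- signal_duration(signal)
  width <- settings$window_width_s
  movement <- settings$window_movement_s
  if (dur < width) {
    stop(sprintf("signal (%.2f s) shorter than one window (%g s)", dur, width),
         call. = FALSE)
  }
  onsets <- seq(0, dur - width, by = movement)
  wlen <- round(width * rate)
  rows <- lapply(onsets, function(onset) {
    i0 <- round(onset * rate) + 1L
    i1 <- min(i0 + wlen - 1L, length(signal$samples))
    analyze_one_window(signal$samples[i0:i1], rate, onset, settings)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("result_table", class(out))
  out
}

#' Cleaned / uncleaned views of a result table
#'
#' The uncleaned series keeps every window with enough peaks to compute the
#' metrics; the cleaned series keeps only windows passing the full outlier
#' screen. By construction `cleaned(x)` is a subset of `uncleaned(x)`.
#'
#' @param results A result table from [analyze()].
#' @return The filtered result table.
#' @export
cleaned <- function(results) results[results$accepted, ]

#' @rdname cleaned
#' @export
uncleaned <- function(results) results[results$sufficient_peaks, ]

#' Write / read a result table as CSV
#'
#' Round-trips the [analyze()] output with full double precision.
#'
#' @param results A result table.
#' @param path CSV path.
#' @return `write_results_csv()`: `path`, invisibly. `read_results_csv()`:
#'   the result table.
#' @export
write_results_csv <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.12g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("onset_s", "bpm", "rmssd", "sdnn", "sdsd", "pnn20", "pnn50", "hf")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$n_peaks <- as.integer(df$n_peaks)
  df$reasons <- ifelse(is.na(df$reasons), "", df$reasons)
  df$flags <- ifelse(is.na(df$flags), "", df$flags)
  out <- tibble::as_tibble(df)
  class(out) <- c("result_table", class(out))
  out
}

#' Plot the time course of a heart metric
#'
#' Line plot of the chosen metric over window onsets; windows rejected by
#' the outlier screen are marked. When the cleaned series is empty the
#' uncleaned trace is drawn with a warning annotation.
#'
#' @param results A result table from [analyze()].
#' @param metric Column to plot: one of `bpm`, `rmssd`, `sdnn`, `sdsd`,
#'   `pnn20`, `pnn50`, `hf`.
#' @param file Optional image path ([ggplot2::ggsave()]); when `NULL` the
#'   plot object is returned without writing.
#' @param cleaned_only Drop rejected windows instead of marking them.
#' @return The ggplot object, invisibly when written to `file`.
#' @export
visualize <- function(results, metric = "bpm", file = NULL,
                      cleaned_only = FALSE) {
  valid <- c("bpm", "rmssd", "sdnn", "sdsd", "pnn20", "pnn50", "hf")
  if (!metric %in% valid) {
    stop(sprintf("unknown metric '%s'; choose one of: %s",
                 metric, paste(valid, collapse = ", ")), call. = FALSE)
  }
  if (nrow(results) == 0L) stop("empty result table", call. = FALSE)
  df <- as.data.frame(uncleaned(results))
  if (nrow(df) == 0L) df <- as.data.frame(results)
  df$status <- ifelse(df$accepted, "accepted", "rejected")
  if (cleaned_only) df <- df[df$accepted, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$onset_s,
                                        y = .data[[metric]])) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 1.8) +
    ggplot2::scale_color_manual(
      values = c(accepted = "#2166ac", rejected = "#b2182b"),
      drop = FALSE) +
    ggplot2::labs(x = "window onset (s)", y = metric, color = NULL) +
    ggplot2::theme_minimal()
  if (!any(results$accepted)) {
    p <- p + ggplot2::annotate(
      "text", x = mean(range(df$onset_s)), y = Inf, vjust = 1.5,
      label = "no windows passed the outlier screen", color = "#b2182b")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
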