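#' Detection settings for windowed peak extraction
#'
#' @param min_amplitude Minimum peak height in scaled (0-100) units
#'   (default 50). Height is measured from the window minimum, which the
#'   scaling maps to 0, so the scaled value itself is the height. For noisy
#'   wrist PPG a lower threshold (e.g. 30) is often needed.
#' @param min_distance_ms Minimum distance between retained peaks in
#'   milliseconds (default 250, i.e. a 240 BPM refractory limit).
#' @param ecg_prt_clustering Enable k-means (k = 3) discrimination of ECG R
#'   waves from P and T waves (default `FALSE`). When enabled, detection runs
#'   at the near-zero `clustering_floor` and the R-wave cluster is selected
#'   by its peak properties.
#' @param clustering_floor Height threshold used instead of `min_amplitude`
#'   when clustering is on (default 5).
#' @param cluster_seed Internal RNG seed for the k-means restarts; fixed so
#'   reruns are bit-identical.
#' @return A list of class `detection_settings`.
#' @export
detection_settings <- function(min_amplitude = 50, min_distance_ms = 250,
                               ecg_prt_clustering = FALSE,
                               clustering_floor = 5, cluster_seed = 17L) {
  stopifnot(min_amplitude >= 0, min_amplitude <= 100, min_distance_ms > 0)
  structure(list(min_amplitude = min_amplitude,
                 min_distance_ms = min_distance_ms,
                 ecg_prt_clustering = isTRUE(ecg_prt_clustering),
                 clustering_floor = clustering_floor,
                 cluster_seed = as.integer(cluster_seed)),
            class = "detection_settings")
}

#' Scale a window of samples to the 0-100 range
#'
#' Affine map sending the window minimum to 0 and maximum to 100, so the
#' amplitude threshold means the same thing regardless of sensor gain.
#'
#' @param samples Non-empty numeric vector.
#' @return Scaled vector with min 0 and max 100.
#' @export
scale_window <- function(samples) {
  if (length(samples) == 0L) stop("empty window", call. = FALSE)
  lo <- min(samples)
  hi <- max(samples)
  if (hi == lo) {
    stop(structure(
      class = c("pulseline_degenerate_window", "error", "condition"),
      list(message = "degenerate window: constant samples cannot be scaled",
           call = NULL)))
  }
  100 * (samples - lo) / (hi - lo)
}

# --- local peak machinery (find_peaks-style) --------------------------------
# Local maxima with plateau handling: a plateau counts as one peak at the
# midpoint of its flat top. Returns integer sample indices.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # sign of slope, propagating through flats so plateaus resolve
  s <- sign(d)
  idx <- which(s != 0)
  if (length(idx) < 2L) return(integer(0))
  peaks <- integer(0)
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    if (s[i] > 0 && s[j] < 0) {
      # rising edge ends at i+1, falling edge starts at j: flat top i+1 .. j
      peaks <- c(peaks, as.integer((i + 1L + j) %/% 2L))
    }
  }
  peaks
}

# Topographic prominence of each peak: lowest contour line enclosing no
# higher peak. For each peak, walk left/right to the nearest strictly higher
# sample (or the signal edge); the prominence base is the higher of the two
# interval minima.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    il <- 1L
    higher <- which(x[seq_len(p - 1L)] > h)
    if (length(higher)) il <- max(higher)
    ir <- n
    if (p < n) {
      higher <- which(x[(p + 1L):n] > h)
      if (length(higher)) ir <- p + min(higher)
    }
    left_min <- min(x[il:p])
    right_min <- min(x[p:ir])
    h - max(left_min, right_min)
  }, numeric(1))
}

# Width of each peak (in samples) at a reference height of
# height - rel_height * prominence, with linear interpolation at the
# crossings, searching within the prominence bases.
peak_widths <- function(x, peaks, prominences, rel_height = 0.5) {
  n <- length(x)
  vapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    ref <- x[p] - rel_height * prominences[k]
    # left crossing
    i <- p
    while (i > 1L && x[i - 1L] >= ref && x[i - 1L] <= x[p]) i <- i - 1L
    left <- if (i == 1L || x[i - 1L] > x[p]) {
      as.numeric(i)
    } else {
      (i - 1L) + (ref - x[i - 1L]) / (x[i] - x[i - 1L])
    }
    # right crossing
    j <- p
    while (j < n && x[j + 1L] >= ref && x[j + 1L] <= x[p]) j <- j + 1L
    right <- if (j == n || x[j + 1L] > x[p]) {
      as.numeric(j)
    } else {
      j + (x[j] - ref) / (x[j] - x[j + 1L])
    }
    right - left
  }, numeric(1))
}

# Greedy minimum-distance pruning: process peaks from tallest to shortest,
# discarding any not-yet-kept peak within `min_dist` samples of a kept one.
enforce_min_distance <- function(peaks, heights, min_dist) {
  keep <- rep(TRUE, length(peaks))
  ord <- order(heights, decreasing = TRUE)
  for (k in ord) {
    if (!keep[k]) next
    close_by <- abs(peaks - peaks[k]) <= min_dist & seq_along(peaks) != k
    keep[close_by & heights <= heights[k]] <- FALSE
  }
  which(keep)
}

#' Detect peaks in a scaled analysis window
#'
#' Finds local maxima at least `min_amplitude` tall (scaled units, measured
#' from the window minimum) and at least `min_distance_ms` apart (the taller
#' of two close peaks wins), and annotates each with its height, topographic
#' prominence, and width at half prominence.
#'
#' @param samples Scaled window samples (see [scale_window()]).
#' @param sampling_rate Sampling rate of the window in Hz.
#' @param onset Window onset in recording seconds; peak times are reported as
#'   absolute recording times (onset + within-window offset).
#' @param settings A [detection_settings()].
#' @return A `peak_set`: tibble with columns `time` (s), `height`,
#'   `prominence` (scaled units), `width` (s), ordered by time.
#' @export
detect_peaks <- function(samples, sampling_rate, onset = 0,
                         settings = detection_settings()) {
  threshold <- if (settings$ecg_prt_clustering) settings$clustering_floor
               else settings$min_amplitude
  idx <- find_local_maxima(samples)
  idx <- idx[samples[idx] >= threshold]
  if (length(idx)) {
    min_dist <- settings$min_distance_ms / 1000 * sampling_rate
    idx <- idx[enforce_min_distance(idx, samples[idx], min_dist)]
    idx <- sort(idx)
  }
  prom <- peak_prominences(samples, idx)
  wid <- peak_widths(samples, idx, prom) / sampling_rate
  ps <- tibble::tibble(
    time = onset + (idx - 1L) / sampling_rate,
    height = samples[idx],
    prominence = prom,
    width = wid
  )
  attr(ps, "clustering_fallback") <- FALSE
  class(ps) <- c("peak_set", class(ps))
  ps
}

#' Discriminate ECG R waves from P and T waves by k-means clustering
#'
#' Candidate peaks (detected at a near-zero threshold) are partitioned into
#' three clusters on their width, height, and prominence (z-scored per
#' window; 10 k-means restarts under a fixed seed). R waves are narrow and
#' prominent, so the cluster whose centroid maximizes
#' (prominence z - width z) is returned, in time order; ties break toward
#' the narrower-width cluster. With fewer than 6 candidates, or degenerate
#' features, clustering is impossible and the function falls back to plain
#' amplitude thresholding at `settings$min_amplitude`, flagging the result
#' (`attr(, "clustering_fallback")`).
#'
#' @param peaks A `peak_set` from [detect_peaks()] run with the clustering
#'   floor.
#' @param settings A [detection_settings()].
#' @return A `peak_set` of R waves only (or the fallback set, flagged).
#' @export
classify_ecg_peaks <- function(peaks, settings = detection_settings()) {
  fallback <- function() {
    out <- peaks[peaks$height >= settings$min_amplitude, ]
    attr(out, "clustering_fallback") <- TRUE
    class(out) <- c("peak_set", setdiff(class(out), "peak_set"))
    out
  }
  if (nrow(peaks) < 6L) return(fallback())
  feats <- cbind(width = peaks$width, height = peaks$height,
                 prominence = peaks$prominence)
  if (nrow(unique(feats)) < 3L) return(fallback())
  sds <- apply(feats, 2, stats::sd)
  z <- scale(feats)
  z[, sds == 0] <- 0
  fit <- tryCatch(
    withr::with_seed(settings$cluster_seed,
                     stats::kmeans(z, centers = 3L, nstart = 10L)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  score <- fit$centers[, "prominence"] - fit$centers[, "width"]
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(fit$centers[best, "width"])]
  out <- peaks[fit$cluster == best, ]
  out <- out[order(out$time), ]
  attr(out, "clustering_fallback") <- FALSE
  class(out) <- c("peak_set", setdiff(class(out), "peak_set"))
  out
}

#' Re-impute the amplitudes of the first and last peaks of a window
#'
#' A sliding window can open or close mid-beat, so the prominence base of the
#' first or last peak may be set on a partial waveform segment (e.g. during a
#' P wave), underestimating its amplitude. The prominence of each edge peak
#' is recomputed against the baseline (height minus prominence) of its
#' nearest interior neighbour; interior peaks are untouched.
#'
#' @param peaks A `peak_set` with at least 2 peaks (fewer are returned
#'   unchanged).
#' @return The `peak_set` with edge prominences repaired.
#' @export
reimpute_edge_amplitudes <- function(peaks) {
  k <- nrow(peaks)
  if (k < 2L) return(peaks)
  baseline <- peaks$height - peaks$prominence
  new_first <- peaks$height[1] - baseline[2]
  peaks$prominence[1] <- min(max(new_first, 0), peaks$height[1])
  new_last <- peaks$height[k] - baseline[k - 1L]
  peaks$prominence[k] <- min(max(new_last, 0), peaks$height[k])
  peaks
}
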