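#' Construct a raw cardiac signal
#'
#' A `raw_signal` is the package's basic container for a uniformly sampled,
#' single-channel waveform: an amplitude vector (arbitrary units), its
#' sampling rate in Hz, and the time of the first sample in seconds.
#'
#' @param samples Numeric vector of amplitudes. Must be non-empty and finite;
#'   non-finite samples are a hard error — artifact handling belongs to the
#'   outlier-screening stage, not to silent imputation here.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `raw_signal`.
#' @examples
#' sig <- raw_signal(sin(2 * pi * seq(0, 10, by = 0.01)), sampling_rate = 100)
#' sig
#' @export
raw_signal <- function(samples, sampling_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf); remove or impute artifacts upstream",
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time)),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz (%.3f s)\n",
              class(x)[1], length(x$samples), x$sampling_rate,
              signal_duration(x)))
  invisible(x)
}

# Recording duration in seconds (span covered by the sample grid, n / rate).
signal_duration <- function(signal) {
  length(signal$samples) / signal$sampling_rate
}

#' Read a cardiac waveform from a plain-text/CSV file
#'
#' Two dialects are supported: a single-column file (one amplitude per line,
#' optional header) for which `sampling_rate` must be supplied, and a
#' two-column `time,amplitude` file whose time stamps must be uniformly spaced
#' to within 1 ppm (the sampling rate is then inferred from the spacing).
#'
#' @param path Path to the file.
#' @param sampling_rate Sampling rate in Hz; required for single-column files,
#'   cross-checked (1 ppm) against the time stamps for two-column files when
#'   given.
#' @return A [raw_signal()].
#' @export
read_signal_csv <- function(path, sampling_rate = NULL) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*[-+0-9.eE]+\\s*(,\\s*[-+0-9.eE]+\\s*)?$", first)
  dat <- utils::read.csv(path, header = header)
  if (ncol(dat) == 1L) {
    if (is.null(sampling_rate)) {
      stop("single-column files need an explicit `sampling_rate`", call. = FALSE)
    }
    return(raw_signal(dat[[1]], sampling_rate))
  }
  if (ncol(dat) >= 2L) {
    tt <- as.numeric(dat[[1]])
    dt <- diff(tt)
    if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1]))) {
      stop("time column is not uniformly spaced (tolerance 1 ppm)", call. = FALSE)
    }
    rate <- 1 / dt[1]
    if (!is.null(sampling_rate) &&
        abs(rate - sampling_rate) > 1e-6 * sampling_rate) {
      stop(sprintf("stated sampling rate (%g Hz) disagrees with time stamps (%g Hz)",
                   sampling_rate, rate), call. = FALSE)
    }
    return(raw_signal(dat[[2]], rate, start_time = tt[1]))
  }
  stop("unrecognized signal file layout", call. = FALSE)
}

#' Write a waveform to a single-column CSV
#'
#' @param signal A [raw_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  utils::write.csv(data.frame(amplitude = signal$samples), path,
                   row.names = FALSE)
  invisible(path)
}
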