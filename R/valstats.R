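#' Intraclass correlation: two-way, absolute agreement, single measure
#'
#' McGraw-Wong ICC(A,1): agreement between two measurement methods treated
#' as fixed raters of random subjects, computed from the two-way ANOVA mean
#' squares. Unlike a Pearson correlation, a constant offset between the
#' methods lowers the value (absolute agreement, not consistency).
#'
#' @param x,y Paired finite vectors, length >= 3.
#' @return The ICC value.
#' @examples
#' icc_a1(c(1, 2, 3, 4, 5), c(1, 3, 2, 4, 6))  # ~0.902
#' @export
icc_a1 <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("ICC inputs must be finite", call. = FALSE)
  }
  k <- 2
  dat <- cbind(x, y)
  gm <- mean(dat)
  if (sum((dat - gm)^2) == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * sum((col_means - gm)^2)
  sst <- sum((dat - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Semantic label for an ICC value
#'
#' Conventional interpretation bands: below 0.5 "poor", 0.5-0.75 "moderate",
#' 0.75-0.9 "good", above 0.9 "excellent".
#'
#' @param icc ICC value(s).
#' @return Character vector of labels.
#' @export
icc_label <- function(icc) {
  as.character(cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = FALSE))
}

#' Root-mean-square error between truth and estimate
#'
#' Pairs with a missing estimate (or truth) are excluded and counted in the
#' `"n_missing"` attribute.
#'
#' @param truth,estimate Equal-length vectors.
#' @return `sqrt(mean((truth - estimate)^2))` over the complete pairs.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  ok <- !is.na(truth) & !is.na(estimate)
  if (!any(ok)) stop("no valid pairs", call. = FALSE)
  out <- sqrt(mean((truth[ok] - estimate[ok])^2))
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' Paired Cohen's d
#'
#' `d = mean(a - b) / sd(a - b)` with the sample SD of the differences.
#'
#' @param a,b Paired vectors.
#' @return The effect size.
#' @export
cohens_d_paired <- function(a, b) {
  d <- a - b
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    stop("zero (or undefined) SD of differences: d undefined", call. = FALSE)
  }
  mean(d) / s
}

#' Cohen's d from a paired t statistic
#'
#' `d = t / sqrt(n)` with `n` the number of pairs (degrees of freedom + 1).
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return The effect size.
#' @examples
#' cohens_d_from_t(1.96, 26)  # 0.384
#' @export
cohens_d_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

# Power of a paired t test with n pairs at effect size d, from the
# noncentral t distribution (ncp = d * sqrt(n)).
paired_t_power <- function(n, d, alpha, sides = 2) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp = ncp)
  }
}

#' Sample size for a paired t test
#'
#' Smallest integer n such that the noncentral-t power of a paired t test at
#' level `alpha` with effect size `d` and `n - 1` degrees of freedom reaches
#' `power`. Found by a doubling bracket followed by binary search on the
#' (monotone in n) power function.
#'
#' @param d Effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param sides 1 or 2 (default 2, two-sided).
#' @return The required number of pairs.
#' @examples
#' paired_t_sample_size(0.384, alpha = 0.001, power = 0.95)  # 171
#' @export
paired_t_sample_size <- function(d, alpha = 0.05, power = 0.8, sides = 2) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, sides %in% c(1, 2))
  if (!is.finite(d) || d <= 0) {
    stop("effect size must be positive (power unreachable at d <= 0)",
         call. = FALSE)
  }
  hi <- 2L
  while (paired_t_power(hi, d, alpha, sides) < power) {
    hi <- hi * 2L
    if (hi > 1e8) stop("required sample size exceeds 1e8; power unreachable",
                       call. = FALSE)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (paired_t_power(mid, d, alpha, sides) >= power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Mean jerk magnitude of a triaxial accelerometer series
#'
#' Jerk is the time derivative of acceleration; per sample interval the
#' per-axis jerk is `diff(a) / diff(t)` and its triaxial magnitude is
#' `sqrt(jx^2 + jy^2 + jz^2)` (m/s^3). The mean magnitude over a recording
#' summarizes wrist-motion intensity, a proxy for motion-artifact severity
#' in wearable PPG.
#'
#' @param time Uniformly spaced timestamps in seconds (tolerance 1 ppm).
#' @param ax,ay,az Per-axis acceleration in m/s^2, same length as `time`.
#' @return List: `magnitude` (per-interval jerk magnitudes, m/s^3) and
#'   `mean` (their average).
#' @export
jerk_magnitude <- function(time, ax, ay, az) {
  n <- length(time)
  stopifnot(length(ax) == n, length(ay) == n, length(az) == n)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1]))) {
    stop("timestamps are not uniformly spaced (tolerance 1 ppm)", call. = FALSE)
  }
  jx <- diff(ax) / dt
  jy <- diff(ay) / dt
  jz <- diff(az) / dt
  mag <- sqrt(jx^2 + jy^2 + jz^2)
  list(magnitude = mag, mean = mean(mag))
}

#' Read a triaxial accelerometer CSV
#'
#' Expects columns `t`, `ax`, `ay`, `az` (seconds and m/s^2).
#'
#' @param path CSV path.
#' @return A tibble with those columns.
#' @export
read_accel_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop("accelerometer CSV needs columns t, ax, ay, az", call. = FALSE)
  }
  tibble::as_tibble(df[need])
}
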