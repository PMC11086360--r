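#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth low-pass (default -3 dB at 18 Hz), applied
#' forward-backward by default so the net filter has zero phase lag (and a
#' -6 dB point at the cutoff); `zero_phase = FALSE` gives the single-pass
#' filter whose magnitude is 1/sqrt(2) at the cutoff.
#'
#' @param series numeric vector.
#' @param rate sampling rate (Hz); must exceed twice the cutoff.
#' @param order filter order.
#' @param cutoff -3 dB frequency (Hz).
#' @param zero_phase forward-backward application.
#' @return Filtered series.
#' @export
butterworth_lowpass <- function(series, rate, order = 4, cutoff = 18,
                                zero_phase = TRUE) {
  if (rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff frequency")
  if (length(series) < 3 * (order + 1))
    stop("series too short to filter")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  if (!zero_phase) return(as.numeric(signal::filter(bf, series)))
  # forward-backward application on an endpoint-reflected padding so the
  # startup transient stays in the pads (plain filtfilt leaves large edge
  # artifacts)
  n <- length(series)
  L <- min(n - 1, max(50, 25 * order))
  padded <- c(2 * series[1] - series[(L + 1):2],
              series,
              2 * series[n] - series[(n - 1):(n - L)])
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(L + 1):(L + n)]
}

#' Detect contact events from vertical GRF
#'
#' Heel strike is the first rise of the vertical ground reaction force
#' above the threshold, toe-off the last fall below it; crossing times are
#' linearly interpolated between samples.
#'
#' @param grf_z vertical GRF series (N).
#' @param time sample times (s), same length.
#' @param threshold contact threshold (N).
#' @return List with `heel_strike` and `toe_off` times (s).
#' @export
detect_events <- function(grf_z, time, threshold = 20) {
  stopifnot(length(grf_z) == length(time))
  above <- grf_z > threshold
  if (!any(above))
    stop("no contact episode: series never exceeds the threshold")
  cross_time <- function(i) {
    # linear interpolation of the crossing between samples i and i+1
    t0 <- time[i]; t1 <- time[i + 1]
    y0 <- grf_z[i]; y1 <- grf_z[i + 1]
    t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
  }
  first_up <- which(above)[1]
  hs <- if (first_up == 1) time[1] else cross_time(first_up - 1)
  last_above <- max(which(above))
  to <- if (last_above == length(grf_z)) time[length(time)]
        else cross_time(last_above)
  list(heel_strike = hs, toe_off = to)
}

#' Phase-normalize a series between contact events
#'
#' Linearly resamples a time series to 101 points over 0-100% of the
#' phase between heel strike (0%) and toe-off (100%).
#'
#' @param series numeric vector.
#' @param time sample times (s).
#' @param events list with `heel_strike`, `toe_off` (s), inside the series
#'   span.
#' @return Object of class `phase_series`: list with `phase` (0..100) and
#'   `values` (length 101).
#' @export
phase_normalize <- function(series, time, events) {
  hs <- events$heel_strike; to <- events$toe_off
  if (to <= hs) stop("events out of order: toe_off must follow heel_strike")
  if (hs < min(time) - 1e-9 || to > max(time) + 1e-9)
    stop("events outside the series span")
  tq <- seq(hs, to, length.out = 101)
  v <- stats::approx(time, series, xout = tq, rule = 2)$y
  structure(list(phase = seq(0, 100, length.out = 101), values = v),
            class = "phase_series")
}

#' Normalize GRF by body weight
#'
#' @param F force (N), vectorized.
#' @param weight body mass (kg).
#' @param g gravitational acceleration (m/s^2).
#' @return Force in percent body weight (%BW).
#' @export
normalize_grf <- function(F, weight, g = 9.81) {
  stopifnot(weight > 0)
  F / (weight * g) * 100
}

#' Normalize GRM by body weight times body height
#'
#' @param M moment (N m), vectorized.
#' @param weight body mass (kg).
#' @param height stature (m).
#' @param g gravitational acceleration (m/s^2).
#' @return Moment in percent body weight x body height (%BW BH).
#' @export
normalize_grm <- function(M, weight, height, g = 9.81) {
  stopifnot(weight > 0, height > 0)
  M / (weight * g * height) * 100
}

#' Agreement metrics between two curves
#'
#' Pearson correlation with its qualitative band, root mean square error,
#' and relative RMSE (RMSE divided by the mean of the two series' ranges,
#' in percent).
#'
#' @param est,ref numeric vectors of equal length (plain or
#'   `phase_series`).
#' @return List of class `series_metrics` with `rho`, `class`, `rmse`,
#'   `rrmse`.  `rho` is `NA` (class `"undefined"`) for zero-variance
#'   input.
#' @export
compare_series <- function(est, ref) {
  if (inherits(est, "phase_series")) est <- est$values
  if (inherits(ref, "phase_series")) ref <- ref$values
  stopifnot(length(est) == length(ref))
  rmse <- sqrt(mean((est - ref)^2))
  rng <- mean(c(diff(range(est)), diff(range(ref))))
  rrmse <- if (rng > 0) rmse / rng * 100 else if (rmse == 0) 0 else Inf
  rho <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
         else stats::cor(est, ref)
  structure(list(rho = rho,
                 class = classify_correlation(rho),
                 rmse = rmse, rrmse = rrmse),
            class = "series_metrics")
}

#' @export
print.series_metrics <- function(x, ...) {
  cat(sprintf("rho = %s (%s), RMSE = %.4g, rRMSE = %.3g%%\n",
              ifelse(is.na(x$rho), "NA", sprintf("%.3f", x$rho)), x$class,
              x$rmse, x$rrmse))
  invisible(x)
}

#' Qualitative correlation band
#'
#' Classifies a Pearson correlation as weak (rho <= 0.35), moderate
#' (0.35 < rho <= 0.67), strong (0.67 < rho <= 0.9) or excellent
#' (rho > 0.9).  Negative correlations fall in the weak band by the
#' signed value.
#'
#' @param rho correlation in `[-1, 1]` (vectorized).
#' @return Character vector of band labels (`"undefined"` for `NA`).
#' @export
classify_correlation <- function(rho) {
  out <- rep("undefined", length(rho))
  ok <- !is.na(rho)
  stopifnot(all(rho[ok] >= -1 & rho[ok] <= 1))
  out[ok & rho <= 0.35] <- "weak"
  out[ok & rho > 0.35 & rho <= 0.67] <- "moderate"
  out[ok & rho > 0.67 & rho <= 0.9] <- "strong"
  out[ok & rho > 0.9] <- "excellent"
  out
}

#' Channel-wise validation report
#'
#' Computes [compare_series()] metrics for each channel of two named
#' lists of phase-normalized curves.
#'
#' @param est,ref named lists of equal-length numeric vectors (or
#'   `phase_series`).
#' @return Data frame of class `metrics_report` with one row per channel:
#'   `channel`, `rho`, `class`, `rmse`, `rrmse`.
#' @export
metrics_report <- function(est, ref) {
  ch <- intersect(names(est), names(ref))
  rows <- lapply(ch, function(nm) {
    m <- compare_series(est[[nm]], ref[[nm]])
    data.frame(channel = nm, rho = m$rho, class = m$class, rmse = m$rmse,
               rrmse = m$rrmse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}
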