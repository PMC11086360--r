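#' Construct an IMU trial
#'
#' Bundles per-sensor accelerometer and gyroscope series with sampling
#' and mounting metadata.  Sampling must be uniform and series lengths
#' equal across sensors.
#'
#' @param time sample times (s), uniformly spaced.
#' @param sensors named list (by segment) of lists with `acc` and `gyr`
#'   3 x T matrices (m/s^2, rad/s, sensor frame).
#' @param mountings mounting list, see [default_mountings()].
#' @param rate sampling rate (Hz); inferred from `time` when missing.
#' @return Object of class `imu_trial`.
#' @export
imu_trial <- function(time, sensors, mountings, rate = NULL) {
  T <- length(time)
  if (T >= 2) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("sampling must be uniform")
    if (is.null(rate)) rate <- 1 / dt[1]
  }
  for (nm in names(sensors)) {
    s <- sensors[[nm]]
    if (!all(dim(s$acc) == c(3, T)) || !all(dim(s$gyr) == c(3, T)))
      stop("sensor ", nm, " series must be 3 x ", T)
  }
  structure(list(time = time, rate = rate, sensors = sensors,
                 mountings = mountings), class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %d sensors, %d samples at %g Hz (%.3f s)\n",
              length(x$sensors), length(x$time), x$rate,
              diff(range(x$time))))
  cat("  sensors:", paste(names(x$sensors), collapse = ", "), "\n")
  invisible(x)
}

#' Low-pass filter every channel of a trial
#'
#' Applies the zero-phase Butterworth low-pass (see
#' [butterworth_lowpass()]) to all accelerometer and gyroscope axes of
#' every sensor — the standard preprocessing applied to all measurements
#' before orientation estimation and cost evaluation.
#'
#' @param trial an [imu_trial()].
#' @param cutoff -3 dB frequency (Hz).
#' @return The filtered `imu_trial`.
#' @export
filter_trial <- function(trial, cutoff = 18) {
  sensors <- lapply(trial$sensors, function(s) list(
    acc = t(apply(s$acc, 1, butterworth_lowpass, rate = trial$rate,
                  cutoff = cutoff)),
    gyr = t(apply(s$gyr, 1, butterworth_lowpass, rate = trial$rate,
                  cutoff = cutoff))))
  imu_trial(trial$time, sensors, trial$mountings, trial$rate)
}

#' Restrict a trial to a time window
#'
#' @param trial an [imu_trial()].
#' @param t0,t1 window bounds (s).
#' @return The windowed `imu_trial`.
#' @export
window_trial <- function(trial, t0, t1) {
  keep <- trial$time >= t0 - 1e-9 & trial$time <= t1 + 1e-9
  if (!any(keep)) stop("empty window")
  sensors <- lapply(trial$sensors, function(s)
    list(acc = s$acc[, keep, drop = FALSE],
         gyr = s$gyr[, keep, drop = FALSE]))
  imu_trial(trial$time[keep], sensors, trial$mountings, trial$rate)
}

#' Write an IMU trial to CSV
#'
#' One row per sample with columns `time_s` and
#' `<sensor>_{ax,ay,az,gx,gy,gz}` in SI units.
#'
#' @param trial an [imu_trial()].
#' @param path output file.
#' @return The data frame, invisibly.
#' @export
write_imu_trial <- function(trial, path) {
  df <- data.frame(time_s = trial$time)
  for (nm in names(trial$sensors)) {
    s <- trial$sensors[[nm]]
    block <- cbind(t(s$acc), t(s$gyr))
    colnames(block) <- paste0(nm, "_", c("ax", "ay", "az", "gx", "gy",
                                         "gz"))
    df <- cbind(df, block)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read an IMU trial from CSV
#'
#' Inverse of [write_imu_trial()]; sensor names are inferred from the
#' column prefixes.
#'
#' @param path CSV file with `time_s` and `<sensor>_{ax..gz}` columns.
#' @param mountings mounting list for the sensors.
#' @return An [imu_trial()].
#' @export
read_imu_trial <- function(path, mountings = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_s" %in% names(df))
  axcols <- grep("_ax$", names(df), value = TRUE)
  sensors <- list()
  for (pre in sub("_ax$", "", axcols)) {
    sensors[[pre]] <- list(
      acc = t(as.matrix(df[paste0(pre, "_a", c("x", "y", "z"))])),
      gyr = t(as.matrix(df[paste0(pre, "_g", c("x", "y", "z"))])))
    dimnames(sensors[[pre]]$acc) <- NULL
    dimnames(sensors[[pre]]$gyr) <- NULL
  }
  if (is.null(mountings)) mountings <- default_mountings()
  imu_trial(df$time_s, sensors, mountings)
}

#' Read a run configuration
#'
#' Loads a YAML (or JSON) run configuration and merges it over the
#' package defaults: participant `height`/`weight`, `gains`, `ground`,
#' cost `weights` (xi1, xi2, xi3), `ga` settings, `noise` model and
#' `seed`.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    height = 1.69, weight = 63.3,
    gains = default_gains(), ground = default_ground(),
    weights = list(xi1 = 1e3, xi2 = 1e3, xi3 = 10),
    ekf = list(w = 1e-3, v = 1e-1, P0 = 1e2),
    ga = list(pop_size = 60, generations = 100, seed = 1),
    noise = list(accel_sd = 0.05, gyro_sd = 0.005, bias_walk_sd = 1e-4),
    event_threshold = 20, lowpass_hz = 18, seed = 1)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

#' Write a run configuration
#'
#' @param config configuration list as from [read_run_config()].
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' Write an orientation estimate to CSV
#'
#' Per-segment quaternions (w, x, y, z) and intrinsic X-Y-Z Euler angles
#' at the trial rate.
#'
#' @param est an `orientation_estimate` from [chain_orientations()].
#' @param path output file.
#' @return The data frame, invisibly.
#' @export
write_orientations <- function(est, path) {
  df <- data.frame(time_s = est$time)
  for (nm in names(est$quat)) {
    block <- cbind(t(est$quat[[nm]]), t(est$euler[[nm]]))
    colnames(block) <- paste0(nm, "_", c("qw", "qx", "qy", "qz",
                                         "phi", "theta", "psi"))
    df <- cbind(df, block)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
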