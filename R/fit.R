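#' Derive optimizer measurements from an IMU trial
#'
#' Runs the paired-IMU extended Kalman filter over the whole sensor tree
#' and assembles the quantities the cost function compares against:
#' per-segment orientation series (quaternion and Euler) and the pelvis
#' accelerometer signal (low-pass filtered, sensor frame).
#'
#' @param trial an [imu_trial()].
#' @param model a [build_model()] object.
#' @param params an [ekf_params()].
#' @param init optional named list of initial sensor quaternions (from
#'   [init_from_calibration()] or fixture metadata).
#' @param lowpass_hz low-pass cutoff applied to all channels before
#'   estimation (Hz; `NULL` to skip filtering).
#' @return List with `time`, `euler`, `quat`, `pelvis_acc` and the full
#'   `orientation_estimate`.
#' @export
trial_measurements <- function(trial, model, params = ekf_params(),
                               init = NULL, lowpass_hz = 18) {
  est <- chain_orientations(trial, model, params, init = init)
  pa <- trial$sensors$pelvis$acc
  if (!is.null(lowpass_hz) && trial$rate > 2.5 * lowpass_hz)
    pa <- t(apply(pa, 1, butterworth_lowpass, rate = trial$rate,
                  cutoff = lowpass_hz))
  list(time = trial$time, euler = est$euler, quat = est$quat,
       pelvis_acc = pa, orientation = est)
}

# internal: joint angles implied by measured segment orientations
# (relative parent->child rotation, intrinsic X-Y-Z Euler decomposition)
measured_joint_angles <- function(measurements) {
  quat <- measurements$quat
  parent <- segment_parent()
  jmap <- list(trunk = c("lumbar_x", "lumbar_y", "lumbar_z"),
               thigh_l = c("hip_l_x", "hip_l_y", "hip_l_z"),
               thigh_r = c("hip_r_x", "hip_r_y", "hip_r_z"),
               shank_l = "knee_l", shank_r = "knee_r",
               foot_l = "ankle_l", foot_r = "ankle_r",
               upper_arm_l = c("shoulder_l_x", "shoulder_l_y",
                               "shoulder_l_z"),
               upper_arm_r = c("shoulder_r_x", "shoulder_r_y",
                               "shoulder_r_z"),
               forearm_l = "elbow_l", forearm_r = "elbow_r")
  T <- length(measurements$time)
  out <- matrix(NA_real_, 21, T,
                dimnames = list(joint_coord_names(), NULL))
  for (s in names(jmap)) {
    p <- parent[[s]]
    if (!(s %in% names(quat)) || !(p %in% names(quat))) next
    coords <- jmap[[s]]
    for (k in seq_len(T)) {
      rel <- quat_mult(quat_conj(quat[[p]][, k]), quat[[s]][, k])
      e <- euler_xyz_from_quat(rel)
      if (length(coords) == 3) out[coords, k] <- e
      else out[coords, k] <- e[1]
    }
  }
  out
}

#' Estimate ground reaction forces from an IMU trial
#'
#' The package's main fitting function.  Fuses the paired-IMU
#' orientations with the extended Kalman filter, allocates reference
#' spline nodes over the analysis window, warm-starts the node values
#' from the measured joint angles, minimizes the three-term cost
#' (orientation error, pelvis-acceleration error, muscle load) with a
#' genetic algorithm, and re-simulates the best trajectory at the output
#' rate to obtain GRF, GRM, joint angles and joint torques.
#'
#' @param trial an [imu_trial()].
#' @param height,weight participant stature (m) and mass (kg).
#' @param model optional prebuilt [build_model()] (overrides
#'   height/weight).
#' @param span analysis window (s); defaults to the trial span.
#' @param state0 initial model state; defaults to the neutral pose (use
#'   the calibration posture or fixture metadata for dynamic starts).
#' @param init_orientation optional named list of initial sensor
#'   quaternions for the EKF.
#' @param ga a [ga_config()].
#' @param weights a [cost_weights()].
#' @param ekf an [ekf_params()]; when `NULL`, defaults are used with the
#'   initial covariance shrunk to `diag(1e-3)` if `init_orientation` is
#'   supplied (a calibration-grade initialization is certain to well
#'   under a degree, and a large `P0` would let the first, least-settled
#'   samples overwrite it).
#' @param role_config node-allocation roles, see [default_role_config()].
#' @param sim_opts list of optimizer simulation options (`method`,
#'   `rtol`, `atol`, `cost_hz`).
#' @param out_hz output rate of the final re-simulation (Hz).
#' @param verbose print GA progress.
#' @return Object of class `grf_fit` with components `model`,
#'   `reference` (optimized trajectory), `sim` (final [simulate_motion()]
#'   result), `cost` (best cost breakdown), `history` (GA trace),
#'   `measurements`, and the call.
#' @seealso [predict.grf_fit()], [coef.grf_fit()], [residuals.grf_fit()]
#' @export
grf_estimate <- function(trial, height = NULL, weight = NULL,
                         model = NULL, span = NULL, state0 = NULL,
                         init_orientation = NULL, ga = ga_config(),
                         weights = cost_weights(), ekf = NULL,
                         role_config = default_role_config(),
                         sim_opts = list(), out_hz = 1000,
                         verbose = FALSE) {
  stopifnot(inherits(trial, "imu_trial"))
  if (is.null(model)) {
    if (is.null(height) || is.null(weight))
      stop("supply either a model or height and weight")
    model <- build_model(height, weight)
  }
  if (is.null(span)) span <- range(trial$time)
  if (is.null(state0)) state0 <- neutral_pose(model)
  if (is.null(ekf))
    ekf <- if (is.null(init_orientation)) ekf_params()
           else ekf_params(P0 = diag(1e-3, 8))
  meas <- trial_measurements(trial, model, ekf, init = init_orientation)
  skeleton <- allocate_nodes(model, span, role_config)
  ja <- measured_joint_angles(meas)
  # warm start: smoothed measured joint angles sampled at the node times,
  # with the first node anchored to the known initial posture
  q0 <- state0$q
  warm_at <- function(cutoff) {
    g <- ref_to_genes(skeleton)
    k <- 0
    for (j in seq_along(skeleton$dofs)) {
      nm <- names(skeleton$dofs)[j]
      nt <- skeleton$dofs[[j]]$times
      m <- length(nt)
      if (!anyNA(ja[nm, ])) {
        sm <- ja[nm, ]
        if (trial$rate > 2.5 * cutoff)
          sm <- butterworth_lowpass(sm, rate = trial$rate,
                                    cutoff = cutoff)
        g[(k + 1):(k + m)] <-
          stats::approx(meas$time, sm, xout = nt, rule = 2)$y
      }
      if (nm %in% names(q0)) g[k + 1] <- unname(q0[nm])
      k <- k + m
    }
    g
  }
  init <- warm_at(6)
  attr(init, "population") <- rbind(warm_at(3), warm_at(12))
  so <- utils::modifyList(list(state0 = state0, method = "trbdf2",
                               rtol = 1e-3, atol = 1e-5, cost_hz = 100),
                          sim_opts)
  opt <- optimize_trajectory(model, meas, skeleton, ga = ga,
                             weights = weights, sim_opts = so,
                             init = init, verbose = verbose)
  sim <- simulate_motion(model, opt$best, t_span = span, state0 = state0,
                         method = so$method, rtol = min(so$rtol, 1e-5),
                         atol = min(so$atol, 1e-7), out_hz = out_hz)
  out <- list(model = model, reference = opt$best, sim = sim,
              cost = opt$best_cost, history = opt$history,
              measurements = meas, ga = ga, weights = weights,
              state0 = state0, span = span, n_failed = opt$n_failed,
              call = match.call())
  class(out) <- "grf_fit"
  out
}

#' @export
print.grf_fit <- function(x, ...) {
  cat("Ground reaction force estimate from IMU data\n")
  cat(sprintf("  model: %.2f m, %.1f kg; window %.2f-%.2f s\n",
              x$model$height, x$model$weight, x$span[1], x$span[2]))
  cat(sprintf("  GA: population %d, %d generations, %d node variables\n",
              x$ga$pop_size, x$ga$generations, x$reference$n_nodes))
  cat(sprintf("  best cost I_all = %.4g (I_Q = %.4g, I_a = %.4g, I_m = %.4g)\n",
              x$cost$I_all, x$cost$I_Q, x$cost$I_a_pelvis,
              x$cost$I_muscle))
  cat(sprintf("  peak vertical GRF %.0f N (%.0f %%BW)\n",
              max(x$sim$grf["z", ]),
              max(normalize_grf(x$sim$grf["z", ], x$model$weight))))
  invisible(x)
}

#' @export
summary.grf_fit <- function(object, ...) {
  x <- object
  grf <- x$sim$grf
  bw <- x$model$weight * x$model$gravity
  ev <- tryCatch(detect_events(grf["z", ], x$sim$time),
                 error = function(e) NULL)
  s <- list(
    call = x$call, span = x$span, cost = x$cost,
    n_nodes = x$reference$n_nodes,
    history_tail = utils::tail(x$history, 3),
    peak_grf_bw = max(grf["z", ]) / bw * 100,
    events = ev, n_failed = x$n_failed)
  class(s) <- "summary.grf_fit"
  s
}

#' @export
print.summary.grf_fit <- function(x, ...) {
  cat("Call:\n  "); print(x$call)
  cat(sprintf("\nAnalysis window: %.2f-%.2f s, %d spline node variables\n",
              x$span[1], x$span[2], x$n_nodes))
  print(x$cost)
  if (!is.null(x$events))
    cat(sprintf("Contact: heel strike %.3f s, toe-off %.3f s\n",
                x$events$heel_strike, x$events$toe_off))
  cat(sprintf("Peak vertical GRF: %.0f %%BW\n", x$peak_grf_bw))
  cat(sprintf("Diverged candidate simulations: %d\n", x$n_failed))
  invisible(x)
}

#' Extract optimized node values
#'
#' @param object a `grf_fit`.
#' @param ... unused.
#' @return Named numeric vector of spline node values (rad), names
#'   `<coord>.<node index>`.
#' @export
coef.grf_fit <- function(object, ...) {
  v <- lapply(object$reference$dofs, `[[`, "values")
  stats::setNames(unlist(v, use.names = FALSE),
                  unlist(lapply(names(v), function(nm)
                    paste0(nm, ".", seq_along(v[[nm]])))))
}

#' Re-simulate a fitted trajectory
#'
#' Runs the forward-dynamics model with the fitted reference trajectory,
#' optionally at a different output rate or integrator setting.
#'
#' @param object a `grf_fit`.
#' @param out_hz output rate (Hz).
#' @param method integrator.
#' @param ... passed to [simulate_motion()].
#' @return A `sim_result`.
#' @export
predict.grf_fit <- function(object, out_hz = 1000, method = "trbdf2",
                            ...) {
  simulate_motion(object$model, object$reference, t_span = object$span,
                  state0 = object$state0, method = method,
                  out_hz = out_hz, ...)
}

#' Orientation residuals of a fit
#'
#' Per-segment Euler-angle residuals (simulated minus measured) on the
#' simulation grid.
#'
#' @param object a `grf_fit`.
#' @param ... unused.
#' @return Named list of 3 x T residual matrices (rad).
#' @export
residuals.grf_fit <- function(object, ...) {
  sim <- object$sim
  meas <- object$measurements
  out <- list()
  for (s in names(sim$orientations)) {
    if (!(s %in% names(meas$euler))) next
    E <- apply(sim$orientations[[s]], 2, euler_xyz_from_quat)
    Em <- apply(meas$euler[[s]], 1, function(row)
      stats::approx(meas$time, row, xout = sim$time, rule = 2)$y)
    out[[s]] <- wrap_angle(E - t(Em))
  }
  out
}

#' Plot a fitted GRF estimate
#'
#' Draws the estimated ground reaction force components over time and the
#' GA cost history.
#'
#' @param x a `grf_fit`.
#' @param ... unused.
#' @export
plot.grf_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  grf <- x$sim$grf
  graphics::matplot(x$sim$time, t(grf), type = "l", lty = 1,
                    col = c("grey60", "steelblue", "black"),
                    xlab = "time (s)", ylab = "GRF (N)",
                    main = "estimated ground reaction force")
  graphics::legend("topright", c("medial", "anterior", "vertical"),
                   col = c("grey60", "steelblue", "black"), lty = 1,
                   bty = "n")
  graphics::plot(x$history$generation, x$history$best, type = "s",
                 xlab = "generation", ylab = "best cost",
                 main = "GA convergence", log = "y")
  invisible(x)
}
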