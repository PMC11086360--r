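#' Sensor noise model
#'
#' Additive white noise for accelerometer and gyroscope plus a slow gyro
#' bias random walk, reproducible from the seed.
#'
#' @param accel_sd accelerometer white-noise standard deviation (m/s^2).
#' @param gyro_sd gyroscope white-noise standard deviation (rad/s).
#' @param bias_walk_sd gyro bias random-walk intensity (rad/s/sqrt(s)).
#' @param seed RNG seed.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(accel_sd = 0.05, gyro_sd = 0.005,
                        bias_walk_sd = 1e-4, seed = 1) {
  stopifnot(accel_sd >= 0, gyro_sd >= 0, bias_walk_sd >= 0)
  structure(list(accel_sd = accel_sd, gyro_sd = gyro_sd,
                 bias_walk_sd = bias_walk_sd, seed = seed),
            class = "noise_model")
}

# scenario node tables: per joint coordinate, values at the 5 evenly
# spaced jump-leg node times (upper-body coordinates are constant)
hop_nodes <- function() {
  # single-leg hop attempt on the left leg: quiet two-footed stance
  # (filter convergence window), countermovement crouch with the right
  # leg tucking clear, then an explosive left-leg push that unloads the
  # stance leg to a fraction of body weight
  list(
    hip_l_x  = c(0.02, 0.02, 0.55, -0.15, 0.10),
    hip_l_y  = c(0.00, 0.00, 0.06, 0.06, 0.03),
    hip_l_z  = rep(0, 5),
    knee_l   = c(-0.05, -0.05, -0.85, 0.10, -0.20),
    ankle_l  = c(0.00, 0.00, 0.25, -0.50, -0.20),
    hip_r_x  = c(0.02, 0.02, 0.55, 0.30, 0.45),
    hip_r_y  = c(0.00, 0.00, -0.06, -0.06, -0.06),
    hip_r_z  = rep(0, 5),
    knee_r   = c(-0.05, -0.05, -0.85, -1.10, -1.20),
    ankle_r  = c(0.00, 0.00, 0.25, -0.10, -0.10)
  )
}

squat_nodes <- function() {
  # bilateral countermovement: quiet stance, unloading dip into a deep
  # crouch, push-off
  leg <- list(
    hip_x  = c(0.02, 0.02, 0.60, -0.10, 0.10),
    hip_y  = c(0, 0, 0, 0, 0),
    hip_z  = c(0, 0, 0, 0, 0),
    knee   = c(-0.05, -0.05, -0.90, 0.05, -0.30),
    ankle  = c(0.00, 0.00, 0.30, -0.50, 0.10)
  )
  list(hip_l_x = leg$hip_x, hip_l_y = leg$hip_y, hip_l_z = leg$hip_z,
       knee_l = leg$knee, ankle_l = leg$ankle,
       hip_r_x = leg$hip_x, hip_r_y = leg$hip_y, hip_r_z = leg$hip_z,
       knee_r = leg$knee, ankle_r = leg$ankle)
}

#' Synthesize a reference trajectory for a test scenario
#'
#' Produces smooth spline node sets that drive the forward-dynamics model
#' through one of three simplified, planar-dominant scenarios:
#' `"calibration-pose"` (static neutral stance), `"squat-jump"`
#' (bilateral countermovement and push-off) or `"single-leg-hop"` (drop
#' landing on the left leg, absorption, push-off into flight).  A small
#' seed-dependent jitter (sd 0.02 rad) individualizes trials; the same
#' seed always gives identical nodes.
#'
#' @param model a [build_model()] object.
#' @param scenario scenario name.
#' @param duration motion duration (s).
#' @param seed RNG seed.
#' @param jitter_sd node jitter standard deviation (rad).
#' @return A `reference_trajectory` (see [allocate_nodes()]).
#' @export
synth_motion <- function(model,
                         scenario = c("single-leg-hop", "squat-jump",
                                      "calibration-pose"),
                         duration = 1.5, seed = 1, jitter_sd = 0.02) {
  scenario <- match.arg(scenario)
  stopifnot(duration > 0.2)
  traj <- allocate_nodes(model, c(0, duration))
  if (scenario == "calibration-pose") return(traj)
  tab <- if (scenario == "single-leg-hop") hop_nodes() else squat_nodes()
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  for (nm in names(tab)) {
    v <- tab[[nm]]
    m <- length(traj$dofs[[nm]]$values)
    stopifnot(m == length(v))
    jit <- stats::rnorm(1, 0, jitter_sd)
    traj$dofs[[nm]]$values <- v * (1 + 0.1 * jit) + jit
  }
  # adjust each DOF's first node so the spline starts at rest (zero
  # initial slope): the trial then opens in a quiet stance with no
  # velocity transient
  for (j in seq_along(traj$dofs)) {
    d <- traj$dofs[[j]]
    if (length(d$values) < 3) next
    slope_with_v1 <- function(v1) {
      vv <- d$values; vv[1] <- v1
      cpp_spline_eval(d$times, vv, d$times[1])$deriv
    }
    s0 <- slope_with_v1(0); s1 <- slope_with_v1(1)
    # derivative is affine in the first node value; clip the adjustment
    # to the joint's limits and to a sane neighbourhood of the design
    v1 <- -s0 / (s1 - s0)
    nm <- names(traj$dofs)[j]
    lim <- model$coords[model$coords$coord == nm, ]
    v1 <- max(min(v1, d$values[1] + 0.3, lim$q_max - 0.05),
              d$values[1] - 0.3, lim$q_min + 0.05)
    traj$dofs[[j]]$values[1] <- v1
  }
  traj
}

# internal: initial state consistent with a reference trajectory: joints
# at the reference values, pelvis placed so the lowest stance-foot contact
# point sits `clearance` above the ground, and the horizontal whole-body
# COM balanced over the stance ankle(s)
scenario_initial_state <- function(model, traj, clearance = 0,
                                   stance_feet = c("foot_l", "foot_r")) {
  st <- neutral_pose(model)
  rv <- spline_reference(traj, traj$span[1])
  st$q[rownames(rv$q_r)] <- rv$q_r[, 1]
  # start joints moving with the reference so the PD derivative term does
  # not kick impulsively at release
  st$qd[rownames(rv$qd_r)] <- rv$qd_r[, 1]
  fk <- cpp_fk(model$cpp, state_vec(model, st))
  minz <- Inf
  for (side in stance_feet) {
    bi <- model$segments[[side]]$body_index
    pts <- fk$R[, , bi] %*% model$contact_points$left$points +
      fk$p[, bi]
    minz <- min(minz, min(pts[3, ]))
  }
  st$q["root_tz"] <- st$q["root_tz"] - minz + clearance
  # scenarios open near the neutral stance, whose COM already sits over
  # the feet; a single damped hold brings the state to rest
  settle_equilibrium(model, st, traj, hold = 1.2)
}

# internal: settle a stance state to static equilibrium by simulating a
# hold phase (constant reference at the trajectory's initial angles) and
# taking the final, fully damped state.  More robust than a root solve
# against the piecewise-smooth contact forces.
settle_equilibrium <- function(model, st, traj, hold = 1.5) {
  rv <- spline_reference(traj, traj$span[1])
  hold_ref <- allocate_nodes(model, c(0, hold))
  for (j in seq_along(hold_ref$dofs)) {
    nm <- names(hold_ref$dofs)[j]
    hold_ref$dofs[[j]]$values[] <- rv$q_r[nm, 1]
  }
  sim <- simulate_motion(model, hold_ref, c(0, hold), state0 = st,
                         method = "trbdf2", rtol = 1e-7, atol = 1e-9,
                         out_hz = 100)
  T <- length(sim$time)
  st$q[] <- sim$q[, T]
  st$qd[] <- sim$qd[, T]
  st
}

#' Synthesize noise-free IMU signals from a simulation
#'
#' Forward sensor model: each accelerometer reads the specific force at
#' its mounting point, `R_sensor->global^-1 (a_point - g)`, where
#' `a_point` combines translational, centripetal and tangential
#' acceleration of the sensor point; each gyro reads the segment angular
#' velocity in the sensor frame.
#'
#' @param sim a [simulate_motion()] result.
#' @param model the generating model.
#' @param mountings mounting list; defaults to the model's.
#' @return A noise-free [imu_trial()].
#' @export
imu_from_sim <- function(sim, model, mountings = model$mountings) {
  g <- c(0, 0, -model$gravity)
  T <- length(sim$time)
  sensors <- list()
  for (nm in names(mountings)) {
    mt <- mountings[[nm]]
    seg <- if (!is.null(mt$segment)) mt$segment else nm
    pk <- point_kinematics(model, sim, seg, mt$lever_arm)
    Rm <- matrix_from_quat(mt$mount_rotation)
    acc <- matrix(0, 3, T); gyr <- matrix(0, 3, T)
    for (s in seq_len(T)) {
      Rs <- pk$R[, , s] %*% Rm
      acc[, s] <- t(Rs) %*% (pk$acc[, s] - g)
      gyr[, s] <- t(Rm) %*% pk$omega_body[, s]
    }
    sensors[[nm]] <- list(acc = acc, gyr = gyr)
  }
  imu_trial(sim$time, sensors, mountings)
}

#' Add sensor noise to an IMU trial
#'
#' Adds white noise to every accelerometer and gyro axis plus an
#' integrated gyro bias random walk, reproducibly from the noise-model
#' seed.
#'
#' @param trial an [imu_trial()].
#' @param noise a [noise_model()].
#' @return The noisy `imu_trial`.
#' @export
add_noise <- function(trial, noise = noise_model()) {
  stopifnot(inherits(trial, "imu_trial"), inherits(noise, "noise_model"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(noise$seed)
  T <- length(trial$time)
  dt <- 1 / trial$rate
  sensors <- trial$sensors
  for (nm in names(sensors)) {
    if (noise$accel_sd > 0)
      sensors[[nm]]$acc <- sensors[[nm]]$acc +
        matrix(stats::rnorm(3 * T, 0, noise$accel_sd), 3, T)
    if (noise$gyro_sd > 0)
      sensors[[nm]]$gyr <- sensors[[nm]]$gyr +
        matrix(stats::rnorm(3 * T, 0, noise$gyro_sd), 3, T)
    if (noise$bias_walk_sd > 0) {
      walk <- apply(matrix(stats::rnorm(3 * T, 0,
                                        noise$bias_walk_sd * sqrt(dt)),
                           3, T), 1, cumsum)
      sensors[[nm]]$gyr <- sensors[[nm]]$gyr + t(walk)
    }
  }
  imu_trial(trial$time, sensors, trial$mountings, trial$rate)
}

#' Generate a complete synthetic trial
#'
#' Builds the model, synthesizes the scenario reference, simulates the
#' ground-truth motion and GRF, derives noise-free IMU signals, adds
#' sensor noise, and (optionally) writes `trial.csv` (IMU), `truth.csv`
#' (coordinates, GRF, GRM) and `meta.yaml` to a fixture directory.
#'
#' @param scenario scenario name, see [synth_motion()].
#' @param height,weight participant anthropometry.
#' @param noise a [noise_model()].
#' @param seed RNG seed for the scenario nodes.
#' @param duration motion duration (s).
#' @param dir optional fixture directory to write to.
#' @param out_hz IMU sampling rate (Hz).
#' @return Object of class `synthetic_trial`: `trial` (noisy IMU),
#'   `trial_clean`, `truth` (ground-truth `sim_result`), `reference`
#'   (generating trajectory), `state0` (true initial state), `init_quat`
#'   (true initial sensor quaternions), `model`, `noise`, `scenario`.
#' @export
make_fixture <- function(scenario = "single-leg-hop", height = 1.69,
                         weight = 63.3, noise = noise_model(), seed = 1,
                         duration = 1.5, dir = NULL, out_hz = 1000) {
  model <- build_model(height, weight)
  ref <- synth_motion(model, scenario, duration, seed)
  # every scenario opens in two-footed stance; start at static contact
  # equilibrium (per-point springs carry the weight at penetration depth
  # m g / (n K_G)), then let the hold-phase settle refine it
  stance <- c("foot_l", "foot_r")
  clearance <- -weight * 9.81 / (44 * default_ground()$K_G)
  st0 <- scenario_initial_state(model, ref, clearance, stance)
  truth <- simulate_motion(model, ref, t_span = c(0, duration),
                           state0 = st0, method = "trbdf2",
                           rtol = 1e-6, atol = 1e-8, out_hz = out_hz)
  clean <- imu_from_sim(truth, model)
  noisy <- add_noise(clean, noise)
  init_quat <- lapply(truth$orientations, function(Q) Q[, 1])
  out <- structure(
    list(trial = noisy, trial_clean = clean, truth = truth,
         reference = ref, state0 = st0, init_quat = init_quat,
         model = model, noise = noise, scenario = scenario,
         height = height, weight = weight, seed = seed),
    class = "synthetic_trial")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_imu_trial(noisy, file.path(dir, "trial.csv"))
    write_sim_result(truth, model, file.path(dir, "truth.csv"))
    yaml::write_yaml(
      list(scenario = scenario, height = height, weight = weight,
           seed = seed, duration = duration,
           noise = unclass(noise)[c("accel_sd", "gyro_sd",
                                    "bias_walk_sd", "seed")],
           state0 = list(q = as.list(st0$q), qd = as.list(st0$qd)),
           init_quat = lapply(init_quat, as.numeric)),
      file.path(dir, "meta.yaml"))
  }
  out
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %s, %.2f s at %g Hz\n", x$scenario,
              diff(range(x$trial$time)), x$trial$rate))
  cat(sprintf("  peak vertical GRF %.0f N (body weight %.0f N)\n",
              max(x$truth$grf["z", ]), x$weight * 9.81))
  invisible(x)
}
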