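#' Active PD joint torque
#'
#' Proportional-derivative tracking torque toward the reference joint
#' angles: `tau_a_j = K_PD (q_r_j - q_j) + D_PD (qd_r_j - qd_j)` for each of
#' the 21 controlled DOFs.
#'
#' @param q_r,qd_r reference joint angles (rad) and velocities (rad/s),
#'   length 21.
#' @param q,qd current joint angles and velocities, length 21.
#' @param gains list with `K_PD` and `D_PD`, see [default_gains()].
#' @return Numeric vector of 21 joint torques (N m).
#' @export
active_torque <- function(q_r, qd_r, q, qd, gains = default_gains()) {
  n <- length(q)
  if (length(q_r) != n || length(qd_r) != n || length(qd) != n)
    stop("q_r, qd_r, q, qd must have equal length")
  gains$K_PD * (q_r - q) + gains$D_PD * (qd_r - qd)
}

#' Passive joint-limit torque
#'
#' Double-exponential passive torque that is dormant in the mid-range and
#' rises steeply beyond the anatomical limits, with light viscous damping:
#' `tau_p = -a exp(b (q - q_max)) + a exp(b (q_min - q)) - c qd`.
#'
#' @param q,qd joint angle (rad) and velocity (rad/s); vectorized.
#' @param joint_spec a data frame (rows recycled against `q`) with columns
#'   `a`, `b`, `c`, `q_min`, `q_max` — e.g. rows of `model$coords`.
#' @details The exponent is capped at 10 (with linear continuation
#'   beyond) so that deep transient overshoots during integration produce
#'   a strong but finite restoring torque.
#' @return Passive torque (N m), same length as `q`.
#' @export
passive_torque <- function(q, qd, joint_spec) {
  capped_exp <- function(e) ifelse(e < 10, exp(e), exp(10) * (1 + e - 10))
  -joint_spec$a * capped_exp(joint_spec$b * (q - joint_spec$q_max)) +
    joint_spec$a * capped_exp(joint_spec$b * (joint_spec$q_min - q)) -
    joint_spec$c * qd
}

#' Foot-ground contact forces at explicit points
#'
#' Viscoelastic normal force with unilateral clamping and regularized
#' Coulomb friction.  For a point at height `rz` with vertical velocity
#' `vrz` below the ground (`rz < rz0`), the vertical force is
#' `Fv = max(0, -K_G (rz - rz0) - D_G vrz)`; above ground it is zero.  The
#' horizontal force opposes the sliding velocity with
#' `|Fh| = mu(v) Fv min(1, v/v0)` where
#' `mu(v) = mu_d + (mu_s - mu_d) exp(-v/v0)`, so `|Fh| <= mu_s Fv` always
#' and `|Fh| -> mu_d Fv` at high sliding speed.
#'
#' @param point_positions 3 x n matrix of world positions (m).
#' @param point_velocities 3 x n matrix of world velocities (m/s).
#' @param ground ground parameters, see [default_ground()].
#' @return List of class `contact_forces` with `Fv` (length n), `Fh`
#'   (2 x n), `F` (3 x n world forces) and `total` (3-vector).
#' @export
contact_forces <- function(point_positions, point_velocities,
                           ground = default_ground()) {
  p <- as.matrix(point_positions); v <- as.matrix(point_velocities)
  stopifnot(nrow(p) == 3, all(dim(p) == dim(v)))
  n <- ncol(p)
  Fv <- numeric(n)
  Fh <- matrix(0, 2, n)
  pen <- p[3, ] - ground$rz0
  below <- pen < 0
  Fv[below] <- pmax(0, -ground$K_G * pen[below] - ground$D_G * v[3, below])
  for (k in which(Fv > 0)) {
    sv <- sqrt(v[1, k]^2 + v[2, k]^2)
    if (sv > 1e-12) {
      mu <- ground$mu_d + (ground$mu_s - ground$mu_d) *
        exp(-sv / ground$friction_reg_speed)
      ramp <- min(1, sv / ground$friction_reg_speed)
      Fh[, k] <- -mu * Fv[k] * ramp * v[1:2, k] / sv
    }
  }
  F <- rbind(Fh, Fv)
  rownames(F) <- c("x", "y", "z")
  out <- list(Fv = Fv, Fh = Fh, F = F, total = rowSums(F))
  class(out) <- "contact_forces"
  out
}

#' Virtual balance torque
#'
#' Restoring torque on the root (pelvis) Euler rotations that keeps the
#' model from tipping over during forward-dynamics simulation:
#' `tau_virtual = -K_virtual q_virtual - D_virtual qd_virtual`
#' componentwise.  With the default zero yaw gain only the sagittal and
#' frontal rotations are restrained.
#'
#' @param q_virtual root Euler angle triple (rad).
#' @param qd_virtual root Euler angle rates (rad/s).
#' @param gains list with `K_virtual`, `D_virtual`, see [default_gains()].
#' @return 3-vector of torques (N m).
#' @export
virtual_torque <- function(q_virtual, qd_virtual, gains = default_gains()) {
  -gains$K_virtual * q_virtual - gains$D_virtual * qd_virtual
}

#' Inertia matrix and bias vector of the equations of motion
#'
#' Returns the joint-space inertia matrix `M(q)` (composite-rigid-body
#' algorithm) and the bias vector `Gamma(q, qd)` collecting Coriolis,
#' centrifugal and gravity terms and, when `include_external`, the
#' contributions of the foot contact forces (mapped through the point
#' Jacobians) and the virtual balance torque, so that
#' `M qdd + Gamma = tau`.
#'
#' @param model a [build_model()] object.
#' @param state a `model_state` (see [neutral_pose()]) or named q vector.
#' @param qd optional velocity vector when `state` is a plain vector.
#' @param include_external include contact and virtual-torque terms.
#' @return List with `M` (27 x 27) and `Gamma` (27-vector).
#' @export
eom_terms <- function(model, state, qd = NULL, include_external = TRUE) {
  q <- state_vec(model, state)
  if (is.null(qd)) qd <- if (inherits(state, "model_state"))
    as.numeric(state$qd[model$coord_names]) else rep(0, length(q))
  out <- cpp_eom(model$cpp, q, qd, include_external)
  dimnames(out$M) <- list(model$coord_names, model$coord_names)
  names(out$Gamma) <- model$coord_names
  out
}

#' Solve the equations of motion for the accelerations
#'
#' Assembles `M(q) qdd + Gamma(q, qd, Fv, Fh, tau_virtual) = tau` at one
#' state and returns `qdd = M^-1 (tau - Gamma)`.  `tau` stacks the 21 joint
#' torques onto zero root forces; contact forces and the virtual torque are
#' computed from the state and enter through the bias term.
#'
#' @param model a [build_model()] object.
#' @param state a `model_state` or named 27-vector of coordinates.
#' @param tau joint torque vector: length 21 (joint DOFs) or 27 (full,
#'   generalized).  Defaults to zero.
#' @param qd optional velocities when `state` is a plain vector.
#' @param include_contact,include_virtual include the contact forces /
#'   virtual balance torque computed at this state.
#' @return Named 27-vector of generalized accelerations.
#' @export
assemble_and_solve <- function(model, state, tau = NULL, qd = NULL,
                               include_contact = TRUE,
                               include_virtual = TRUE) {
  q <- state_vec(model, state)
  if (is.null(qd)) qd <- if (inherits(state, "model_state"))
    as.numeric(state$qd[model$coord_names]) else rep(0, length(q))
  if (is.null(tau)) tau <- rep(0, 27)
  if (length(tau) == 21) tau <- c(rep(0, 6), tau)
  if (length(tau) != 27) stop("tau must have length 21 or 27")
  qdd <- cpp_qdd(model$cpp, q, qd, tau, include_contact, include_virtual)
  if (!all(is.finite(qdd)))
    stop("singular inertia matrix or non-finite state; q = ",
         paste(signif(q, 4), collapse = ", "))
  stats::setNames(as.numeric(qdd), model$coord_names)
}

#' Forward-dynamics simulation
#'
#' Integrates the equations of motion under PD tracking of the reference
#' joint-angle splines, passive joint-limit torques, foot-ground contact
#' and the virtual balance torque, and returns motion and reaction-force
#' time series resampled on a fixed output grid.
#'
#' Two integrators are available: `"rk45"`, an adaptive Dormand-Prince
#' 4(5) pair, and `"trbdf2"`, an L-stable TR-BDF2 method with lazy
#' Jacobian re-use.  The contact damping makes stance-phase dynamics stiff,
#' so `"trbdf2"` is typically 1-2 orders of magnitude faster there at
#' equal output accuracy and is the default inside the trajectory
#' optimizer; `"rk45"` is the reference integrator.
#'
#' @param model a [build_model()] object.
#' @param reference a `reference_trajectory` (see [allocate_nodes()]), or
#'   `NULL` to simulate passively (no PD torque).
#' @param t_span length-2 simulation interval (s).
#' @param state0 initial `model_state`; defaults to [neutral_pose()].
#' @param method `"rk45"` or `"trbdf2"`.
#' @param rtol,atol relative / absolute integration tolerances.
#' @param out_hz output sampling rate (Hz).
#' @param hmax,hmin maximum / minimum step size (s).
#' @param max_steps step budget before aborting.
#' @return Object of class `sim_result`: `time`, matrices `q`, `qd`, `qdd`
#'   (27 x T, named rows), `grf` (3 x T total ground reaction force, N),
#'   `pelvis_acc` (3 x T specific force at the pelvis sensor in the sensor
#'   frame, m/s^2), `orientations` (list per segment: 4 x T quaternion
#'   series, global frame), plus solver diagnostics.
#' @examples
#' \donttest{
#' m <- build_model(1.69, 63.3)
#' ref <- constant_reference(m, duration = 0.3)
#' sim <- simulate_motion(m, ref, t_span = c(0, 0.3), method = "trbdf2")
#' range(sim$grf["z", ])
#' }
#' @export
simulate_motion <- function(model, reference, t_span, state0 = NULL,
                            method = c("trbdf2", "rk45"),
                            rtol = 1e-6, atol = 1e-8, out_hz = 1000,
                            hmax = 0.01, hmin = 1e-12, max_steps = 5e7) {
  method <- match.arg(method)
  stopifnot(inherits(model, "body_model"), length(t_span) == 2,
            t_span[2] > t_span[1])
  if (is.null(state0)) state0 <- neutral_pose(model)
  active <- !is.null(reference)
  ref_list <- if (active) {
    stopifnot(inherits(reference, "reference_trajectory"))
    check_reference_span(reference, t_span)
    lapply(reference$dofs, function(d) list(times = d$times,
                                            values = d$values))
  } else {
    lapply(seq_len(21), function(j) list(times = t_span, values = c(0, 0)))
  }
  q0 <- state_vec(model, state0)
  qd0 <- as.numeric(state0$qd[model$coord_names])
  out <- cpp_simulate(model$cpp, ref_list, q0, qd0, t_span[1], t_span[2],
                      out_hz, method, rtol, atol, hmax, hmin, max_steps,
                      active)
  if (!isTRUE(out$ok))
    stop("integration failed: ", out$message,
         sprintf(" (last valid time %.4f s)", out$t_end))
  rownames(out$q) <- rownames(out$qd) <- rownames(out$qdd) <-
    model$coord_names
  rownames(out$grf) <- c("x", "y", "z")
  res <- list(time = as.numeric(out$time), q = out$q, qd = out$qd,
              qdd = out$qdd, grf = out$grf,
              nsteps = out$nsteps, nfev = out$nfev, method = method,
              rtol = rtol, atol = atol, out_hz = out_hz,
              model_mass = model$total_mass)
  res$pelvis_acc <- pelvis_sensor_acceleration(model, res)
  res$orientations <- segment_orientations(model, res)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.3f-%.3f s, %d samples at %g Hz (%s)\n",
              x$time[1], x$time[length(x$time)], length(x$time), x$out_hz,
              x$method))
  cat(sprintf("  integrator steps %d, derivative evaluations %d\n",
              as.integer(x$nsteps), as.integer(x$nfev)))
  cat(sprintf("  vertical GRF range [%.1f, %.1f] N\n",
              min(x$grf["z", ]), max(x$grf["z", ])))
  invisible(x)
}

# internal: classical kinematics of a body-fixed point across a sim result
point_kinematics <- function(model, sim, segment, point) {
  body <- model$segments[[segment]]$body_index - 1L
  cpp_point_kin(model$cpp, sim$q, sim$qd, sim$qdd, body, point)
}

# internal: specific force (accelerometer reading) at the pelvis sensor,
# expressed in the sensor frame
pelvis_sensor_acceleration <- function(model, sim) {
  mt <- model$mountings$pelvis
  pk <- point_kinematics(model, sim, "pelvis", mt$lever_arm)
  g <- c(0, 0, -model$gravity)
  Rm <- matrix_from_quat(mt$mount_rotation)
  T <- length(sim$time)
  out <- matrix(0, 3, T, dimnames = list(c("x", "y", "z"), NULL))
  for (s in seq_len(T)) {
    Rs <- pk$R[, , s] %*% Rm
    out[, s] <- t(Rs) %*% (pk$acc[, s] - g)
  }
  out
}

# internal: per-segment orientation quaternion (and Euler) series
segment_orientations <- function(model, sim) {
  bodies <- vapply(model$segments, `[[`, 0L, "body_index") - 1L
  os <- cpp_orient_series(model$cpp, sim$q, bodies)
  out <- lapply(seq_along(bodies), function(j) os$quat[, , j])
  names(out) <- names(model$segments)
  attr(out, "euler") <- stats::setNames(
    lapply(seq_along(bodies), function(j) os$euler[, , j]),
    names(model$segments))
  out
}

#' Ground reaction moment about the ankle ground projection
#'
#' Computes the moment of all per-point contact forces of one foot about
#' the point on the ground directly below the ankle joint centre, expressed
#' in a horizontal frame aligned with the foot's heading (Y anterior along
#' the horizontal projection of the foot axis, Z up, X = Y x Z lateral).
#'
#' @param sim a [simulate_motion()] result.
#' @param model the generating [build_model()] object.
#' @param foot `"left"` or `"right"`.
#' @return 3 x T matrix (N m): sagittal (about lateral X), frontal (about
#'   anterior Y) and transverse (about vertical Z) components.
#' @export
grm_about_ankle <- function(sim, model, foot = c("left", "right")) {
  foot <- match.arg(foot)
  seg <- paste0("foot_", substr(foot, 1, 1))
  T <- length(sim$time)
  out <- matrix(0, 3, T,
                dimnames = list(c("sagittal", "frontal", "transverse"), NULL))
  side <- if (foot == "left") "left" else "right"
  for (s in seq_len(T)) {
    ct <- cpp_contact(model$cpp, sim$q[, s], sim$qd[, s])
    fk <- cpp_fk(model$cpp, sim$q[, s])
    bi <- model$segments[[seg]]$body_index
    ankle <- fk$p[, bi]          # foot-frame origin = ankle centre
    origin <- c(ankle[1], ankle[2], model$ground$rz0)
    Rf <- fk$R[, , bi]
    yh <- Rf %*% c(0, 1, 0); yh[3] <- 0
    ny <- sqrt(sum(yh^2))
    yh <- if (ny > 1e-9) yh / ny else c(0, 1, 0)
    zh <- c(0, 0, 1)
    xh <- c(yh[2], -yh[1], 0)     # yh x zh
    Fm <- ct[[paste0("F_", side)]]
    Pm <- ct[[paste0("pos_", side)]]
    mom <- c(0, 0, 0)
    for (k in seq_len(ncol(Fm))) {
      f <- Fm[, k]
      if (all(f == 0)) next
      r <- Pm[, k] - origin
      mom <- mom + c(r[2] * f[3] - r[3] * f[2],
                     r[3] * f[1] - r[1] * f[3],
                     r[1] * f[2] - r[2] * f[1])
    }
    out[, s] <- c(sum(mom * xh), sum(mom * yh), sum(mom * zh))
  }
  out
}

# internal: total-body COM position/acceleration series from a sim result
com_kinematics <- function(model, sim) {
  T <- length(sim$time)
  pos <- matrix(0, 3, T); acc <- matrix(0, 3, T)
  for (nm in names(model$segments)) {
    s <- model$segments[[nm]]
    pk <- point_kinematics(model, sim, nm, s$com_offset)
    pos <- pos + s$mass * pk$pos
    acc <- acc + s$mass * pk$acc
  }
  list(pos = pos / model$total_mass, acc = acc / model$total_mass)
}

#' Export a simulation result as CSV
#'
#' Writes a wide CSV (time, generalized coordinates, total GRF, GRM of both
#' feet, pelvis sensor acceleration) plus a JSON sidecar with solver
#' metadata.
#'
#' @param sim a [simulate_motion()] result.
#' @param model the generating model.
#' @param path output CSV path; metadata is written to `paste0(path,
#'   ".meta.json")`.
#' @return The data frame, invisibly.
#' @export
write_sim_result <- function(sim, model, path) {
  grml <- grm_about_ankle(sim, model, "left")
  grmr <- grm_about_ankle(sim, model, "right")
  df <- data.frame(time_s = sim$time, t(sim$q), t(sim$qd),
                   grf_x = sim$grf["x", ], grf_y = sim$grf["y", ],
                   grf_z = sim$grf["z", ],
                   grm_left_sag = grml[1, ], grm_left_fro = grml[2, ],
                   grm_left_tra = grml[3, ],
                   grm_right_sag = grmr[1, ], grm_right_fro = grmr[2, ],
                   grm_right_tra = grmr[3, ],
                   pelvis_acc_x = sim$pelvis_acc[1, ],
                   pelvis_acc_y = sim$pelvis_acc[2, ],
                   pelvis_acc_z = sim$pelvis_acc[3, ],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(method = sim$method, rtol = sim$rtol, atol = sim$atol,
               out_hz = sim$out_hz, nsteps = sim$nsteps, nfev = sim$nfev,
               height = model$height, weight = model$weight)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(df)
}
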