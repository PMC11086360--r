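#' EKF parameters
#'
#' Noise scales and initial covariance of the paired-IMU orientation
#' filter.  `v` is the observation noise standard deviation; `w` is a
#' continuous-time process random-walk intensity whose per-step
#' covariance is `diag(w^2 dt)`.
#'
#' @param w process-noise scale per quaternion-state component (length 8,
#'   quaternion units per sqrt(s)).
#' @param v observation-noise scale per acceleration component
#'   (m/s^2, length 6).
#' @param P0 initial state covariance (8 x 8).
#' @param dt sampling interval (s).
#' @param gate innovation gate: updates whose normalized innovation
#'   squared `nu' S^-1 nu` exceeds this chi-square threshold are skipped,
#'   so the filter coasts on gyro integration through transients (ground
#'   impacts, push-off) where the finite-difference angular-acceleration
#'   compensation is unreliable.  `NULL` disables gating.
#' @return List of class `ekf_params`.
#' @export
ekf_params <- function(w = rep(1e-3, 8), v = rep(1e-1, 6),
                       P0 = diag(1e2, 8), dt = 1e-3,
                       gate = stats::qchisq(0.999, 6)) {
  stopifnot(all(w > 0), all(v > 0), dt > 0, nrow(P0) == 8)
  # w is a continuous-time random-walk intensity (quaternion units per
  # sqrt(s)): the per-step process covariance scales with dt, keeping
  # the drift rate of the unobservable common-mode independent of the
  # sampling rate
  structure(list(w = w, v = v, P0 = P0, dt = dt, gate = gate,
                 W = diag(w^2 * dt), V = diag(v^2)),
            class = "ekf_params")
}

#' Quaternion angular-rate matrix
#'
#' The 4 x 4 skew matrix `Omega(omega)` of the quaternion kinematics
#' `qdot = 1/2 Omega q` for a body-frame angular velocity, scalar-first
#' convention.
#'
#' @param omega angular velocity 3-vector (rad/s).
#' @return 4 x 4 antisymmetric matrix.
#' @export
omega_matrix <- function(omega) {
  wx <- omega[1]; wy <- omega[2]; wz <- omega[3]
  matrix(c(0, -wx, -wy, -wz,
           wx, 0, wz, -wy,
           wy, -wz, 0, wx,
           wz, wy, -wx, 0), 4, 4, byrow = TRUE)
}

#' Centripetal plus tangential acceleration at a sensor
#'
#' The acceleration of a point rigidly attached at lever arm `ls` from the
#' rotation centre: `omega x (omega x ls) + omegadot x ls`, all in the
#' sensor/segment frame.  Subtracting this from the accelerometer output
#' leaves the shared gravitational + translational component that the
#' paired-sensor observation compares.
#'
#' @param omega angular velocity (rad/s).
#' @param omegadot angular acceleration (rad/s^2).
#' @param ls lever arm from the proximal joint to the sensor (m).
#' @return 3-vector (m/s^2).
#' @export
centripetal_tangential <- function(omega, omegadot, ls) {
  cross3(omega, cross3(omega, ls)) + cross3(omegadot, ls)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Initialize an EKF state
#'
#' @param q_s,q_s1 initial quaternions of the two links (scalar first).
#' @param params an [ekf_params()].
#' @return List of class `ekf_state` with `x` (8-vector) and `P`.
#' @export
ekf_state <- function(q_s = c(1, 0, 0, 0), q_s1 = c(1, 0, 0, 0),
                      params = ekf_params()) {
  structure(list(x = c(quat_normalize(q_s), quat_normalize(q_s1)),
                 P = params$P0), class = "ekf_state")
}

#' EKF prediction step
#'
#' Propagates both quaternions by first-order integration of the gyro
#' rates, `x <- (I + dt/2 blkdiag(Omega_s, Omega_s1)) x`, renormalizes
#' them (the first-order transition does not preserve unit norm), and
#' inflates the covariance by the process noise.
#'
#' @param state an [ekf_state()].
#' @param omega_s,omega_s1 body-frame gyro samples of the two links
#'   (rad/s).
#' @param params an [ekf_params()].
#' @return Updated `ekf_state`.
#' @export
ekf_predict <- function(state, omega_s, omega_s1, params) {
  Fm <- diag(8)
  Fm[1:4, 1:4] <- Fm[1:4, 1:4] + params$dt / 2 * omega_matrix(omega_s)
  Fm[5:8, 5:8] <- Fm[5:8, 5:8] + params$dt / 2 * omega_matrix(omega_s1)
  x <- Fm %*% state$x
  x[1:4] <- quat_normalize(x[1:4])
  x[5:8] <- quat_normalize(x[5:8])
  P <- Fm %*% state$P %*% t(Fm) + params$W
  structure(list(x = as.numeric(x), P = (P + t(P)) / 2,
                 n_gated = state$n_gated),
            class = "ekf_state")
}

# 3 x 4 Jacobian of R(q) v with respect to q (R maps body -> global)
dRv_dq <- function(q, v) {
  v <- as.numeric(v)
  w <- q[1]; u <- q[2:4]
  uxv <- cross3(u, v)
  dw <- 2 * (w * v + uxv)
  du <- 2 * (sum(u * v) * diag(3) + u %o% v - v %o% u - w * skew3(v))
  cbind(dw, du)
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
         byrow = TRUE)
}

# homogeneous quaternion rotation (valid derivative for non-unit q); the
# analytic Jacobian below linearizes this form
rot_hom <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  (w^2 - sum(u^2)) * v + 2 * u * sum(u * v) + 2 * w * cross3(u, v)
}

# observation in the homogeneous form (equals ekf_h at unit quaternions)
ekf_h_hom <- function(x, b_s, b_s1) {
  qs <- x[1:4]; qs1 <- x[5:8]
  c(rot_hom(quat_conj(qs), rot_hom(qs1, b_s1)),
    rot_hom(quat_conj(qs1), rot_hom(qs, b_s)))
}

# innovation h(x): what each sensor's compensated acceleration should look
# like seen through the other link's frame
ekf_h <- function(x, b_s, b_s1) {
  Rs <- matrix_from_quat(x[1:4]); Rs1 <- matrix_from_quat(x[5:8])
  c(t(Rs) %*% (Rs1 %*% b_s1), t(Rs1) %*% (Rs %*% b_s))
}

ekf_H <- function(x, b_s, b_s1) {
  qs <- x[1:4]; qs1 <- x[5:8]
  Rs <- matrix_from_quat(qs); Rs1 <- matrix_from_quat(qs1)
  Dconj <- diag(c(1, -1, -1, -1))
  H <- matrix(0, 6, 8)
  w1 <- Rs1 %*% b_s1
  H[1:3, 1:4] <- dRv_dq(quat_conj(qs), w1) %*% Dconj
  H[1:3, 5:8] <- t(Rs) %*% dRv_dq(qs1, b_s1)
  w2 <- Rs %*% b_s
  H[4:6, 5:8] <- dRv_dq(quat_conj(qs1), w2) %*% Dconj
  H[4:6, 1:4] <- t(Rs1) %*% dRv_dq(qs, b_s)
  H
}

#' EKF measurement update
#'
#' Updates the paired quaternion state from the two accelerometer outputs
#' after compensation of centripetal and tangential components.  The
#' observation compares each link's compensated acceleration with the
#' other link's, rotated across the joint, so only the relative
#' orientation is observable; a common heading offset leaves the
#' innovation unchanged.
#'
#' @param state an [ekf_state()].
#' @param a_s,a_s1 raw accelerometer outputs (m/s^2, sensor frames).
#' @param a_ct_s,a_ct_s1 centripetal+tangential compensation terms from
#'   [centripetal_tangential()].
#' @param params an [ekf_params()].
#' @return Updated `ekf_state`.
#' @export
ekf_update <- function(state, a_s, a_s1, a_ct_s, a_ct_s1, params) {
  b_s <- a_s - a_ct_s
  b_s1 <- a_s1 - a_ct_s1
  z <- c(b_s, b_s1)
  h <- ekf_h(state$x, b_s, b_s1)
  H <- ekf_H(state$x, b_s, b_s1)
  S <- H %*% state$P %*% t(H) + params$V
  Sc <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(Sc)) {
    warning("innovation covariance singular; regularizing")
    S <- S + diag(1e-9 * max(diag(S)), 6)
    Sc <- chol(S)
  }
  Sinv <- chol2inv(Sc)
  nu <- z - h
  if (!is.null(params$gate) &&
      drop(t(nu) %*% Sinv %*% nu) > params$gate) {
    ng <- if (is.null(state$n_gated)) 0 else state$n_gated
    if (ng < 100) {   # rescue: never reject indefinitely
      state$n_gated <- ng + 1
      return(state)
    }
  }
  K <- state$P %*% t(H) %*% Sinv
  dx <- as.numeric(K %*% nu)
  # The observation carries no information about a common rotation of
  # both links.  Decompose the correction in the tangent basis spanned by
  # common rotations (N), rotations of the distal link only (M, which
  # alter the relative orientation) and the radial norm directions, and
  # keep only the relative part: absolute orientation is then maintained
  # by gyro integration alone and residual model error cannot push it.
  qs <- state$x[1:4]; qs1 <- state$x[5:8]
  B <- matrix(0, 8, 8)
  for (j in 1:3) {
    e <- c(0, as.numeric(1:3 == j))
    B[, j] <- 0.5 * c(quat_mult(e, qs), quat_mult(e, qs1))       # common
    B[, 3 + j] <- 0.5 * c(rep(0, 4), quat_mult(e, qs1))          # relative
  }
  B[1:4, 7] <- qs; B[5:8, 8] <- qs1                              # radial
  coords <- tryCatch(solve(B, dx), error = function(e) NULL)
  if (!is.null(coords)) {
    keep <- coords
    keep[c(1:3, 7:8)] <- 0
    dx <- as.numeric(B %*% keep)
  }
  x <- state$x + dx
  x[1:4] <- quat_normalize(x[1:4])
  x[5:8] <- quat_normalize(x[5:8])
  IKH <- diag(8) - K %*% H
  P <- IKH %*% state$P %*% t(IKH) + K %*% params$V %*% t(K)
  structure(list(x = x, P = (P + t(P)) / 2, n_gated = 0),
            class = "ekf_state")
}

# internal: angular acceleration by central differences on the gyro
# series after a zero-phase low-pass (raw differentiation amplifies the
# gyro white noise far beyond the modeled observation noise).  The
# band-limited estimate is briefly wrong through contact transients;
# those updates are rejected by the innovation gate.
gyro_derivative <- function(gyr, rate, lowpass_hz = 18) {
  g <- gyr
  if (!is.null(lowpass_hz) && rate > 2.5 * lowpass_hz)
    g <- t(apply(gyr, 1, butterworth_lowpass, rate = rate,
                 cutoff = lowpass_hz))
  T <- ncol(g)
  gd <- matrix(0, 3, T)
  if (T >= 3) {
    gd[, 2:(T - 1)] <- (g[, 3:T] - g[, 1:(T - 2)]) * (rate / 2)
    gd[, 1] <- (g[, 2] - g[, 1]) * rate
    gd[, T] <- (g[, T] - g[, T - 1]) * rate
  }
  gd
}

#' Run the paired-IMU EKF over a trial
#'
#' Alternates prediction (gyro integration) and update (compensated
#' acceleration comparison) over the full series for two sensors spanning
#' one joint, and returns both quaternion series.
#'
#' @param trial an [imu_trial()] object.
#' @param pair character vector of two segment names, proximal first.
#' @param params an [ekf_params()]; its `dt` is overridden by the trial
#'   rate.
#' @param init optional list with `q_s`, `q_s1` initial quaternions;
#'   defaults to identity.
#' @param lever_arms optional list overriding the trial mountings.
#' @return List with `time`, `q_s`, `q_s1` (4 x T quaternion series of
#'   the SENSOR frames) and the final `state`.
#' @export
run_pair_ekf <- function(trial, pair, params = ekf_params(), init = NULL,
                         lever_arms = NULL) {
  stopifnot(inherits(trial, "imu_trial"), length(pair) == 2)
  if (!all(pair %in% names(trial$sensors)))
    stop("sensors missing for pair: ",
         paste(setdiff(pair, names(trial$sensors)), collapse = ", "))
  sA <- trial$sensors[[pair[1]]]; sB <- trial$sensors[[pair[2]]]
  T <- ncol(sA$acc)
  if (ncol(sB$acc) != T || ncol(sA$gyr) != T || ncol(sB$gyr) != T)
    stop("sensor series lengths differ; gap in trial data")
  dt_new <- 1 / trial$rate
  if (abs(dt_new - params$dt) > 1e-12) {
    params$W <- params$W * (dt_new / params$dt)
    params$dt <- dt_new
  }
  la <- if (!is.null(lever_arms)) lever_arms else
    list(trial$mountings[[pair[1]]]$lever_arm,
         trial$mountings[[pair[2]]]$lever_arm)
  gdA <- gyro_derivative(sA$gyr, trial$rate)
  gdB <- gyro_derivative(sB$gyr, trial$rate)
  st <- if (is.null(init)) ekf_state(params = params)
        else ekf_state(init$q_s, init$q_s1, params)
  # the zero-phase derivative filter needs past and future samples; its
  # estimates inside the edge-settling window are unreliable, so the
  # filter coasts on prediction there instead of updating
  margin <- max(2, round(0.15 * trial$rate))
  QA <- matrix(0, 4, T); QB <- matrix(0, 4, T)
  for (k in seq_len(T)) {
    if (k > 1) st <- ekf_predict(st, sA$gyr[, k], sB$gyr[, k], params)
    if (k > margin && k <= T - margin) {
      actA <- centripetal_tangential(sA$gyr[, k], gdA[, k], la[[1]])
      actB <- centripetal_tangential(sB$gyr[, k], gdB[, k], la[[2]])
      st <- ekf_update(st, sA$acc[, k], sB$acc[, k], actA, actB, params)
    }
    QA[, k] <- st$x[1:4]; QB[, k] <- st$x[5:8]
  }
  list(time = trial$time, q_s = QA, q_s1 = QB, state = st)
}

# internal: lever arms of the two sensors of a pair, both measured from
# the joint the pair spans.  The child's mounting lever is already
# joint-referenced; the parent's is re-referenced from the parent frame
# origin to the connecting joint.
pair_lever_arms <- function(model, parent_seg, child_seg) {
  pb <- model$segments[[parent_seg]]$body_index
  cb <- model$segments[[child_seg]]$body_index
  i <- cb
  repeat {
    p <- model$cpp$parent[i] + 1L
    if (p == pb) break
    i <- p
    if (p <= 0) stop("segments are not adjacent in the tree")
  }
  joint_offset <- model$cpp$offset[, i]
  list(model$mountings[[parent_seg]]$lever_arm - joint_offset,
       model$mountings[[child_seg]]$lever_arm)
}

# kinematic-tree sensor pairs (proximal segment first)
segment_pairs <- function() {
  list(c("pelvis", "trunk"),
       c("pelvis", "thigh_l"), c("thigh_l", "shank_l"),
       c("shank_l", "foot_l"),
       c("pelvis", "thigh_r"), c("thigh_r", "shank_r"),
       c("shank_r", "foot_r"),
       c("trunk", "upper_arm_l"), c("upper_arm_l", "forearm_l"),
       c("trunk", "upper_arm_r"), c("upper_arm_r", "forearm_r"))
}

segment_parent <- function() {
  c(trunk = "pelvis", thigh_l = "pelvis", shank_l = "thigh_l",
    foot_l = "shank_l", thigh_r = "pelvis", shank_r = "thigh_r",
    foot_r = "shank_r", upper_arm_l = "trunk", forearm_l = "upper_arm_l",
    upper_arm_r = "trunk", forearm_r = "upper_arm_r")
}

#' Estimate all segment orientations from an IMU trial
#'
#' Runs one paired EKF per joint of the kinematic tree and composes the
#' pairwise relative orientations outward from the pelvis into global
#' segment orientations.  The pelvis absolute orientation is taken from
#' the pelvis-trunk pair filter (initialized from calibration and
#' corrected only through the pairwise constraint), so absolute heading
#' drifts slowly with gyro bias; relative orientations are drift-
#' corrected by the acceleration observations.
#'
#' @param trial an [imu_trial()]; sensors must form a connected subtree
#'   containing the pelvis.
#' @param model a [build_model()] (for mount rotations).
#' @param params an [ekf_params()].
#' @param init optional named list of initial SENSOR quaternions per
#'   segment (e.g. from [init_from_calibration()]).
#' @return Object of class `orientation_estimate`: `time`, `quat` (named
#'   list of 4 x T segment quaternion series, global frame), `euler`
#'   (named list of 3 x T intrinsic X-Y-Z Euler series).
#' @export
chain_orientations <- function(trial, model, params = ekf_params(),
                               init = NULL) {
  stopifnot(inherits(trial, "imu_trial"))
  sens <- names(trial$sensors)
  if (!("pelvis" %in% sens))
    stop("sensor set must include the pelvis (root) sensor")
  parent <- segment_parent()
  usable <- vapply(sens, function(s)
    s == "pelvis" || (s %in% names(parent) && parent[[s]] %in% sens),
    TRUE)
  if (!all(usable))
    stop("disconnected sensor graph: ",
         paste(sens[!usable], collapse = ", "))
  pairs <- Filter(function(p) all(p %in% sens), segment_pairs())
  fits <- lapply(pairs, function(p) {
    pi <- if (is.null(init)) NULL else
      list(q_s = init[[p[1]]], q_s1 = init[[p[2]]])
    run_pair_ekf(trial, p, params, init = pi,
                 lever_arms = pair_lever_arms(model, p[1], p[2]))
  })
  names(fits) <- vapply(pairs, function(p) paste(p, collapse = "-"), "")
  T <- length(trial$time)
  quat <- list()
  # pelvis from the pelvis-trunk pair (or first pelvis pair available)
  root_pair <- which(vapply(pairs, function(p) p[1] == "pelvis", TRUE))[1]
  quat$pelvis <- fits[[root_pair]]$q_s
  todo <- setdiff(sens, "pelvis")
  while (length(todo)) {
    progressed <- FALSE
    for (s in todo) {
      p <- parent[[s]]
      if (!(p %in% names(quat))) next
      pid <- which(vapply(pairs, function(pp) pp[1] == p && pp[2] == s,
                          TRUE))[1]
      f <- fits[[pid]]
      Qs <- matrix(0, 4, T)
      for (k in seq_len(T)) {
        rel <- quat_mult(quat_conj(f$q_s[, k]), f$q_s1[, k])
        Qs[, k] <- quat_normalize(quat_mult(quat[[p]][, k], rel))
      }
      quat[[s]] <- Qs
      todo <- setdiff(todo, s)
      progressed <- TRUE
    }
    if (!progressed) stop("disconnected sensor graph")
  }
  # sensor -> segment via mount rotations
  for (s in names(quat)) {
    qm <- model$mountings[[s]]$mount_rotation
    if (!is.null(qm) && any(abs(qm - c(1, 0, 0, 0)) > 1e-12)) {
      qmc <- quat_conj(qm)
      for (k in seq_len(T))
        quat[[s]][, k] <- quat_mult(quat[[s]][, k], qmc)
    }
  }
  euler <- lapply(quat, function(Q) {
    E <- apply(Q, 2, euler_xyz_from_quat)
    rownames(E) <- c("phi", "theta", "psi")
    E
  })
  structure(list(time = trial$time, quat = quat, euler = euler,
                 pairs = names(fits)),
            class = "orientation_estimate")
}

#' Initial orientations and neutral pose from a calibration window
#'
#' From a quasi-static window of IMU data, recovers each sensor's roll and
#' pitch from the gravity direction of the time-averaged acceleration
#' (yaw is defined as zero in the calibration heading) and derives the
#' model's neutral joint angles from the relative segment orientations.
#'
#' @param window an [imu_trial()] restricted to the static calibration
#'   posture.
#' @param model a [build_model()] object.
#' @param static_gyro_tol maximum mean gyro norm (rad/s) for the window to
#'   count as static.
#' @return List with `quat` (named initial SENSOR quaternions), `neutral`
#'   (named joint angles, rad) and `tilt` (per-sensor roll/pitch, rad).
#' @export
init_from_calibration <- function(window, model, static_gyro_tol = 0.1) {
  stopifnot(inherits(window, "imu_trial"))
  gnorm <- vapply(window$sensors, function(s)
    mean(sqrt(colSums(s$gyr^2))), 0)
  if (any(gnorm > static_gyro_tol))
    stop("calibration window not static (mean gyro norm ",
         signif(max(gnorm), 3), " rad/s)")
  quat <- list(); tilt <- list()
  for (s in names(window$sensors)) {
    a <- rowMeans(window$sensors[[s]]$acc)
    a <- a / sqrt(sum(a^2))
    phi <- asin(max(-1, min(1, a[2])))
    theta <- atan2(-a[1], a[3])
    quat[[s]] <- quat_from_euler_xyz(c(phi, theta, 0))
    tilt[[s]] <- c(roll = phi, pitch = theta)
  }
  # neutral joint angles from relative sensor orientations (identity
  # mounts assumed segment-aligned)
  parent <- segment_parent()
  neutral <- c()
  jmap <- c(trunk = "lumbar", thigh_l = "hip_l", thigh_r = "hip_r",
            shank_l = "knee_l", shank_r = "knee_r", foot_l = "ankle_l",
            foot_r = "ankle_r", upper_arm_l = "shoulder_l",
            upper_arm_r = "shoulder_r", forearm_l = "elbow_l",
            forearm_r = "elbow_r")
  three_dof <- c("lumbar", "hip_l", "hip_r", "shoulder_l", "shoulder_r")
  for (s in names(quat)) {
    p <- parent[s]
    if (is.na(p) || !(p %in% names(quat))) next
    rel <- quat_mult(quat_conj(quat[[p]]), quat[[s]])
    e <- euler_xyz_from_quat(rel)
    j <- jmap[[s]]
    if (j %in% three_dof) {
      neutral[paste0(j, c("_x", "_y", "_z"))] <- unname(e)
    } else {
      neutral[j] <- unname(e[1])
    }
  }
  list(quat = quat, neutral = neutral, tilt = tilt)
}
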