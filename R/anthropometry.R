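#' Default anthropometry table
#'
#' Segment mass fractions, length fractions (of stature), centre-of-mass
#' locations and radii of gyration used to scale the 12-segment model from a
#' participant's height and weight.  Values are a de Leva-style
#' adjusted-Zatsiorsky adult set, rounded, with the head+neck lumped into the
#' trunk segment and the hand lumped into the forearm (the model has no
#' separate head or hand segments).  All entries can be replaced by supplying
#' a modified copy to [build_model()].
#'
#' @details Columns of `$segments`:
#' \describe{
#'   \item{segment}{one of `pelvis`, `trunk`, `upper_arm`, `forearm`,
#'     `thigh`, `shank`, `foot` (bilateral segments share one row)}
#'   \item{mass_frac}{segment mass as a fraction of body mass; fractions are
#'     renormalized to sum to exactly 1 at build time}
#'   \item{length_frac}{segment length as a fraction of stature}
#'   \item{com_frac}{COM distance from the proximal joint along the segment
#'     long axis, as a fraction of segment length}
#'   \item{k_t, k_l}{radii of gyration about the transverse and longitudinal
#'     axes through the COM, as fractions of segment length}
#' }
#' `hip_half_spacing` and `shoulder_half_spacing` are lateral joint-centre
#' offsets as fractions of stature.
#'
#' @return A list with elements `segments` (data frame), `hip_half_spacing`,
#'   `shoulder_half_spacing`.
#' @export
default_anthropometry <- function() {
  segments <- data.frame(
    segment     = c("pelvis", "trunk", "upper_arm", "forearm",
                    "thigh", "shank", "foot"),
    mass_frac   = c(0.1117, 0.3923, 0.0271, 0.0223, 0.1416, 0.0433, 0.0137),
    length_frac = c(0.090, 0.288, 0.186, 0.146, 0.245, 0.246, 0.152),
    com_frac    = c(0.40, 0.55, 0.436, 0.530, 0.433, 0.433, 0.44),
    k_t         = c(0.31, 0.35, 0.285, 0.295, 0.329, 0.255, 0.257),
    k_l         = c(0.30, 0.16, 0.158, 0.130, 0.149, 0.103, 0.124),
    stringsAsFactors = FALSE
  )
  list(segments = segments,
       hip_half_spacing = 0.0955,
       shoulder_half_spacing = 0.1295)
}

#' Default foot geometry
#'
#' Landmark distances defining the sole polygon of each foot: distances from
#' the ankle to the heel, to the metatarsophalangeal (MTP) joint line and to
#' the tip of the second proximal phalanx, the widths at the heel, MTP line
#' and between the first and second proximal phalanges, and the heights of
#' the ankle and the first proximal phalanx above the ground.  Defaults scale
#' with stature.
#'
#' @param height participant stature (m).
#' @return A named list of distances in metres (`d_heel`, `d_mtp`, `d_toe`,
#'   `w_heel`, `w_mtp`, `w_phal`, `h_ankle`, `h_phal`).
#' @export
default_foot_geometry <- function(height = 1.7) {
  lf <- 0.152 * height
  list(d_heel = 0.25 * lf, d_mtp = 0.45 * lf, d_toe = 0.75 * lf,
       w_heel = 0.25 * lf, w_mtp = 0.35 * lf, w_phal = 0.16 * lf,
       h_ankle = 0.039 * height, h_phal = 0.020 * height)
}

# joint coordinate bookkeeping: one row per rotational DOF, in generalized-
# coordinate order (root coordinates excluded)
joint_coord_names <- function() {
  c("hip_l_x", "hip_l_y", "hip_l_z", "knee_l", "ankle_l",
    "hip_r_x", "hip_r_y", "hip_r_z", "knee_r", "ankle_r",
    "lumbar_x", "lumbar_y", "lumbar_z",
    "shoulder_l_x", "shoulder_l_y", "shoulder_l_z", "elbow_l",
    "shoulder_r_x", "shoulder_r_y", "shoulder_r_z", "elbow_r")
}

#' Default anatomical joint limits
#'
#' Ranges of motion (rad) per joint rotational DOF, used by the passive
#' double-exponential limit torque.  Signs follow the model's intrinsic
#' X-Y-Z convention (X flexion-extension, Y adduction-abduction, Z axial
#' rotation; knee flexion and elbow extension are negative X rotations).
#'
#' @return Data frame with columns `coord`, `q_min`, `q_max` (rad).
#' @export
default_joint_limits <- function() {
  lim <- list(
    hip_x = c(-0.5, 2.1), hip_y = c(-0.9, 0.9), hip_z = c(-0.9, 0.9),
    knee = c(-2.3, 0.05), ankle = c(-0.9, 0.6),
    lumbar_x = c(-0.8, 0.8), lumbar_y = c(-0.8, 0.8), lumbar_z = c(-0.8, 0.8),
    shoulder_x = c(-1.0, 3.0), shoulder_y = c(-1.5, 1.5),
    shoulder_z = c(-1.5, 1.5), elbow = c(-0.05, 2.5)
  )
  key <- c(hip_l_x = "hip_x", hip_l_y = "hip_y", hip_l_z = "hip_z",
           knee_l = "knee", ankle_l = "ankle",
           hip_r_x = "hip_x", hip_r_y = "hip_y", hip_r_z = "hip_z",
           knee_r = "knee", ankle_r = "ankle",
           lumbar_x = "lumbar_x", lumbar_y = "lumbar_y", lumbar_z = "lumbar_z",
           shoulder_l_x = "shoulder_x", shoulder_l_y = "shoulder_y",
           shoulder_l_z = "shoulder_z", elbow_l = "elbow",
           shoulder_r_x = "shoulder_x", shoulder_r_y = "shoulder_y",
           shoulder_r_z = "shoulder_z", elbow_r = "elbow")
  cn <- joint_coord_names()
  data.frame(coord = cn,
             q_min = vapply(cn, function(n) lim[[key[[n]]]][1], 0),
             q_max = vapply(cn, function(n) lim[[key[[n]]]][2], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default maximum joint torques
#'
#' Maximum positive and negative voluntary joint torques (N m) per joint DOF,
#' used to normalize active torque in the muscle-load cost term.  These are
#' literature-scale defaults for healthy adults; the negative maximum is
#' stored as a negative number so that the normalized extension effort
#' `tau_a / tau_minus_max` is non-negative.  Override via [build_model()].
#'
#' @return Data frame with columns `coord`, `tau_plus_max` (> 0) and
#'   `tau_minus_max` (< 0), both in N m.
#' @export
default_torque_limits <- function() {
  tl <- list(
    hip_x = c(150, -200), hip_y = c(100, -100), hip_z = c(60, -60),
    knee = c(150, -120), ankle = c(80, -140),
    lumbar_x = c(200, -250), lumbar_y = c(150, -150), lumbar_z = c(90, -90),
    shoulder_x = c(70, -70), shoulder_y = c(70, -70), shoulder_z = c(40, -40),
    elbow = c(60, -45)
  )
  key <- c(hip_l_x = "hip_x", hip_l_y = "hip_y", hip_l_z = "hip_z",
           knee_l = "knee", ankle_l = "ankle",
           hip_r_x = "hip_x", hip_r_y = "hip_y", hip_r_z = "hip_z",
           knee_r = "knee", ankle_r = "ankle",
           lumbar_x = "lumbar_x", lumbar_y = "lumbar_y", lumbar_z = "lumbar_z",
           shoulder_l_x = "shoulder_x", shoulder_l_y = "shoulder_y",
           shoulder_l_z = "shoulder_z", elbow_l = "elbow",
           shoulder_r_x = "shoulder_x", shoulder_r_y = "shoulder_y",
           shoulder_r_z = "shoulder_z", elbow_r = "elbow")
  cn <- joint_coord_names()
  data.frame(coord = cn,
             tau_plus_max = vapply(cn, function(n) tl[[key[[n]]]][1], 0),
             tau_minus_max = vapply(cn, function(n) tl[[key[[n]]]][2], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default passive-torque coefficients
#'
#' Coefficients of the passive joint torque
#' `tau_p = -a exp(b (q - q_max)) + a exp(b (q_min - q)) - c qdot`,
#' a double-exponential that is dormant mid-range and rises steeply beyond
#' the anatomical limits, plus light viscous damping.
#'
#' @return Data frame with columns `coord`, `a` (N m), `b` (1/rad),
#'   `c` (N m s/rad).
#' @export
default_passive_params <- function() {
  cn <- joint_coord_names()
  data.frame(coord = cn, a = 2, b = 20, c = 0.1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default control gains
#'
#' PD tracking gains for the active joint torque and the virtual balance
#' torque gains applied to the root (pelvis) Euler rotations.  The yaw
#' component of the virtual gains is zero so that axial rotation of the body
#' is unimpeded.
#'
#' @return List with `K_PD` (N m/rad), `D_PD` (N m s/rad), `K_virtual`
#'   (length-3, N m/rad), `D_virtual` (length-3, N m s/rad).
#' @export
default_gains <- function() {
  list(K_PD = 1000, D_PD = 10,
       K_virtual = c(400, 400, 0), D_virtual = c(40, 40, 0))
}

#' Default ground-contact parameters
#'
#' Viscoelastic normal force and regularized Coulomb friction parameters of
#' the foot-ground contact model.
#'
#' @return List with `K_G` (N/m), `D_G` (N s/m), `mu_s`, `mu_d`
#'   (dimensionless), `rz0` (ground height, m), `friction_reg_speed` (m/s).
#' @export
default_ground <- function() {
  list(K_G = 1.0e3, D_G = 1.0e4, mu_s = 0.7, mu_d = 0.5,
       rz0 = 0, friction_reg_speed = 0.01)
}

#' Default IMU mountings
#'
#' Sensor placements for the 12 IMUs, one per segment: the lever arm from
#' the segment's proximal joint to the sensor origin (segment frame, m) and
#' the sensor-to-segment mounting rotation (unit quaternion, scalar first;
#' identity by default).
#'
#' @param height participant stature (m).
#' @param anthropometry anthropometry list, see [default_anthropometry()].
#' @return Named list of mountings, each with `segment`, `lever_arm`,
#'   `mount_rotation`.
#' @export
default_mountings <- function(height = 1.7,
                              anthropometry = default_anthropometry()) {
  seg <- anthropometry$segments
  L <- function(s) seg$length_frac[seg$segment == s] * height
  fg <- default_foot_geometry(height)
  mk <- function(segment, lever) {
    list(segment = segment, lever_arm = lever,
         mount_rotation = c(1, 0, 0, 0))
  }
  list(
    pelvis      = mk("pelvis", c(0, -0.08, 0)),
    trunk       = mk("trunk", c(0, -0.03, 0.90 * L("trunk"))),
    upper_arm_l = mk("upper_arm_l", c(0, 0, -0.75 * L("upper_arm"))),
    upper_arm_r = mk("upper_arm_r", c(0, 0, -0.75 * L("upper_arm"))),
    forearm_l   = mk("forearm_l", c(0, 0, -0.50 * L("forearm"))),
    forearm_r   = mk("forearm_r", c(0, 0, -0.50 * L("forearm"))),
    thigh_l     = mk("thigh_l", c(0, 0, -0.75 * L("thigh"))),
    thigh_r     = mk("thigh_r", c(0, 0, -0.75 * L("thigh"))),
    shank_l     = mk("shank_l", c(0, 0, -0.95 * L("shank"))),
    shank_r     = mk("shank_r", c(0, 0, -0.95 * L("shank"))),
    foot_l      = mk("foot_l", c(0, 0.3 * (fg$d_mtp), -0.5 * fg$h_ankle)),
    foot_r      = mk("foot_r", c(0, 0.3 * (fg$d_mtp), -0.5 * fg$h_ankle))
  )
}
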