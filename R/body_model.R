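#' Build the articulated human body model
#'
#' Constructs the 12-segment, 27-DOF rigid-body model from a participant's
#' height and weight.  Segments are the trunk (with head lumped in), pelvis,
#' and bilateral upper arms, forearms (hands lumped in), thighs, shanks and
#' feet.  Joints carry 21 rotational DOFs (3-DOF hips, lumbar and shoulders
#' with an intrinsic X-Y-Z Euler sequence; 1-DOF knees, ankles and elbows)
#' and a 6-DOF virtual root joint connects the pelvis to the global frame
#' (Z up, gravity along -Z).  Segment masses are `weight` times the table
#' mass fractions (renormalized to sum to one); lengths scale with `height`;
#' inertia tensors are diagonal in the segment frame from the radii of
#' gyration, `I = m (k L)^2`.
#'
#' @param height participant stature in metres, in `[1.0, 2.3]`.
#' @param weight participant body mass in kg, in `[20, 200]`.
#' @param anthropometry anthropometry table, see [default_anthropometry()].
#' @param joint_limits data frame of anatomical limits,
#'   see [default_joint_limits()].
#' @param torque_limits data frame of maximum joint torques,
#'   see [default_torque_limits()].
#' @param passive data frame of passive-torque coefficients,
#'   see [default_passive_params()].
#' @param gains control gains, see [default_gains()].
#' @param ground contact parameters, see [default_ground()].
#' @param foot_geometry sole landmark distances,
#'   see [default_foot_geometry()].
#' @param mountings IMU mounting list, see [default_mountings()].
#' @param neutral optional named numeric vector of neutral joint angles
#'   (rad) overriding the zero default, names as in the model's coordinate
#'   table.
#' @param gravity gravitational acceleration magnitude (m/s^2).
#'
#' @return An object of class `body_model`: a list with the segment table,
#'   joint coordinate table (limits, torque maxima, passive coefficients),
#'   contact point sets, mountings, and the internal kinematic-tree
#'   description used by the dynamics engine.
#' @examples
#' m <- build_model(height = 1.69, weight = 63.3)
#' m$total_mass
#' nrow(m$coords)   # 21 rotational joint DOFs
#' @export
build_model <- function(height, weight,
                        anthropometry = default_anthropometry(),
                        joint_limits = default_joint_limits(),
                        torque_limits = default_torque_limits(),
                        passive = default_passive_params(),
                        gains = default_gains(),
                        ground = default_ground(),
                        foot_geometry = default_foot_geometry(height),
                        mountings = default_mountings(height, anthropometry),
                        neutral = NULL,
                        gravity = 9.81) {
  if (!is.numeric(height) || height < 1.0 || height > 2.3)
    stop("height must be in [1.0, 2.3] m")
  if (!is.numeric(weight) || weight < 20 || weight > 200)
    stop("weight must be in [20, 200] kg")
  seg <- anthropometry$segments
  need <- c("pelvis", "trunk", "upper_arm", "forearm", "thigh", "shank",
            "foot")
  if (!all(need %in% seg$segment))
    stop("anthropometry table must cover segments: ",
         paste(setdiff(need, seg$segment), collapse = ", "))
  seg <- seg[match(need, seg$segment), ]
  bilateral <- c("upper_arm", "forearm", "thigh", "shank", "foot")
  mult <- ifelse(seg$segment %in% bilateral, 2, 1)
  # renormalize so segment masses sum to the input weight exactly
  seg$mass_frac <- seg$mass_frac / sum(seg$mass_frac * mult)

  row <- function(s) seg[seg$segment == s, ]
  lengths <- stats::setNames(seg$length_frac * height, seg$segment)
  masses <- stats::setNames(seg$mass_frac * weight, seg$segment)
  hip_half <- anthropometry$hip_half_spacing * height
  sho_half <- anthropometry$shoulder_half_spacing * height
  fg <- foot_geometry

  inertia_diag <- function(s, long_axis = "z") {
    r <- row(s)
    m <- masses[[s]]; L <- lengths[[s]]
    it <- m * (r$k_t * L)^2
    il <- m * (r$k_l * L)^2
    d <- c(x = it, y = it, z = it)
    d[long_axis] <- il
    diag(unname(d[c("x", "y", "z")]))
  }

  # COM in segment frame (origin at proximal joint; long axis +Z except the
  # foot, whose long axis is +Y anterior with origin at the ankle)
  com_of <- function(s, sign_z = -1) c(0, 0, sign_z * row(s)$com_frac *
                                         lengths[[s]])
  foot_com <- c(0, row("foot")$com_frac * lengths[["foot"]] - fg$d_heel,
                -0.5 * fg$h_ankle)

  cp <- foot_contact_points(fg)

  # ---- kinematic tree: 27 chained 1-DOF joints, topologically ordered ----
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1); z3 <- c(0, 0, 0)
  tree <- list()  # each: parent (1-based, 0 = world), jtype, axis, offset
  add <- function(tree, name, parent, jtype, axis, offset,
                  segment = NA_character_) {
    tree[[name]] <- list(parent = parent, jtype = jtype, axis = axis,
                         offset = offset, segment = segment)
    tree
  }
  tree <- add(tree, "root_tx", 0L, 0L, ex, z3)
  tree <- add(tree, "root_ty", 1L, 0L, ey, z3)
  tree <- add(tree, "root_tz", 2L, 0L, ez, z3)
  tree <- add(tree, "root_rx", 3L, 1L, ex, z3)
  tree <- add(tree, "root_ry", 4L, 1L, ey, z3)
  tree <- add(tree, "root_rz", 5L, 1L, ez, z3, "pelvis")
  # left leg (+X lateral side)
  tree <- add(tree, "hip_l_x", 6L, 1L, ex, c(hip_half, 0, 0))
  tree <- add(tree, "hip_l_y", 7L, 1L, ey, z3)
  tree <- add(tree, "hip_l_z", 8L, 1L, ez, z3, "thigh_l")
  tree <- add(tree, "knee_l", 9L, 1L, ex, c(0, 0, -lengths[["thigh"]]),
              "shank_l")
  tree <- add(tree, "ankle_l", 10L, 1L, ex, c(0, 0, -lengths[["shank"]]),
              "foot_l")
  tree <- add(tree, "hip_r_x", 6L, 1L, ex, c(-hip_half, 0, 0))
  tree <- add(tree, "hip_r_y", 12L, 1L, ey, z3)
  tree <- add(tree, "hip_r_z", 13L, 1L, ez, z3, "thigh_r")
  tree <- add(tree, "knee_r", 14L, 1L, ex, c(0, 0, -lengths[["thigh"]]),
              "shank_r")
  tree <- add(tree, "ankle_r", 15L, 1L, ex, c(0, 0, -lengths[["shank"]]),
              "foot_r")
  tree <- add(tree, "lumbar_x", 6L, 1L, ex, c(0, 0, lengths[["pelvis"]]))
  tree <- add(tree, "lumbar_y", 17L, 1L, ey, z3)
  tree <- add(tree, "lumbar_z", 18L, 1L, ez, z3, "trunk")
  tree <- add(tree, "shoulder_l_x", 19L, 1L, ex,
              c(sho_half, 0, lengths[["trunk"]]))
  tree <- add(tree, "shoulder_l_y", 20L, 1L, ey, z3)
  tree <- add(tree, "shoulder_l_z", 21L, 1L, ez, z3, "upper_arm_l")
  tree <- add(tree, "elbow_l", 22L, 1L, ex, c(0, 0, -lengths[["upper_arm"]]),
              "forearm_l")
  tree <- add(tree, "shoulder_r_x", 19L, 1L, ex,
              c(-sho_half, 0, lengths[["trunk"]]))
  tree <- add(tree, "shoulder_r_y", 24L, 1L, ey, z3)
  tree <- add(tree, "shoulder_r_z", 25L, 1L, ez, z3, "upper_arm_r")
  tree <- add(tree, "elbow_r", 26L, 1L, ex, c(0, 0, -lengths[["upper_arm"]]),
              "forearm_r")

  nb <- length(tree)
  seg_of_body <- vapply(tree, function(b) b$segment, "")
  seg_base <- function(s) sub("_(l|r)$", "", s)

  mass_v <- numeric(nb)
  com_m <- matrix(0, 3, nb)
  inert <- rep(list(matrix(0, 3, 3)), nb)
  segments <- list()
  for (i in seq_len(nb)) {
    s <- seg_of_body[i]
    if (is.na(s)) next
    base <- seg_base(s)
    mass_v[i] <- masses[[base]]
    if (base == "foot") {
      com_m[, i] <- foot_com
      inert[[i]] <- inertia_diag("foot", long_axis = "y")
    } else if (base %in% c("trunk", "pelvis")) {
      com_m[, i] <- com_of(base, sign_z = +1)
      inert[[i]] <- inertia_diag(base)
    } else {
      com_m[, i] <- com_of(base, sign_z = -1)
      inert[[i]] <- inertia_diag(base)
    }
    segments[[s]] <- list(
      name = s, mass = mass_v[i], length = lengths[[base]],
      com_offset = com_m[, i], inertia = inert[[i]],
      parent_joint = names(tree)[i], body_index = i)
  }

  coords <- joint_coord_names()
  stopifnot(identical(coords, names(tree)[7:nb]))
  jl <- joint_limits[match(coords, joint_limits$coord), ]
  tq <- torque_limits[match(coords, torque_limits$coord), ]
  pp <- passive[match(coords, passive$coord), ]
  if (anyNA(jl$q_min) || anyNA(tq$tau_plus_max) || anyNA(pp$a))
    stop("joint configuration tables must cover every joint coordinate")
  if (any(jl$q_min >= jl$q_max)) stop("q_min must be < q_max")
  if (any(tq$tau_plus_max <= 0) || any(tq$tau_minus_max >= 0))
    stop("tau_plus_max must be > 0 and tau_minus_max < 0")

  coord_table <- data.frame(
    coord = coords,
    q_min = jl$q_min, q_max = jl$q_max,
    tau_plus_max = tq$tau_plus_max, tau_minus_max = tq$tau_minus_max,
    a = pp$a, b = pp$b, c = pp$c,
    row.names = NULL, stringsAsFactors = FALSE)

  neutral_q <- stats::setNames(rep(0, length(coords)), coords)
  if (!is.null(neutral)) {
    bad <- setdiff(names(neutral), coords)
    if (length(bad)) stop("unknown neutral coordinates: ",
                          paste(bad, collapse = ", "))
    neutral_q[names(neutral)] <- neutral
  }

  cpp <- list(
    parent = vapply(tree, function(b) b$parent, 0L) - 1L,
    jtype = vapply(tree, function(b) b$jtype, 0L),
    axis = vapply(tree, function(b) b$axis, numeric(3)),
    offset = vapply(tree, function(b) b$offset, numeric(3)),
    mass = mass_v,
    com = com_m,
    inertia = inert,
    left_foot = segments$foot_l$body_index - 1L,
    right_foot = segments$foot_r$body_index - 1L,
    pelvis = segments$pelvis$body_index - 1L,
    cp_left = cp$points,
    cp_right = cp$points,
    gains = gains,
    ground = ground,
    passive = list(a = coord_table$a, b = coord_table$b, c = coord_table$c,
                   q_min = coord_table$q_min, q_max = coord_table$q_max),
    gravity = gravity
  )

  model <- list(
    height = height, weight = weight, total_mass = weight,
    segments = segments, coords = coord_table,
    coord_names = c(names(tree)[1:6], coords),
    contact_points = list(left = cp, right = cp),
    foot_geometry = fg, mountings = mountings,
    gains = gains, ground = ground, neutral = neutral_q,
    lengths = lengths, hip_half_spacing = hip_half,
    shoulder_half_spacing = sho_half,
    gravity = gravity, cpp = cpp)
  class(model) <- "body_model"
  stopifnot(abs(sum(vapply(model$segments, `[[`, 0, "mass")) - weight) <
              1e-9 * weight)
  model
}

#' Foot sole contact points
#'
#' Lays out the 22 contact points of one foot from its sole landmark
#' geometry: a 7 x 3 grid spanning heel to the second-phalanx tip, the grid
#' width interpolated between the heel, MTP and phalanx widths, all at the
#' sole depth below the ankle, plus one toe-tip point at the first-phalanx
#' height.  Foot frame: origin at the ankle, +Y anterior, +X lateral,
#' +Z up.
#'
#' @param geometry landmark distances, see [default_foot_geometry()].
#' @return List with `points` (3 x 22 matrix, metres, foot frame) and the
#'   generating `geometry`.
#' @export
foot_contact_points <- function(geometry = default_foot_geometry()) {
  g <- geometry
  vals <- unlist(g[c("d_heel", "d_mtp", "d_toe", "w_heel", "w_mtp",
                     "w_phal", "h_ankle", "h_phal")])
  if (any(vals < 0)) stop("foot geometry distances must be non-negative")
  if (g$d_toe <= g$d_mtp) stop("d_toe must exceed d_mtp")
  # six rows span heel to the MTP line (so the widest row sits exactly
  # at the MTP joint) and a seventh row crosses the toes
  ys <- c(seq(-g$d_heel, g$d_mtp, length.out = 6), g$d_toe)
  width_at <- function(y) {
    stats::approx(x = c(-g$d_heel, g$d_mtp, g$d_toe),
                  y = c(g$w_heel, g$w_mtp, g$w_phal),
                  xout = y, rule = 2)$y
  }
  pts <- do.call(cbind, lapply(ys, function(y) {
    w <- width_at(y)
    rbind(c(-w / 2, 0, w / 2), rep(y, 3), rep(-g$h_ankle, 3))
  }))
  pts <- cbind(pts, c(0, g$d_toe, -g$h_phal))   # toe tip pad
  stopifnot(ncol(pts) == 22)
  dimnames(pts) <- list(c("x", "y", "z"), NULL)
  list(points = pts, geometry = g)
}

#' Neutral model state
#'
#' Returns the model state (generalized coordinates and velocities) at the
#' configured neutral posture: joint angles at their neutral values (zero by
#' default), root orientation identity, and the pelvis raised so that both
#' soles rest on the ground plane.
#'
#' @param model a [build_model()] object.
#' @return A list of class `model_state` with `q` (27 named coordinates),
#'   `qd` (27 zeros) and `t = 0`.
#' @export
neutral_pose <- function(model) {
  stopifnot(inherits(model, "body_model"))
  n <- length(model$coord_names)
  q <- stats::setNames(rep(0, n), model$coord_names)
  q[names(model$neutral)] <- model$neutral
  q["root_tz"] <- model$foot_geometry$h_ankle +
    model$lengths[["shank"]] + model$lengths[["thigh"]]
  state <- list(q = q, qd = stats::setNames(rep(0, n), model$coord_names),
                t = 0)
  class(state) <- "model_state"
  state
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model>  12 segments, 21 joint DOFs + 6-DOF root = 27 coordinates\n")
  cat(sprintf("  height %.2f m, total mass %.1f kg\n", x$height, x$total_mass))
  cat(sprintf("  contact points per foot: %d\n",
              ncol(x$contact_points$left$points)))
  masses <- vapply(x$segments, `[[`, 0, "mass")
  cat("  segment masses (kg):\n")
  print(round(masses, 2))
  invisible(x)
}

#' Export a model summary as JSON
#'
#' Writes segment masses, lengths, inertias, the DOF list, and contact
#' points to a JSON file (or returns the JSON string) for inspection and as
#' a test fixture format.
#'
#' @param model a [build_model()] object.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
model_summary_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "body_model"))
  summary <- list(
    height = model$height, total_mass = model$total_mass,
    coordinates = model$coord_names,
    segments = lapply(model$segments, function(s)
      list(mass = s$mass, length = s$length, com_offset = s$com_offset,
           inertia = s$inertia)),
    contact_points = list(left = model$contact_points$left$points,
                          right = model$contact_points$right$points),
    joint_table = model$coords)
  js <- jsonlite::toJSON(summary, digits = NA, auto_unbox = TRUE,
                         matrix = "columnmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# internal: named 27-vector in canonical order from a model_state or vector
state_vec <- function(model, x) {
  if (inherits(x, "model_state")) x <- x$q
  if (is.null(names(x))) {
    stopifnot(length(x) == length(model$coord_names))
    return(as.numeric(x))
  }
  as.numeric(x[model$coord_names])
}
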