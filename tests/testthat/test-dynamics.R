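test_that("active PD torque follows the gain law", {
  g <- default_gains()
  q <- rep(0.2, 21); qd <- rep(-0.1, 21)
  expect_equal(active_torque(q, qd, q, qd, g), rep(0, 21))
  q_r <- q; q_r[5] <- q[5] + 0.1
  expect_equal(active_torque(q_r, qd, q, qd, g)[5], 100)
  qd_r <- qd; qd_r[7] <- qd[7] + 1
  expect_equal(active_torque(q, qd_r, q, qd, g)[7], 10)
  expect_error(active_torque(q[1:5], qd, q, qd, g), "equal length")
})

test_that("passive torque is dormant mid-range and restoring past limits", {
  spec <- data.frame(a = 2, b = 20, c = 0.1, q_min = -1, q_max = 1)
  expect_lt(abs(passive_torque(0, 0, spec)), 0.1)
  t1 <- passive_torque(1.1, 0, spec)
  t0 <- passive_torque(1.0, 0, spec)
  expect_lt(t1, 0)              # restoring beyond q_max
  expect_gt(abs(t1), abs(t0))   # monotone in violation depth
  expect_gt(passive_torque(-1.1, 0, spec), 0)
  # matches the configured double exponential pointwise
  qs <- seq(-1.2, 1.2, by = 0.2)
  expect_equal(passive_torque(qs, 0.3, spec),
               -2 * exp(20 * (qs - 1)) + 2 * exp(20 * (-1 - qs)) -
                 0.1 * 0.3)
  # sign test over a grid: zero-ish inside, restoring outside
  grid <- seq(-1.5, 1.5, by = 0.05)
  tp <- passive_torque(grid, 0, spec)
  expect_true(all(abs(tp[abs(grid) < 0.7]) < 0.1))
  expect_true(all(tp[grid > 1.05] < 0))
  expect_true(all(tp[grid < -1.05] > 0))
})

test_that("contact force spot checks match the viscoelastic law", {
  gr <- default_ground()   # K_G = 1e3, D_G = 1e4
  above <- contact_forces(matrix(c(0, 0, 0.01)), matrix(0, 3, 1), gr)
  expect_equal(above$Fv, 0)
  still <- contact_forces(matrix(c(0, 0, -0.01)), matrix(0, 3, 1), gr)
  expect_equal(still$Fv, 10, tolerance = 1e-9)
  moving <- contact_forces(matrix(c(0, 0, -0.01)),
                           matrix(c(0, 0, -0.5)), gr)
  expect_equal(moving$Fv, 5010, tolerance = 1e-9)
})

test_that("friction respects the cone on randomized states", {
  gr <- default_ground()
  set.seed(42)
  for (i in 1:50) {
    p <- matrix(rnorm(3 * 10, sd = 0.02), 3)
    v <- matrix(rnorm(3 * 10, sd = 0.5), 3)
    cf <- contact_forces(p, v, gr)
    expect_true(all(cf$Fv >= 0))
    fh <- sqrt(colSums(cf$Fh^2))
    expect_true(all(fh <= gr$mu_s * cf$Fv + 1e-9))
    # horizontal force opposes sliding velocity
    act <- cf$Fv > 0 & sqrt(colSums(v[1:2, , drop = FALSE]^2)) > 1e-6
    if (any(act))
      expect_true(all(colSums(cf$Fh[, act, drop = FALSE] *
                                v[1:2, act, drop = FALSE]) <= 1e-9))
  }
})

test_that("virtual torque acts on sagittal and frontal rotations only", {
  g <- default_gains()
  expect_equal(virtual_torque(c(0, 0, 0), c(0, 0, 0), g), c(0, 0, 0))
  expect_equal(virtual_torque(c(0, 0, 0.5), c(0, 0, 1), g)[3], 0)
  expect_equal(virtual_torque(c(0.1, 0, 0), c(0, 0, 0),
                              list(K_virtual = c(400, 400, 0),
                                   D_virtual = c(40, 40, 0)))[1], -40)
})

test_that("free fall produces pure root acceleration", {
  m <- ref_model()
  st <- neutral_pose(m)
  q <- grfimu:::state_vec(m, st)
  q[3] <- q[3] + 1   # airborne
  qdd <- assemble_and_solve(m, stats::setNames(q, m$coord_names),
                            tau = rep(0, 21))
  expect_equal(unname(qdd[1:6]), c(0, 0, -9.81, 0, 0, 0), tolerance = 1e-10)
  expect_true(all(abs(qdd[7:27]) < 1e-10))
})

test_that("articulated-body solution equals M^-1 (tau - Gamma)", {
  m <- ref_model()
  st <- neutral_pose(m)
  set.seed(7)
  for (i in 1:5) {
    q <- grfimu:::state_vec(m, st) + rnorm(27, 0, 0.1)
    qd <- rnorm(27, 0, 0.5)
    tau <- c(rep(0, 6), rnorm(21, 0, 20))
    qdd1 <- grfimu:::cpp_qdd(m$cpp, q, qd, tau, TRUE, TRUE)
    eo <- grfimu:::cpp_eom(m$cpp, q, qd, TRUE)
    qdd2 <- solve(eo$M, tau - eo$Gamma)
    expect_equal(max(abs(qdd1 - qdd2)), 0, tolerance = 1e-8)
    # inertia matrix symmetric positive definite
    expect_equal(eo$M, t(eo$M), tolerance = 1e-10)
    expect_gt(min(eigen(eo$M, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("fast derivative path matches the reference algorithms", {
  m <- ref_model()
  ref <- grfimu:::constant_reference(m, 1)
  rl <- lapply(ref$dofs, function(d) list(times = d$times,
                                          values = d$values))
  st <- neutral_pose(m)
  set.seed(12)
  for (i in 1:5) {
    y <- c(grfimu:::state_vec(m, st) + rnorm(27, 0, 0.15), rnorm(27, 0, 1))
    dy <- grfimu:::cpp_deriv_bench(m$cpp, rl, y, 0.4, 1)
    rv <- spline_reference(ref, 0.4)
    tau <- active_torque(rv$q_r[, 1], rv$qd_r[, 1], y[7:27], y[34:54],
                         m$gains) +
      passive_torque(y[7:27], y[34:54], m$coords)
    qdd <- grfimu:::cpp_qdd(m$cpp, y[1:27], y[28:54], c(rep(0, 6), tau),
                            TRUE, TRUE)
    expect_equal(dy[28:54], as.numeric(qdd), tolerance = 1e-9)
  }
})

test_that("locked-chain hinge matches the compound pendulum closed form", {
  m <- ref_model()
  st <- neutral_pose(m)
  q <- grfimu:::state_vec(m, st)
  q[3] <- q[3] + 2                 # airborne, no contact
  ang <- 0.4
  iknee <- which(m$coord_names == "knee_l")
  q[iknee] <- ang
  eo <- grfimu:::cpp_eom(m$cpp, q, rep(0, 27), include_external = FALSE)
  # locked chain: all other coordinates held, only the knee accelerates
  qdd_hinge <- -eo$Gamma[iknee] / eo$M[iknee, iknee]
  # closed-form compound pendulum: shank + foot about the knee axis.
  # gravity moment about the hinge; inertia by the parallel-axis theorem
  sh <- m$segments$shank_l; ft <- m$segments$foot_l
  Ls <- m$lengths[["shank"]]
  d_sh <- abs(sh$com_offset[3])
  # foot COM position relative to the knee, in the shank frame
  ft_com_rel <- c(0, ft$com_offset[2], -Ls + ft$com_offset[3])
  d_ft2 <- sum(ft_com_rel[2:3]^2)
  I_hinge <- sh$inertia[1, 1] + sh$mass * d_sh^2 +
    ft$inertia[1, 1] + ft$mass * d_ft2
  # gravity torque about X at knee flexion `ang` (rotation about +X moves
  # the distal segment; moment arm = horizontal (y) offset of the COMs)
  R <- grfimu:::matrix_from_euler_xyz(c(ang, 0, 0))
  com_sh <- R %*% sh$com_offset
  com_ft <- R %*% ft_com_rel
  tau_g <- -9.81 * (sh$mass * com_sh[2] + ft$mass * com_ft[2])
  qdd_closed <- tau_g / I_hinge
  expect_equal(qdd_hinge, unname(qdd_closed), tolerance = 1e-4 *
                 max(1, abs(qdd_closed)))
})

test_that("standing simulation settles to body weight and obeys Newton", {
  m <- ref_model()
  ref <- grfimu:::constant_reference(m, 2)
  sim <- simulate_motion(m, ref, c(0, 2), method = "trbdf2",
                         out_hz = 200)
  bw <- m$total_mass * m$gravity
  expect_equal(unname(sim$grf["z", ncol(sim$grf)]), bw,
               tolerance = 1e-3 * bw)
  ck <- grfimu:::com_kinematics(m, sim)
  res <- m$total_mass * ck$acc - (sim$grf + c(0, 0, -bw))
  expect_lt(max(abs(res)), 1)
})

test_that("integration is deterministic and both integrators agree", {
  m <- ref_model()
  ref <- grfimu:::constant_reference(m, 0.25)
  s1 <- simulate_motion(m, ref, c(0, 0.25), method = "trbdf2", out_hz = 200)
  s2 <- simulate_motion(m, ref, c(0, 0.25), method = "trbdf2", out_hz = 200)
  expect_identical(s1$q, s2$q)       # bit-identical repeat
  s3 <- simulate_motion(m, ref, c(0, 0.25), method = "rk45", out_hz = 200)
  expect_equal(s1$grf["z", ], s3$grf["z", ], tolerance = 5e-3 * 621)
})

test_that("airborne whole-body angular momentum is conserved", {
  gains <- default_gains()
  gains$K_virtual <- c(0, 0, 0); gains$D_virtual <- c(0, 0, 0)
  m <- build_model(1.69, 63.3, gains = gains)
  st <- neutral_pose(m)
  st$q["root_tz"] <- st$q["root_tz"] + 1.5
  st$qd["root_rz"] <- 2; st$qd["root_rx"] <- 0.5
  st$qd["knee_l"] <- 1
  sim <- simulate_motion(m, NULL, c(0, 0.3), state0 = st,
                         method = "rk45", out_hz = 100)
  expect_true(all(sim$grf == 0))
  # angular momentum about the COM from segment kinematics
  Lmom <- function(s) {
    com <- c(0, 0, 0); vel <- c(0, 0, 0)
    parts <- list()
    for (nm in names(m$segments)) {
      sg <- m$segments[[nm]]
      pk <- grfimu:::point_kinematics(m, sim, nm, sg$com_offset)
      parts[[nm]] <- pk
      com <- com + sg$mass * pk$pos[, s]
      vel <- vel + sg$mass * pk$vel[, s]
    }
    com <- com / m$total_mass; vel <- vel / m$total_mass
    L <- c(0, 0, 0)
    for (nm in names(m$segments)) {
      sg <- m$segments[[nm]]
      pk <- parts[[nm]]
      r <- pk$pos[, s] - com
      v <- pk$vel[, s] - vel
      Rb <- pk$R[, , s]
      L <- L + sg$mass * grfimu:::cross3(r, v) +
        Rb %*% (sg$inertia %*% pk$omega_body[, s])
    }
    L
  }
  L1 <- Lmom(1); L2 <- Lmom(31)
  expect_equal(as.numeric(L2), as.numeric(L1),
               tolerance = 1e-4 * max(1, max(abs(L1))))
})

test_that("ground reaction moment matches a direct cross-product sum", {
  m <- ref_model()
  ref <- grfimu:::constant_reference(m, 0.2)
  sim <- simulate_motion(m, ref, c(0, 0.2), method = "trbdf2", out_hz = 50)
  grm <- grm_about_ankle(sim, m, "left")
  s <- ncol(sim$q)
  ct <- grfimu:::cpp_contact(m$cpp, sim$q[, s], sim$qd[, s])
  fk <- grfimu:::cpp_fk(m$cpp, sim$q[, s])
  bi <- m$segments$foot_l$body_index
  origin <- c(fk$p[1:2, bi], 0)
  mom <- c(0, 0, 0)
  for (k in seq_len(ncol(ct$F_left)))
    mom <- mom + grfimu:::cross3(ct$pos_left[, k] - origin, ct$F_left[, k])
  # foot heading is neutral here, so the foot-aligned frame coincides
  # with the world frame
  expect_equal(grm[, s], mom, tolerance = 1e-8, ignore_attr = TRUE)
})
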