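ref_to_genes_test <- function(traj)
  unlist(lapply(traj$dofs, `[[`, "values"), use.names = FALSE)

test_that("scenario references are reproducible and calibration is static", {
  m <- ref_model()
  calib <- synth_motion(m, "calibration-pose", duration = 1)
  expect_true(all(vapply(calib$dofs, function(d)
    all(d$values == d$values[1]) && all(d$values == 0), TRUE)))
  a <- synth_motion(m, "single-leg-hop", seed = 4)
  b <- synth_motion(m, "single-leg-hop", seed = 4)
  expect_identical(ref_to_genes_test(a), ref_to_genes_test(b))
  c <- synth_motion(m, "single-leg-hop", seed = 5)
  expect_false(identical(ref_to_genes_test(a), ref_to_genes_test(c)))
})

test_that("squat jump shows an unloading dip then a propulsion peak", {
  fx <- cached("squat", function()
    make_fixture("squat-jump", noise = noise_model(0, 0, 0)))
  z <- fx$truth$grf["z", ]
  bw <- fx$weight * 9.81
  # quiet opening phase near body weight (before the countermovement)
  expect_lt(max(abs(z[50:150] - bw)), 0.2 * bw)
  dip <- min(z[300:1100])
  peak <- max(z[seq(which.min(z[300:1100]) + 299, 1400)])
  expect_lt(dip, 0.85 * bw)
  expect_gt(peak, 1.1 * bw)
})

test_that("synthetic accelerometers read gravity when standing still", {
  fx <- calib_fixture()
  tr <- fx$trial_clean
  for (nm in names(tr$sensors)) {
    amag <- sqrt(colSums(tr$sensors[[nm]]$acc[, 800:1000]^2))
    expect_equal(mean(amag), 9.81, tolerance = 0.02)
    expect_lt(max(abs(tr$sensors[[nm]]$gyr[, 800:1000])), 0.02)
  }
})

test_that("sensor model matches the closed-form rotating-frame oracle", {
  # airborne model with only the left knee rotating at a constant rate:
  # the shank sensor must read the centripetal acceleration about the
  # knee plus the gravity projection
  m <- ref_model()
  st <- neutral_pose(m)
  w0 <- 3                        # rad/s about the knee X axis
  T <- 21
  tgrid <- seq(0, 0.2, length.out = T)
  ik <- which(m$coord_names == "knee_l")
  Q <- matrix(grfimu:::state_vec(m, st), 27, T)
  Q[3, ] <- Q[3, ] + 2           # airborne (irrelevant to kinematics)
  Q[ik, ] <- -0.3 + w0 * tgrid
  Qd <- matrix(0, 27, T); Qd[ik, ] <- w0
  Qdd <- matrix(0, 27, T)
  sim <- list(time = tgrid, q = Q, qd = Qd, qdd = Qdd, out_hz = 100)
  rownames(sim$q) <- rownames(sim$qd) <- rownames(sim$qdd) <-
    m$coord_names
  trial <- imu_from_sim(sim, m, m$mountings["shank_l"])
  ls <- m$mountings$shank_l$lever_arm
  g <- c(0, 0, -9.81)
  for (k in c(1, 10, 20)) {
    th <- -0.3 + w0 * tgrid[k]
    R <- grfimu:::matrix_from_euler_xyz(c(th, 0, 0))   # shank -> world
    a_expected <- grfimu:::cross3(c(w0, 0, 0),
                                  grfimu:::cross3(c(w0, 0, 0), ls)) -
      drop(t(R) %*% g)
    expect_equal(trial$sensors$shank_l$acc[, k], a_expected,
                 tolerance = 1e-10)
    expect_equal(trial$sensors$shank_l$gyr[, k], c(w0, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("feeding noise-free signals back recovers orientations", {
  fx <- calib_fixture()
  pp <- ekf_params(dt = 1 / fx$trial$rate, P0 = diag(1e-4, 8))
  f <- run_pair_ekf(fx$trial_clean, c("pelvis", "thigh_l"), pp,
                    init = list(q_s = fx$init_quat$pelvis,
                                q_s1 = fx$init_quat$thigh_l),
                    lever_arms = grfimu:::pair_lever_arms(
                      fx$model, "pelvis", "thigh_l"))
  T <- length(fx$trial$time)
  ks <- seq(50, T, 50)
  err <- rel_err_deg(f$q_s, f$q_s1,
                     fx$truth$orientations$pelvis,
                     fx$truth$orientations$thigh_l, ks)
  expect_lt(max(err), 0.1)
})

test_that("sensor noise is reproducible and has the configured variance", {
  fx <- calib_fixture()
  nm <- noise_model(accel_sd = 0.05, gyro_sd = 0.005, bias_walk_sd = 1e-4,
                    seed = 31)
  n1 <- add_noise(fx$trial_clean, nm)
  n2 <- add_noise(fx$trial_clean, nm)
  expect_identical(n1$sensors, n2$sensors)
  # zero noise is the identity
  n0 <- add_noise(fx$trial_clean, noise_model(0, 0, 0))
  expect_identical(n0$sensors, fx$trial_clean$sensors)
  # sample variance of the added accelerometer noise within 5 %
  big <- imu_trial(seq(0, by = 1e-3, length.out = 40000),
                   list(s = list(acc = matrix(0, 3, 40000),
                                 gyr = matrix(0, 3, 40000))),
                   list(s = list(segment = "s", lever_arm = c(0, 0, 0),
                                 mount_rotation = c(1, 0, 0, 0))))
  nb <- add_noise(big, noise_model(accel_sd = 0.05, gyro_sd = 0,
                                   bias_walk_sd = 0, seed = 9))
  expect_equal(stats::var(as.numeric(nb$sensors$s$acc)), 0.05^2,
               tolerance = 0.05)
})

test_that("fixtures round-trip through the CSV readers", {
  dir <- tempfile("fix")
  fx <- make_fixture("calibration-pose", duration = 0.5,
                     noise = noise_model(seed = 3), dir = dir)
  expect_true(file.exists(file.path(dir, "trial.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "meta.yaml")))
  back <- read_imu_trial(file.path(dir, "trial.csv"),
                         fx$trial$mountings)
  expect_equal(back$sensors$pelvis$acc, fx$trial$sensors$pelvis$acc,
               tolerance = 1e-9)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  expect_equal(meta$scenario, "calibration-pose")
  unlink(dir, recursive = TRUE)
})

test_that("fixture truth satisfies the whole-body Newton check", {
  fx <- hop_fixture()
  m <- fx$model
  ck <- grfimu:::com_kinematics(m, fx$truth)
  bw <- m$total_mass * m$gravity
  res <- m$total_mass * ck$acc - (fx$truth$grf + c(0, 0, -bw))
  expect_lt(max(abs(res)), 1)
})

test_that("calibration fixture passes the static calibration check", {
  fx <- calib_fixture()
  ic <- init_from_calibration(window_trial(fx$trial_clean, 0.4, 1.0),
                              fx$model)
  expect_lt(max(abs(unlist(ic$tilt))), 0.05)
  expect_lt(max(abs(ic$neutral)), 0.05)
})
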