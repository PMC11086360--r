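test_that("angular-rate matrix has the quaternion-kinematics structure", {
  expect_equal(omega_matrix(c(0, 0, 0)), matrix(0, 4, 4))
  set.seed(3)
  for (i in 1:5) {
    w <- rnorm(3)
    Om <- omega_matrix(w)
    expect_equal(Om, -t(Om))   # antisymmetric
    # Omega q equals the quaternion-product derivative rule q (x) (0, w)
    q <- grfimu:::quat_normalize(rnorm(4))
    expect_equal(as.numeric(Om %*% q), qmul(q, c(0, w)), tolerance = 1e-12)
  }
})

test_that("prediction integrates gyro rates and renormalizes", {
  pp <- ekf_params(dt = 1e-3)
  st <- ekf_state(params = pp)
  st2 <- ekf_predict(st, c(0, 0, 0), c(0, 0, 0), pp)
  expect_equal(st2$x, st$x)
  expect_true(all(diag(st2$P) > diag(st$P)))   # process noise inflation
  # constant yaw rate pi rad/s for 0.5 s -> yaw pi/2
  st <- ekf_state(params = pp)
  for (k in 1:500) st <- ekf_predict(st, c(0, 0, pi), c(0, 0, 0), pp)
  target <- grfimu:::quat_from_euler_xyz(c(0, 0, pi / 2))
  expect_lt(grfimu:::quat_angle(st$x[1:4], target), 1e-3)
  expect_equal(sum(st$x[1:4]^2), 1, tolerance = 1e-14)
  expect_equal(sum(st$x[5:8]^2), 1, tolerance = 1e-14)
})

test_that("centripetal + tangential compensation is exact vector algebra", {
  expect_equal(centripetal_tangential(c(0, 0, 0), c(0, 0, 0), c(1, 2, 3)),
               c(0, 0, 0))
  expect_equal(centripetal_tangential(c(0, 0, 10), c(0, 0, 0),
                                      c(0.1, 0, 0)), c(-10, 0, 0))
  expect_equal(centripetal_tangential(c(0, 0, 0), c(0, 0, 5),
                                      c(0.1, 0, 0)), c(0, 0.5, 0))
})

test_that("observation Jacobian matches finite differences", {
  set.seed(4)
  for (i in 1:5) {
    x <- c(grfimu:::quat_normalize(rnorm(4)),
           grfimu:::quat_normalize(rnorm(4)))
    bA <- rnorm(3); bB <- rnorm(3)
    H <- grfimu:::ekf_H(x, bA, bB)
    # homogeneous-form finite differences
    Hfd <- sapply(1:8, function(j) {
      dx <- rep(0, 8); dx[j] <- 1e-7
      h1 <- grfimu:::ekf_h_hom(x + dx, bA, bB)
      h0 <- grfimu:::ekf_h_hom(x, bA, bB)
      (h1 - h0) / 1e-7
    })
    expect_equal(H, Hfd, tolerance = 1e-5)
  }
})

test_that("static update is consistent and contracts errors", {
  pp <- ekf_params(dt = 1e-3)
  a <- c(0, 0, 9.81); zero <- c(0, 0, 0)
  st <- ekf_state(params = pp)
  st2 <- ekf_update(st, a, a, zero, zero, pp)
  expect_lt(grfimu:::quat_angle(st2$x[1:4], c(1, 0, 0, 0)), 1e-10)
  # 5 degree hinge perturbation shrinks after one update
  q0 <- grfimu:::quat_from_euler_xyz(c(5 * pi / 180, 0, 0))
  aB <- drop(t(grfimu:::matrix_from_quat(q0)) %*% a) * 0 + a  # truth: identity
  stp <- ekf_state(c(1, 0, 0, 0), q0, pp)
  before <- grfimu:::quat_angle(stp$x[5:8], c(1, 0, 0, 0))
  stu <- ekf_update(stp, a, a, zero, zero, pp)
  after <- grfimu:::quat_angle(stu$x[5:8], c(1, 0, 0, 0))
  expect_lt(after, before)
  # covariance stays symmetric positive semidefinite
  expect_equal(stu$P, t(stu$P))
  expect_true(min(eigen(stu$P, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-12)
})

test_that("pairwise observation is blind to a common heading offset", {
  set.seed(9)
  qA <- grfimu:::quat_normalize(rnorm(4))
  qB <- grfimu:::quat_normalize(rnorm(4))
  bA <- rnorm(3); bB <- rnorm(3)
  h1 <- grfimu:::ekf_h(c(qA, qB), bA, bB)
  yaw <- grfimu:::quat_from_euler_xyz(c(0, 0, 0.7))
  h2 <- grfimu:::ekf_h(c(qmul(yaw, qA), qmul(yaw, qB)), bA, bB)
  expect_equal(h1, h2, tolerance = 1e-12)
  # and indeed to any common rotation
  rot <- grfimu:::quat_normalize(rnorm(4))
  h3 <- grfimu:::ekf_h(c(qmul(rot, qA), qmul(rot, qB)), bA, bB)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("paired filter tracks a synthetic hinge oscillation", {
  # noise-free, exact initialization: inverse-crime limit
  hz0 <- make_hinge_trial(duration = 4)
  pp <- ekf_params(dt = 1e-3, P0 = diag(1e-3, 8))
  f0 <- run_pair_ekf(hz0$trial, c("A", "B"), pp,
                     init = list(q_s = c(1, 0, 0, 0),
                                 q_s1 = hz0$quatB[, 1]))
  ks <- seq(1, ncol(hz0$quatB), 40)
  err0 <- rel_err_deg(f0$q_s, f0$q_s1, hz0$quatA, hz0$quatB, ks)
  expect_lt(max(err0), 0.1)
  # sensor noise at the documented scales: relative flexion within 2
  # degrees RMS over 10 s; the full 3D relative angle carries an extra
  # weakly observable component about gravity and stays under 5 degrees
  hz <- make_hinge_trial(duration = 10, noise = noise_model(seed = 2))
  f <- run_pair_ekf(hz$trial, c("A", "B"), pp,
                    init = list(q_s = c(1, 0, 0, 0),
                                q_s1 = hz$quatB[, 1]))
  ks <- seq(1, ncol(hz$quatB), 50)
  flex <- vapply(ks, function(k) {
    rel <- qmul(qconj(f$q_s[, k]), f$q_s1[, k])
    grfimu:::euler_xyz_from_quat(rel)[1] * 180 / pi - hz$theta[k] * 180 / pi
  }, 0)
  expect_lt(sqrt(mean(flex^2)), 2)
  err <- rel_err_deg(f$q_s, f$q_s1, hz$quatA, hz$quatB, ks)
  expect_lt(sqrt(mean(err^2)), 5)
})

test_that("static trial with noise keeps the observable error small", {
  t <- seq(0, 10, by = 1e-3); T <- length(t)
  sensors <- list(
    A = list(acc = matrix(c(0, 0, 9.81), 3, T), gyr = matrix(0, 3, T)),
    B = list(acc = matrix(c(0, 0, 9.81), 3, T), gyr = matrix(0, 3, T)))
  mnt <- list(A = list(segment = "A", lever_arm = c(0, 0, 0),
                       mount_rotation = c(1, 0, 0, 0)),
              B = list(segment = "B", lever_arm = c(0, 0, -0.2),
                       mount_rotation = c(1, 0, 0, 0)))
  trial <- add_noise(imu_trial(t, sensors, mnt), noise_model(seed = 5))
  pp <- ekf_params(dt = 1e-3, P0 = diag(1e-3, 8))
  f <- run_pair_ekf(trial, c("A", "B"), pp)
  ks <- seq(1, T, 100)
  # in a gravity-aligned static posture the relative rotation about the
  # gravity axis is unobservable and drifts with the integrated gyro
  # noise; the observable tilt component must stay well under a degree
  comp <- vapply(ks, function(k) {
    rel <- qmul(qconj(f$q_s[, k]), f$q_s1[, k])
    e <- grfimu:::euler_xyz_from_quat(rel) * 180 / pi
    c(sqrt(e[1]^2 + e[2]^2), abs(e[3]))
  }, numeric(2))
  expect_lt(sqrt(mean(comp[1, ]^2)), 1)    # tilt
  expect_lt(sqrt(mean(comp[2, ]^2)), 5)    # gravity-axis drift bound
})

test_that("error decreases monotonically as observation noise shrinks", {
  errs <- vapply(c(0.2, 0.05, 0.01), function(sd) {
    hz <- make_hinge_trial(duration = 5,
                           noise = noise_model(accel_sd = sd,
                                               gyro_sd = sd / 10,
                                               bias_walk_sd = 0, seed = 3))
    pp <- ekf_params(dt = 1e-3, P0 = diag(1e-3, 8))
    f <- run_pair_ekf(hz$trial, c("A", "B"), pp,
                      init = list(q_s = c(1, 0, 0, 0),
                                  q_s1 = hz$quatB[, 1]))
    ks <- seq(1, ncol(hz$quatB), 50)
    sqrt(mean(rel_err_deg(f$q_s, f$q_s1, hz$quatA, hz$quatB, ks)^2))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("whole-body chain recovers segment orientations", {
  fx <- cached("squat", function()
    make_fixture("squat-jump", noise = noise_model(0, 0, 0)))
  m <- fx$model
  pp <- ekf_params(dt = 1 / fx$trial$rate, P0 = diag(1e-3, 8))
  est <- chain_orientations(window_trial(fx$trial_clean, 0, 3), m, pp,
                            init = fx$init_quat)
  T <- length(est$time)
  errs <- vapply(names(est$quat), function(s) {
    ks <- seq(1, T, 40)
    sqrt(mean(vapply(ks, function(k)
      qangle_deg(est$quat[[s]][, k], fx$truth$orientations[[s]][, k]),
      0)^2))
  }, 0)
  expect_lt(max(errs), 5)
  # composing pelvis->thigh->shank equals the direct pelvis->shank
  # relative rotation to within filter tolerance
  k <- T %/% 2
  rel_chain <- qmul(qconj(est$quat$pelvis[, k]), est$quat$shank_l[, k])
  rel_direct <- qmul(qconj(fx$truth$orientations$pelvis[, k]),
                     fx$truth$orientations$shank_l[, k])
  expect_lt(qangle_deg(rel_chain, rel_direct), 5)
})

test_that("chain requires a connected sensor graph with a pelvis root", {
  fx <- calib_fixture()
  tr <- fx$trial_clean
  tr$sensors$pelvis <- NULL
  expect_error(chain_orientations(tr, fx$model), "pelvis")
  tr2 <- fx$trial_clean
  tr2$sensors$thigh_l <- NULL   # orphans the shank/foot
  expect_error(chain_orientations(tr2, fx$model), "disconnected")
})

test_that("calibration initialization recovers roll and pitch", {
  mk_static <- function(acc, T = 2000, gyro_sd = 0, acc_sd = 0, seed = 1) {
    set.seed(seed)
    t <- seq(0, by = 1e-3, length.out = T)
    a <- matrix(acc, 3, T) + matrix(rnorm(3 * T, 0, acc_sd), 3, T)
    g <- matrix(rnorm(3 * T, 0, gyro_sd), 3, T)
    imu_trial(t, list(pelvis = list(acc = a, gyr = g)),
              list(pelvis = list(segment = "pelvis",
                                 lever_arm = c(0, 0, 0),
                                 mount_rotation = c(1, 0, 0, 0))))
  }
  m <- ref_model()
  flat <- init_from_calibration(mk_static(c(0, 0, 9.81)), m)
  expect_lt(qangle_deg(flat$quat$pelvis, c(1, 0, 0, 0)), 1e-6)
  # 30 degree roll about X
  R <- grfimu:::matrix_from_euler_xyz(c(30 * pi / 180, 0, 0))
  tilted <- init_from_calibration(mk_static(t(R) %*% c(0, 0, 9.81)), m)
  expect_equal(unname(tilted$tilt$pelvis["roll"]), 30 * pi / 180,
               tolerance = 1e-6)
  # noisy averaging over 2 s still recovers tilt within 0.5 degrees
  noisy <- init_from_calibration(
    mk_static(t(R) %*% c(0, 0, 9.81), acc_sd = 0.1, seed = 8), m)
  expect_lt(abs(noisy$tilt$pelvis["roll"] - 30 * pi / 180), 0.5 * pi / 180)
  # non-static window is rejected
  expect_error(init_from_calibration(mk_static(c(0, 0, 9.81),
                                               gyro_sd = 1), m),
               "not static")
})

test_that("covariance stays symmetric PSD through a filtering run", {
  hz <- make_hinge_trial(duration = 0.5, noise = noise_model(seed = 4))
  pp <- ekf_params(dt = 1e-3)
  sA <- hz$trial$sensors$A; sB <- hz$trial$sensors$B
  st <- ekf_state(params = pp)
  for (k in seq(1, 500, 25)) {
    st <- ekf_predict(st, sA$gyr[, k], sB$gyr[, k], pp)
    st <- ekf_update(st, sA$acc[, k], sB$acc[, k], c(0, 0, 0), c(0, 0, 0),
                     pp)
    expect_equal(st$P, t(st$P))
    expect_gt(min(eigen(st$P, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
})
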