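# shared lazily-built fixtures, cached across test files
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .cache)) assign(name, builder(), .cache)
  get(name, .cache)
}

ref_model <- function() cached("model", function() build_model(1.69, 63.3))

calib_fixture <- function() cached("calib", function()
  make_fixture("calibration-pose", duration = 1.0,
               noise = noise_model(0, 0, 0)))

hop_fixture <- function() cached("hop", function()
  make_fixture("single-leg-hop", noise = noise_model(0, 0, 0)))

# quaternion helpers for assertions
qmul <- function(p, q) grfimu:::quat_mult(p, q)
qconj <- function(q) grfimu:::quat_conj(q)
qangle_deg <- function(p, q) grfimu:::quat_angle(p, q) * 180 / pi

# relative-orientation error (deg) between estimated and true quaternion
# series at sampled indices
rel_err_deg <- function(qA, qB, tA, tB, ks) {
  vapply(ks, function(k) {
    rt <- qmul(qconj(tA[, k]), tB[, k])
    re <- qmul(qconj(qA[, k]), qB[, k])
    qangle_deg(rt, re)
  }, 0)
}

# analytic two-link hinge trial: sensor A on a fixed link (reads pure
# gravity), sensor B on a link rotating about the world X axis by
# theta(t) = amp * sin(2 pi f t), mounted at lever ls from the hinge.
make_hinge_trial <- function(duration = 10, rate = 1000, amp = pi / 4,
                             freq = 0.5, ls = c(0, 0, -0.2),
                             noise = NULL) {
  t <- seq(0, duration, by = 1 / rate)
  T <- length(t)
  th <- amp * sin(2 * pi * freq * t)
  w <- amp * 2 * pi * freq * cos(2 * pi * freq * t)
  wd <- -amp * (2 * pi * freq)^2 * sin(2 * pi * freq * t)
  g <- c(0, 0, -9.81)
  accB <- matrix(0, 3, T); gyrB <- matrix(0, 3, T)
  quatB <- matrix(0, 4, T)
  for (k in seq_len(T)) {
    R <- grfimu:::matrix_from_euler_xyz(c(th[k], 0, 0))  # link -> world
    quatB[, k] <- grfimu:::quat_from_matrix(R)
    wv <- c(w[k], 0, 0); wdv <- c(wd[k], 0, 0)
    a_ct <- grfimu:::cross3(wv, grfimu:::cross3(wv, ls)) +
      grfimu:::cross3(wdv, ls)
    accB[, k] <- drop(t(R) %*% (-g)) + a_ct   # specific force + rotation
    gyrB[, k] <- wv
  }
  sensors <- list(
    A = list(acc = matrix(c(0, 0, 9.81), 3, T), gyr = matrix(0, 3, T)),
    B = list(acc = accB, gyr = gyrB))
  mountings <- list(
    A = list(segment = "A", lever_arm = c(0, 0, 0),
             mount_rotation = c(1, 0, 0, 0)),
    B = list(segment = "B", lever_arm = ls,
             mount_rotation = c(1, 0, 0, 0)))
  trial <- imu_trial(t, sensors, mountings)
  if (!is.null(noise)) trial <- add_noise(trial, noise)
  list(trial = trial, theta = th, quatB = quatB,
       quatA = matrix(c(1, 0, 0, 0), 4, T))
}
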