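test_that("assembled model has the documented structure", {
  m <- ref_model()
  expect_s3_class(m, "body_model")
  expect_length(m$segments, 12)
  expect_equal(nrow(m$coords), 21)
  expect_length(m$coord_names, 27)
  expect_equal(ncol(m$contact_points$left$points), 22)
  expect_equal(ncol(m$contact_points$right$points), 22)
  expect_equal(m$total_mass, 63.3)
  # mass conservation to round-off
  masses <- vapply(m$segments, `[[`, 0, "mass")
  expect_equal(sum(masses), 63.3, tolerance = 1e-12)
})

test_that("segment masses scale linearly with body weight", {
  m1 <- build_model(1.75, 60)
  m2 <- build_model(1.75, 120)
  for (nm in names(m1$segments))
    expect_equal(m2$segments[[nm]]$mass, 2 * m1$segments[[nm]]$mass)
})

test_that("thigh inertia matches hand evaluation of the scaling rule", {
  tab <- default_anthropometry()$segments
  row <- tab[tab$segment == "thigh", ]
  h <- 1.8; wgt <- 70
  m <- build_model(h, wgt, anthropometry = default_anthropometry())
  # hand evaluation: mass = w * frac / sum(frac * laterality),
  # I_t = m (k_t * L)^2, L = length_frac * h
  mult <- ifelse(tab$segment %in% c("upper_arm", "forearm", "thigh",
                                    "shank", "foot"), 2, 1)
  mfrac <- row$mass_frac / sum(tab$mass_frac * mult)
  mass <- wgt * mfrac
  L <- row$length_frac * h
  I_t <- mass * (row$k_t * L)^2
  I_l <- mass * (row$k_l * L)^2
  expect_equal(m$segments$thigh_l$mass, mass, tolerance = 1e-12)
  expect_equal(diag(m$segments$thigh_l$inertia), c(I_t, I_t, I_l),
               tolerance = 1e-12)
  # inertia symmetric positive definite
  I <- m$segments$thigh_l$inertia
  expect_equal(I, t(I))
  expect_true(all(eigen(I, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("out-of-range inputs and incomplete tables are rejected", {
  expect_error(build_model(0.8, 60), "height")
  expect_error(build_model(1.7, 300), "weight")
  an <- default_anthropometry()
  an$segments <- an$segments[an$segments$segment != "foot", ]
  expect_error(build_model(1.7, 60, anthropometry = an), "foot")
})

test_that("foot contact points span the documented sole geometry", {
  g <- default_foot_geometry(1.69)
  cp <- foot_contact_points(g)
  pts <- cp$points
  expect_equal(ncol(pts), 22)
  # bounding box: heel-to-toe length by maximum width
  expect_equal(diff(range(pts["y", ])), g$d_heel + g$d_toe)
  expect_equal(diff(range(pts["x", ])), max(g$w_heel, g$w_mtp, g$w_phal))
  # all points on/below the sole plane at the phalanx height
  expect_true(all(pts["z", ] <= -g$h_phal + 1e-12))
  # degenerate widths collapse to the foot axis
  g0 <- g; g0$w_heel <- 0; g0$w_mtp <- 0; g0$w_phal <- 0
  cp0 <- foot_contact_points(g0)
  expect_true(all(abs(cp0$points["x", ]) < 1e-12))
  g$d_heel <- -0.1
  expect_error(foot_contact_points(g), "non-negative")
})

test_that("neutral pose is zero angles with both feet at equal height", {
  m <- ref_model()
  st <- neutral_pose(m)
  expect_true(all(st$q[7:27] == 0))
  expect_true(all(st$q[c("root_rx", "root_ry", "root_rz")] == 0))
  expect_true(all(st$qd == 0))
  # overrides pass through
  m2 <- build_model(1.69, 63.3, neutral = c(knee_l = -0.2))
  expect_equal(unname(neutral_pose(m2)$q["knee_l"]), -0.2)
  # forward kinematics: both soles at the same height, on the ground
  fk <- grfimu:::cpp_fk(m$cpp, grfimu:::state_vec(m, st))
  zl <- min((fk$R[, , m$segments$foot_l$body_index] %*%
               m$contact_points$left$points +
               fk$p[, m$segments$foot_l$body_index])[3, ])
  zr <- min((fk$R[, , m$segments$foot_r$body_index] %*%
               m$contact_points$left$points +
               fk$p[, m$segments$foot_r$body_index])[3, ])
  expect_equal(zl, zr, tolerance = 1e-12)
  expect_equal(zl, 0, tolerance = 1e-12)
})

test_that("chain of zero rotations reproduces summed segment offsets", {
  m <- ref_model()
  st <- neutral_pose(m)
  fk <- grfimu:::cpp_fk(m$cpp, grfimu:::state_vec(m, st))
  # oracle: cumulative addition of offsets down the left leg
  root <- c(0, 0, unname(st$q["root_tz"]))
  hip <- root + c(m$hip_half_spacing, 0, 0)
  knee <- hip + c(0, 0, -m$lengths[["thigh"]])
  ankle <- knee + c(0, 0, -m$lengths[["shank"]])
  expect_equal(fk$p[, m$segments$thigh_l$body_index], hip)
  expect_equal(fk$p[, m$segments$shank_l$body_index], knee)
  expect_equal(fk$p[, m$segments$foot_l$body_index], ankle)
})

test_that("model summary exports parseable JSON", {
  m <- ref_model()
  js <- model_summary_json(m)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$total_mass, 63.3)
  expect_length(parsed$coordinates, 27)
  expect_length(parsed$segments, 12)
})
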