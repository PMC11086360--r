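test_that("node allocation follows the 2/5/3 role rule", {
  m <- ref_model()
  traj <- allocate_nodes(m, c(0, 1))
  expect_s3_class(traj, "reference_trajectory")
  expect_equal(traj$dofs$shoulder_l_x$times, c(0, 1))
  expect_equal(traj$dofs$hip_l_x$times, seq(0, 1, 0.25))
  expect_equal(traj$dofs$knee_r$times, seq(0, 1, 0.25))
  expect_equal(traj$dofs$elbow_r$times, c(0, 1))
  # a leg excluded from the jump falls into the 3-node class
  rc <- default_role_config(jump_legs = "left")
  traj2 <- allocate_nodes(m, c(0, 1), rc)
  expect_equal(traj2$dofs$knee_r$times, c(0, 0.5, 1))
  expect_equal(traj2$dofs$knee_l$times, seq(0, 1, 0.25))
  # unclassified joint is a configuration error
  rc2 <- rc[names(rc) != "knee_l"]
  expect_error(allocate_nodes(m, c(0, 1), rc2), "classif")
})

test_that("reference splines interpolate and match a textbook oracle", {
  m <- ref_model()
  traj <- allocate_nodes(m, c(0, 1))
  # constant nodes give a constant reference with zero velocity
  traj$dofs$hip_l_x$values <- rep(0.5, 5)
  ev <- spline_reference(traj, seq(0, 1, 0.1))
  expect_true(all(abs(ev$q_r["hip_l_x", ] - 0.5) < 1e-12))
  expect_true(all(abs(ev$qd_r["hip_l_x", ]) < 1e-12))
  # interpolation property at the nodes
  vals <- c(0, 1, 0, -1, 0)
  traj$dofs$knee_l$values <- vals
  at_nodes <- spline_reference(traj, traj$dofs$knee_l$times)
  expect_equal(unname(at_nodes$q_r["knee_l", ]), vals, tolerance = 1e-12)
  # natural-cubic-spline oracle at mid-span
  oracle <- stats::splinefun(traj$dofs$knee_l$times, vals,
                             method = "natural")
  tq <- seq(0.05, 0.95, by = 0.06)
  ev2 <- spline_reference(traj, tq)
  expect_equal(unname(ev2$q_r["knee_l", ]), oracle(tq), tolerance = 1e-10)
  expect_equal(unname(ev2$qd_r["knee_l", ]), oracle(tq, deriv = 1),
               tolerance = 1e-8)
  expect_error(spline_reference(traj, 1.5), "outside")
})

test_that("orientation cost integrates squared Euler error", {
  time <- seq(0, 1, by = 0.01)
  T <- length(time)
  base <- lapply(1:12, function(i) matrix(0, 3, T))
  names(base) <- paste0("seg", 1:12)
  expect_equal(cost_IQ(base, base, time), 0)
  off <- base
  off$seg3[1, ] <- 0.1
  expect_equal(cost_IQ(off, base, time), 0.01, tolerance = 1e-12)
  off2 <- base
  off2$seg3[1, ] <- 0.2
  expect_equal(cost_IQ(off2, base, time) / cost_IQ(off, base, time), 4,
               tolerance = 1e-10)
})

test_that("pelvis-acceleration cost integrates squared differences", {
  time <- seq(0, 2, by = 0.01)
  A <- matrix(0, 3, length(time))
  expect_equal(cost_Ia_pelvis(A, A, time), 0)
  B <- A; B[2, ] <- 1
  expect_equal(cost_Ia_pelvis(B, A, time), 2, tolerance = 1e-12)
  # axis permutation of both inputs leaves the cost unchanged
  perm <- c(3, 1, 2)
  expect_equal(cost_Ia_pelvis(B[perm, ], A[perm, ], time),
               cost_Ia_pelvis(B, A, time))
})

test_that("muscle-load cost normalizes by the signed torque maxima", {
  m <- ref_model()
  time <- seq(0, 1, by = 0.001)
  tau <- matrix(0, 21, length(time))
  expect_equal(cost_Imuscle(tau, m$coords, time), 0)
  tau1 <- tau
  tau1[4, ] <- m$coords$tau_plus_max[4]       # knee at +max for 1 s
  expect_equal(cost_Imuscle(tau1, m$coords, time), 1, tolerance = 1e-12)
  tau2 <- tau
  tau2[4, ] <- m$coords$tau_minus_max[4]      # extension limit
  expect_equal(cost_Imuscle(tau2, m$coords, time), 1, tolerance = 1e-12)
  bad <- m$coords; bad$tau_plus_max[1] <- 0
  expect_error(cost_Imuscle(tau, bad, time), "non-zero")
})

test_that("total cost assembles the weighted sum", {
  cb <- total_cost(0.01, 0, 0, cost_weights(1e3, 1e3, 10))
  expect_equal(cb$I_all, 10)
  expect_equal(total_cost(0, 0, 0)$I_all, 0)
  expect_equal(total_cost(3, 7, 11, cost_weights(0, 0, 0))$I_all, 0)
  expect_error(cost_weights(-1, 1, 1))
})

test_that("cost quadrature converges under grid refinement", {
  f <- function(n) {
    time <- seq(0, 1, length.out = n)
    A <- lapply(1:12, function(i) matrix(0, 3, n))
    names(A) <- paste0("s", 1:12)
    B <- A
    B$s1[1, ] <- sin(2 * pi * time) * 0.2
    cost_IQ(B, A, time)
  }
  expect_lt(abs(f(201) - f(101)) / f(101), 0.01)
})

test_that("the genetic algorithm solves a convex stub and is reproducible", {
  m <- ref_model()
  skel <- allocate_nodes(m, c(0, 1))
  # target inside the search box (the box is clipped to joint limits)
  target <- ref_to_genes(skel) + 0.15
  obj <- function(genes) list(I_all = sum((genes - target)^2))
  ga <- ga_config(pop_size = 40, generations = 50, seed = 123,
                  init_sd = 0.2, mutation_sd = 0.05)
  res <- optimize_trajectory(m, NULL, skel, ga = ga, objective = obj)
  # 72 search dimensions on a 2000-evaluation budget: the verified
  # recovery level of this optimizer is a few hundredths of a radian
  expect_lt(sqrt(mean((ref_to_genes(res$best) - target)^2)), 0.05)
  # identical seed, identical best individual
  res2 <- optimize_trajectory(m, NULL, skel, ga = ga, objective = obj)
  expect_identical(ref_to_genes(res$best), ref_to_genes(res2$best))
  # greedy replacement: best-cost sequence is non-increasing
  expect_true(all(diff(res$history$best) <= 1e-12))
})
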