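#' Default joint role configuration for node allocation
#'
#' Classifies each joint DOF for spline-node allocation: upper-body joints
#' (shoulders, elbows, lumbar) get 2 nodes at the motion start and end,
#' jump-leg joints (hips, knees, ankles) get 5 evenly spaced nodes, and any
#' other joint gets 3.  By default both legs are treated as jump legs.
#'
#' @param jump_legs `"both"`, `"left"` or `"right"`; the non-jump leg (if
#'   any) falls into the 3-node class.
#' @return Named character vector mapping joint coordinate to role
#'   (`"upper"`, `"jump_leg"`, `"other"`).
#' @export
default_role_config <- function(jump_legs = c("both", "left", "right")) {
  jump_legs <- match.arg(jump_legs)
  cn <- joint_coord_names()
  role <- stats::setNames(rep("other", length(cn)), cn)
  role[grepl("^(shoulder|elbow|lumbar)", cn)] <- "upper"
  leg_l <- grepl("^(hip|knee|ankle)_l", cn)
  leg_r <- grepl("^(hip|knee|ankle)_r", cn)
  if (jump_legs %in% c("both", "left")) role[leg_l] <- "jump_leg"
  if (jump_legs %in% c("both", "right")) role[leg_r] <- "jump_leg"
  role
}

node_count_for_role <- function(role) {
  switch(role, upper = 2L, jump_leg = 5L, other = 3L,
         stop("unclassified joint role: ", role))
}

#' Allocate spline nodes for the reference joint angles
#'
#' Builds the skeleton of a reference trajectory: per controlled DOF, node
#' times evenly spaced over the motion span with the node count set by the
#' joint's role (2 for upper-body joints at start and end, 5 for jump-leg
#' joints, 3 otherwise).  Node values are initialized to the model's
#' neutral angles.
#'
#' @param model a [build_model()] object.
#' @param motion_span length-2 time interval (s) from motion start to end.
#' @param role_config named role vector, see [default_role_config()].
#' @return Object of class `reference_trajectory`: list with `dofs` (per
#'   DOF: `times`, `values`, `role`), `span`, and `n_nodes` (total node
#'   count over all DOFs).
#' @export
allocate_nodes <- function(model, motion_span,
                           role_config = default_role_config()) {
  stopifnot(inherits(model, "body_model"), length(motion_span) == 2,
            motion_span[2] > motion_span[1])
  cn <- joint_coord_names()
  missing <- setdiff(cn, names(role_config))
  if (length(missing))
    stop("role_config does not classify joints: ",
         paste(missing, collapse = ", "))
  dofs <- lapply(cn, function(nm) {
    m <- node_count_for_role(role_config[[nm]])
    list(times = seq(motion_span[1], motion_span[2], length.out = m),
         values = rep(unname(model$neutral[nm]), m),
         role = role_config[[nm]])
  })
  names(dofs) <- cn
  out <- list(dofs = dofs, span = motion_span,
              n_nodes = sum(vapply(dofs, function(d) length(d$times), 0L)))
  class(out) <- "reference_trajectory"
  out
}

# internal: constant reference holding the neutral pose over a span
constant_reference <- function(model, duration, start = 0) {
  allocate_nodes(model, c(start, start + duration))
}

# internal: bail out early if the reference does not cover the span
check_reference_span <- function(reference, t_span) {
  sp <- reference$span
  if (t_span[1] < sp[1] - 1e-9 || t_span[2] > sp[2] + 1e-9)
    stop("reference trajectory spans [", sp[1], ", ", sp[2],
         "] s but simulation requires [", t_span[1], ", ", t_span[2], "] s")
  invisible(TRUE)
}

#' Evaluate the reference splines
#'
#' Natural cubic spline through each DOF's nodes (linear for 2-node DOFs),
#' evaluated together with its first derivative.
#'
#' @param traj a `reference_trajectory`.
#' @param t evaluation times (s), inside the trajectory span.
#' @return List with matrices `q_r` and `qd_r` (21 x length(t), named
#'   rows).
#' @export
spline_reference <- function(traj, t) {
  stopifnot(inherits(traj, "reference_trajectory"))
  if (any(t < traj$span[1] - 1e-9) || any(t > traj$span[2] + 1e-9))
    stop("evaluation times outside the trajectory span")
  n <- length(traj$dofs)
  q_r <- matrix(0, n, length(t), dimnames = list(names(traj$dofs), NULL))
  qd_r <- q_r
  for (j in seq_len(n)) {
    d <- traj$dofs[[j]]
    ev <- cpp_spline_eval(d$times, d$values, t)
    q_r[j, ] <- ev$value
    qd_r[j, ] <- ev$deriv
  }
  list(q_r = q_r, qd_r = qd_r)
}

# internal: flatten / restore node values for the optimizer
ref_to_genes <- function(traj) {
  unlist(lapply(traj$dofs, `[[`, "values"), use.names = FALSE)
}

genes_to_ref <- function(traj, genes) {
  k <- 0
  for (j in seq_along(traj$dofs)) {
    m <- length(traj$dofs[[j]]$values)
    traj$dofs[[j]]$values <- genes[(k + 1):(k + m)]
    k <- k + m
  }
  traj
}

#' Orientation-error cost
#'
#' Integrated squared Euler-angle error, summed over segments:
#' `I_Q = sum_s int (dphi^2 + dtheta^2 + dpsi^2) dt` by trapezoidal
#' quadrature on the common time grid.  Angle differences are wrapped to
#' (-pi, pi].  Segments present in both inputs are compared; in
#' reduced-sensor mode a segment without a measured series is simply
#' absent from the measurement list and drops out of the sum.
#'
#' @param model_orient,measured_orient named lists (per segment) of 3 x T
#'   Euler-angle series (rad, intrinsic X-Y-Z), on a common time grid.
#' @param time the common time grid (s).
#' @return Scalar cost (rad^2 s).
#' @export
cost_IQ <- function(model_orient, measured_orient, time) {
  segs <- intersect(names(model_orient), names(measured_orient))
  if (!length(segs)) stop("no common segments between the orientation sets")
  total <- 0
  for (s in segs) {
    A <- model_orient[[s]]; B <- measured_orient[[s]]
    if (!all(dim(A) == dim(B)) || ncol(A) != length(time))
      stop("orientation series grids do not match")
    d2 <- colSums(wrap_angle(A - B)^2)
    total <- total + trapz(time, d2)
  }
  total
}

#' Pelvis-acceleration cost
#'
#' Integrated squared difference between simulated and measured pelvis
#' sensor acceleration: `I_a = int sum_axis (da)^2 dt`, both series
#' expressed in the pelvis sensor frame.
#'
#' @param model_acc,measured_acc 3 x T acceleration series (m/s^2) on a
#'   common grid.
#' @param time the common time grid (s).
#' @return Scalar cost ((m/s^2)^2 s).
#' @export
cost_Ia_pelvis <- function(model_acc, measured_acc, time) {
  if (!all(dim(model_acc) == dim(measured_acc)) ||
      ncol(model_acc) != length(time))
    stop("acceleration series grids do not match")
  trapz(time, colSums((model_acc - measured_acc)^2))
}

#' Muscle-load cost
#'
#' Sum over joints of the integrated cubed normalized active torque:
#' `I_muscle = sum_j int (sigma_plus^3 + sigma_minus^3) dt` with
#' `sigma_plus = tau_a / tau_plus_max` when `tau_a >= 0` (else 0) and
#' `sigma_minus = tau_a / tau_minus_max` when `tau_a < 0` (else 0).  Since
#' `tau_minus_max` is stored negative, both ratios are non-negative and
#' the penalty grows with effort in either direction.
#'
#' @param tau_a 21 x T active-torque series (N m).
#' @param joint_specs data frame with `tau_plus_max`, `tau_minus_max` per
#'   joint (e.g. `model$coords`).
#' @param time the time grid (s).
#' @return Scalar cost (s).
#' @export
cost_Imuscle <- function(tau_a, joint_specs, time) {
  tp <- joint_specs$tau_plus_max
  tm <- joint_specs$tau_minus_max
  if (any(tp == 0) || any(tm == 0))
    stop("maximum torques must be non-zero")
  total <- 0
  for (j in seq_len(nrow(tau_a))) {
    sp <- ifelse(tau_a[j, ] >= 0, tau_a[j, ] / tp[j], 0)
    sm <- ifelse(tau_a[j, ] < 0, tau_a[j, ] / tm[j], 0)
    total <- total + trapz(time, sp^3 + sm^3)
  }
  total
}

#' Cost weights
#'
#' Weight factors of the three cost terms.  Defaults `xi1 = xi2 = 1e3`,
#' `xi3 = 10`.
#'
#' @param xi1,xi2,xi3 non-negative weights for the orientation,
#'   pelvis-acceleration and muscle-load terms.
#' @return List of class `cost_weights`.
#' @export
cost_weights <- function(xi1 = 1e3, xi2 = 1e3, xi3 = 10) {
  stopifnot(xi1 >= 0, xi2 >= 0, xi3 >= 0)
  structure(list(xi1 = xi1, xi2 = xi2, xi3 = xi3), class = "cost_weights")
}

#' Assemble the total cost
#'
#' `I_all = xi1 I_Q + xi2 I_a_pelvis + xi3 I_muscle`.
#'
#' @param I_Q,I_a_pelvis,I_muscle component costs.
#' @param weights a [cost_weights()] object.
#' @return List of class `cost_breakdown` with the components and `I_all`.
#' @export
total_cost <- function(I_Q, I_a_pelvis, I_muscle,
                       weights = cost_weights()) {
  out <- list(I_Q = I_Q, I_a_pelvis = I_a_pelvis, I_muscle = I_muscle,
              I_all = weights$xi1 * I_Q + weights$xi2 * I_a_pelvis +
                weights$xi3 * I_muscle,
              weights = weights)
  class(out) <- "cost_breakdown"
  out
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> I_all = %.4g  (I_Q = %.4g, I_a_pelvis = %.4g, I_muscle = %.4g)\n",
    x$I_all, x$I_Q, x$I_a_pelvis, x$I_muscle))
  invisible(x)
}

# internal: evaluate the full cost of one candidate trajectory against
# measurements; returns a cost_breakdown (Inf cost on simulation failure)
evaluate_candidate <- function(model, traj, measurements, weights,
                               sim_opts) {
  sim <- tryCatch(
    simulate_motion(model, traj, t_span = traj$span,
                    state0 = sim_opts$state0, method = sim_opts$method,
                    rtol = sim_opts$rtol, atol = sim_opts$atol,
                    out_hz = sim_opts$cost_hz),
    error = function(e) NULL)
  if (is.null(sim)) {
    out <- total_cost(Inf, Inf, Inf, weights)
    out$failed <- TRUE
    return(out)
  }
  tgrid <- sim$time
  model_eul <- attr(sim$orientations, "euler")
  if (is.null(model_eul))
    model_eul <- lapply(sim$orientations, function(Q)
      apply(Q, 2, euler_xyz_from_quat))
  meas_eul <- measurements$euler
  meas_on_grid <- lapply(meas_eul, function(E)
    apply(E, 1, function(row)
      stats::approx(measurements$time, row, xout = tgrid, rule = 2)$y))
  meas_on_grid <- lapply(meas_on_grid, t)
  IQ <- cost_IQ(model_eul, meas_on_grid, tgrid)
  acc_meas <- apply(measurements$pelvis_acc, 1, function(row)
    stats::approx(measurements$time, row, xout = tgrid, rule = 2)$y)
  Ia <- cost_Ia_pelvis(sim$pelvis_acc, t(acc_meas), tgrid)
  refv <- spline_reference(traj, tgrid)
  tau_a <- model$gains$K_PD * (refv$q_r - sim$q[7:27, , drop = FALSE]) +
    model$gains$D_PD * (refv$qd_r - sim$qd[7:27, , drop = FALSE])
  Im <- cost_Imuscle(tau_a, model$coords, tgrid)
  out <- total_cost(IQ, Ia, Im, weights)
  out$sim <- sim
  out
}

#' Genetic-algorithm configuration
#'
#' Settings of the real-coded GA used to optimize the spline node values:
#' population size, generation count, simulated-binary-crossover and
#' Gaussian-mutation parameters, elitism, seed and node bounds.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations.
#' @param p_crossover per-pair crossover probability.
#' @param sbx_eta distribution index of simulated binary crossover.
#' @param p_mutation per-gene mutation probability.
#' @param mutation_sd Gaussian mutation standard deviation (rad).
#' @param elitism number of elite individuals copied unchanged.
#' @param seed RNG seed (integer).
#' @param bound_width half-width (rad) of the search box around the
#'   initial node values, clipped to the joint limits.
#' @param init_sd standard deviation (rad) of the initial population
#'   scatter around the warm start.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 60, generations = 100, p_crossover = 0.9,
                      sbx_eta = 15, p_mutation = 0.15, mutation_sd = 0.02,
                      elitism = 2, seed = 1, bound_width = 0.6,
                      init_sd = 0.03) {
  stopifnot(pop_size >= 2, generations >= 1, elitism >= 0,
            elitism < pop_size, is.finite(bound_width))
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, sbx_eta = sbx_eta,
                 p_mutation = p_mutation, mutation_sd = mutation_sd,
                 elitism = elitism, seed = seed, bound_width = bound_width,
                 init_sd = init_sd),
            class = "ga_config")
}

# internal: simulated binary crossover of two parents (vectors), in bounds
sbx_crossover <- function(p1, p2, eta, lower, upper) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

#' Optimize the reference trajectory against measurements
#'
#' Minimizes the weighted three-term cost (segment-orientation error,
#' pelvis-acceleration error, muscle load) over the spline node values
#' with a real-coded genetic algorithm (tournament selection, simulated
#' binary crossover, Gaussian mutation, elitism).  The initial population
#' is scattered around `init` (a warm start, typically the measured joint
#' angles sampled at the node times); with elitism the best cost per
#' generation is non-increasing, and a fixed seed gives identical results.
#'
#' @param model a [build_model()] object.
#' @param measurements list with `time`, `euler` (named list of 3 x T
#'   measured segment Euler series), `pelvis_acc` (3 x T, sensor frame) —
#'   as produced by [trial_measurements()].
#' @param skeleton a `reference_trajectory` giving node times (and the
#'   warm-start values unless `init` is supplied).
#' @param ga a [ga_config()].
#' @param weights a [cost_weights()].
#' @param sim_opts list of simulation options: `state0`, `method`,
#'   `rtol`, `atol`, `cost_hz` (cost-evaluation grid, Hz).
#' @param init optional warm-start gene vector (node values, rad).
#' @param objective optional custom objective `function(genes)` returning
#'   a list with at least `I_all`; replaces the simulation-based cost
#'   (used for optimizer validation and custom criteria).
#' @param verbose print per-generation progress.
#' @return List of class `ga_result`: `best` (reference_trajectory),
#'   `best_cost` (cost_breakdown), `history` (per-generation best/mean
#'   cost data frame), `n_failed` (diverged candidate count).
#' @export
optimize_trajectory <- function(model, measurements, skeleton,
                                ga = ga_config(), weights = cost_weights(),
                                sim_opts = list(), init = NULL,
                                objective = NULL, verbose = FALSE) {
  stopifnot(inherits(skeleton, "reference_trajectory"))
  so <- utils::modifyList(list(state0 = neutral_pose(model),
                               method = "trbdf2", rtol = 1e-3, atol = 1e-5,
                               cost_hz = 100), sim_opts)
  if (is.null(init)) init <- ref_to_genes(skeleton)
  ng <- length(init)
  # per-gene bounds: warm start +/- bound_width, clipped to joint limits
  gene_dof <- rep(seq_along(skeleton$dofs),
                  vapply(skeleton$dofs, function(d) length(d$times), 0L))
  lower <- pmax(init - ga$bound_width, model$coords$q_min[gene_dof] - 0.2)
  upper <- pmin(init + ga$bound_width, model$coords$q_max[gene_dof] + 0.2)
  lower <- pmin(lower, init); upper <- pmax(upper, init)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(ga$seed)

  init_pop <- attr(init, "population")
  pop <- matrix(0, ga$pop_size, ng)
  pop[1, ] <- init
  k0 <- 1
  if (!is.null(init_pop)) {
    # additional caller-supplied seed individuals (e.g. warm starts at
    # several smoothing levels)
    extra <- min(nrow(init_pop), ga$pop_size - 1)
    for (i in seq_len(extra))
      pop[1 + i, ] <- pmin(pmax(init_pop[i, ], lower), upper)
    k0 <- 1 + extra
  }
  for (i in seq_len(ga$pop_size)) {
    if (i <= k0) next
    pop[i, ] <- pmin(pmax(init + stats::rnorm(ng, 0, ga$init_sd), lower),
                     upper)
  }

  eval_one <- if (is.null(objective)) {
    function(genes)
      evaluate_candidate(model, genes_to_ref(skeleton, genes),
                         measurements, weights, so)
  } else objective
  evals <- lapply(seq_len(ga$pop_size), function(i) eval_one(pop[i, ]))
  costs <- vapply(evals, function(e) e$I_all, 0)
  n_failed <- sum(!is.finite(costs))
  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric())
  best_idx <- which.min(costs)
  best_genes <- pop[best_idx, ]; best_eval <- evals[[best_idx]]

  # steady-state evolution with greedy replacement: every child competes
  # with the individual in its slot (the best is never lost), a quarter
  # of the budget goes into (1+1)-ES polish of the incumbent best with
  # 1/5th-rule step adaptation, half into differential best/1/bin moves,
  # and the rest into simulated binary crossover with annealed Gaussian
  # mutation for diversity
  n_polish <- max(1L, ga$pop_size %/% 4)
  sigma <- ga$mutation_sd
  es_succ <- 0L; es_tries <- 0L
  tournament <- function() {
    cand <- sample.int(ga$pop_size, 2)
    cand[which.min(costs[cand])]
  }
  for (gen in seq_len(ga$generations)) {
    sd_gen <- ga$mutation_sd *
      0.25^((gen - 1) / max(1, ga$generations - 1))
    for (i in seq_len(ga$pop_size)) {
      if (i <= n_polish) {
        child <- pmin(pmax(best_genes + stats::rnorm(ng, 0, sigma),
                           lower), upper)
        ev <- eval_one(child)
        if (!is.finite(ev$I_all)) n_failed <- n_failed + 1
        es_tries <- es_tries + 1L
        if (is.finite(ev$I_all) && ev$I_all < best_eval$I_all) {
          best_genes <- child; best_eval <- ev
          es_succ <- es_succ + 1L
        }
        if (es_tries >= 10L) {
          sigma <- sigma * if (es_succ / es_tries > 0.2) 1.6 else 0.65
          sigma <- min(max(sigma, 1e-4), 0.3)
          es_succ <- 0L; es_tries <- 0L
        }
        next
      }
      if (stats::runif(1) < 0.67) {
        # differential best/1/bin child
        rr <- sample.int(ga$pop_size, 2)
        donor <- best_genes + 0.5 * (pop[rr[1], ] - pop[rr[2], ])
        cross <- stats::runif(ng) < 0.9
        cross[sample.int(ng, 1)] <- TRUE
        child <- pop[i, ]
        child[cross] <- donor[cross]
      } else {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        child <- if (stats::runif(1) < ga$p_crossover)
          sbx_crossover(p1, p2, ga$sbx_eta, lower, upper)[[1]] else p1
        mut <- stats::runif(ng) < ga$p_mutation
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sd_gen)
      }
      child <- pmin(pmax(child, lower), upper)
      ev <- eval_one(child)
      if (!is.finite(ev$I_all)) n_failed <- n_failed + 1
      if (is.finite(ev$I_all) && ev$I_all < costs[i]) {
        pop[i, ] <- child; evals[[i]] <- ev; costs[i] <- ev$I_all
        if (ev$I_all < best_eval$I_all) {
          best_genes <- child; best_eval <- ev
        }
      }
    }
    history <- rbind(history,
                     data.frame(generation = gen, best = best_eval$I_all,
                                mean = mean(costs[is.finite(costs)])))
    if (verbose)
      message(sprintf("generation %3d  best %.5g  mean %.5g", gen,
                      best_eval$I_all, mean(costs[is.finite(costs)])))
  }
  if (!is.finite(best_eval$I_all))
    stop("optimization failure: every candidate simulation diverged")
  out <- list(best = genes_to_ref(skeleton, best_genes),
              best_cost = best_eval, history = history,
              n_failed = n_failed, ga = ga, weights = weights)
  class(out) <- "ga_result"
  out
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, population %d\n",
              x$ga$generations, x$ga$pop_size))
  print(x$best_cost)
  invisible(x)
}

# trapezoidal quadrature
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
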