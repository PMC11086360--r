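---
title: "Estimating ground reaction forces from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ground reaction forces from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Force plates measure ground reaction forces (GRF) directly but confine the
movement to a laboratory. `grfimu` estimates GRF, ground reaction moments
(GRM), joint angles and joint torques of dynamic whole-body movements from
body-worn inertial measurement units (IMUs) alone. The approach is
physics-based rather than data-driven: a forward-dynamics simulation of an
articulated human model *generates* candidate movements, and an optimizer
adjusts the movement until it agrees with what the sensors recorded. The
ground reaction force is then read off the model's foot–ground contact
elements, so it is biomechanically consistent by construction, even when not
every segment carries a sensor.

The pipeline is:

1. build the subject-scaled rigid-body model from height and weight;
2. fuse each adjacent sensor pair with an extended Kalman filter (EKF) to
   obtain segment orientations that are insensitive to dynamic acceleration;
3. parameterize reference joint-angle trajectories as cubic splines over a
   small number of nodes;
4. simulate the model tracking those references with PD joint torques, and
   score the simulation against the fused orientations and the pelvis
   accelerometer plus an internal muscle-load penalty;
5. minimize that score over the node values with a genetic algorithm (GA);
6. re-simulate the best reference and export GRF/GRM/joint time series.

`grf_estimate()` wraps steps 2–6 behind one fitting call and returns a
`grf_fit` object with `print`, `summary`, `coef`, `predict`, `plot` and
`residuals` methods.

# The human model

The skeleton has 12 rigid segments — pelvis, trunk (head and neck lumped
in), and bilateral upper arms, forearms (hands lumped in), thighs, shanks
and feet. Joints contribute 21 rotational degrees of freedom: 3-DOF hips,
lumbar joint and shoulders (intrinsic X–Y–Z Euler sequences:
flexion–extension, adduction–abduction, axial rotation), and 1-DOF knees,
ankles and elbows. A 6-DOF virtual joint links the pelvis to the global
frame (Z up, gravity $(0,0,-9.81)\,\mathrm{m/s^2}$), for 27 generalized
coordinates in total. Internally every multi-DOF joint is expanded into
chained single-axis joints with massless intermediate bodies, which lets the
dynamics engine run standard recursive algorithms (articulated-body for
forward dynamics; composite-rigid-body and recursive Newton–Euler for the
inertia matrix and bias forces, kept as an independent cross-check of the
hot path).

Segment masses, lengths, centres of mass and radii of gyration scale from
the participant's height and weight through a pluggable anthropometry table
(`default_anthropometry()`), a rounded de Leva-style adjusted-Zatsiorsky
adult set. Mass fractions are renormalized so the segment masses sum to the
input weight exactly. Any table with the same columns can be substituted,
e.g. population-specific or athlete data.

# Torques, contact and balance

The equations of motion $M(q)\ddot q + \Gamma(q,\dot q, F_v, F_h,
\tau_{virtual}) = \tau$ are driven by three torque groups:

* **Active torque** — PD tracking of the reference angles,
  $\tau_a = K_{PD}(q_r - q) + D_{PD}(\dot q_r - \dot q)$ with
  $K_{PD} = 1000\,$N·m/rad and $D_{PD} = 10\,$N·m·s/rad on all 21 joint
  DOFs (a single scalar gain pair, as printed).
* **Passive torque** — a double exponential that is dormant mid-range and
  rises steeply at the anatomical limits,
  $\tau_p = -a e^{b(q - q_{max})} + a e^{b(q_{min} - q)} - c\dot q$
  (defaults $a = 2\,$N·m, $b = 20\,$rad$^{-1}$, $c = 0.1\,$N·m·s/rad; the
  published coefficient sources do not print values, so these are package
  defaults, per-DOF configurable). The exponent is capped at 10 with a
  linear continuation so that transient overshoots during integration
  produce strong but finite torques.
* **Virtual balance torque** — $\tau_{virtual} = -K_{virtual} q_{virtual}
  - D_{virtual}\dot q_{virtual}$ on the root Euler rotations, with
  $K_{virtual} = (400, 400, 0)$ N·m/rad and $D_{virtual} = (40, 40, 0)$
  N·m·s/rad. The printed gain digits are typographically ambiguous; we
  adopt the zero-yaw reading because the method's own error analysis
  attributes the virtual torque to sagittal and frontal plane rotations,
  and axial (twist) rotation should remain free. The torque is applied as
  a generalized force on the root Euler coordinates — a pure torque, no
  force component.

Each foot carries 22 contact points laid out from sole landmark distances
(heel, metatarsophalangeal joint and second-phalanx tip distances, three
widths, two heights): a 7×3 grid with interpolated width plus a toe-tip
pad. Each point generates a unilateral viscoelastic normal force
$F_v = \max(0, -K_G(r_z - r_{z0}) - D_G \dot r_z)$ ($K_G = 10^3\,$N/m,
$D_G = 10^4\,$N·s/m, $r_{z0} = 0$) — clamped to zero outside penetration,
since the ground cannot pull — and regularized Coulomb friction
$|F_h| = \mu(v) F_v \min(1, v/v_0)$ with
$\mu(v) = \mu_d + (\mu_s - \mu_d)e^{-v/v_0}$, $\mu_s = 0.7$,
$\mu_d = 0.5$ and regularization speed $v_0 = 0.01$ m/s. The ramp below
$v_0$ removes the discontinuity at rest, at the cost of permitting slow
creep under sustained shear — a standard trade-off of regularized
friction.

# Numerical integration

Two integrators are built in. The reference integrator is an adaptive
Dormand–Prince Runge–Kutta 4(5) (rel. tol. $10^{-6}$, abs. tol.
$10^{-8}$). The contact damping, however, makes stance-phase dynamics
stiff: $D_G$ acting through 22 points on a ~0.9 kg foot gives eigenvalues
of order $-10^5\,$s$^{-1}$, limiting any explicit method to ~10 µs steps.
We therefore also provide an L-stable TR-BDF2 method (adaptive, embedded
third-order error estimate, modified Newton with lazy numerically
differenced Jacobians) which takes millisecond-scale steps through stance
at equal output accuracy and is the default inside the optimizer loop,
where hundreds of candidate simulations are required (at a relaxed
tolerance of $10^{-3}$ relative — candidate ranking is insensitive to
the few-newton GRF differences this introduces; the final re-simulation
of the best trajectory runs at $10^{-5}$). The two integrators
are compared against each other in the test suite; simulations are
deterministic (identical inputs give bit-identical outputs).

Outputs are sampled on a fixed grid (default 1000 Hz) by stepping exactly
onto the output times. Integration aborts with a diagnostic if any joint
exceeds its anatomical limit by more than 1 rad; inside the GA such
divergent candidates simply receive infinite cost.

# Orientation estimation

Accelerometer-based inclination fails during high-acceleration movement,
and magnetometers are unreliable indoors. The package therefore fuses each
*adjacent pair* of IMUs across a joint: after subtracting each sensor's
centripetal and tangential components $\omega\times(\omega\times l_s) +
\dot\omega\times l_s$ (lever arms measured from the spanned joint), both
sensors observe the same gravitational-plus-translational acceleration.
Expressing that equality in each sensor's frame yields the EKF observation;
the state stacks both orientation quaternions (scalar-first), propagated by
first-order gyro integration $x \leftarrow (I + \tfrac{dt}{2}
\,\mathrm{blkdiag}(\Omega_s, \Omega_{s+1}))\,x$ and renormalized after
every step, since the first-order transition does not preserve unit norm.
Process and observation noise scales default to $w = 10^{-3}$ (per state
component) and $v = 10^{-1}\,$m/s² with initial covariance
$P_0 = \mathrm{diag}(10^2)$. The printed scales do not state units; $v$
is treated as an observation standard deviation and $w$ as a
continuous-time random-walk intensity, so the per-step process
covariance is $\mathrm{diag}(w^2\,dt)$ — this keeps the drift rate of
the unobservable directions independent of the sampling rate.
Observation Jacobians are analytic derivatives of the homogeneous
quaternion rotation, verified against finite differences in the tests.

Design choices worth knowing about:

* **Angular acceleration** is obtained by central differences of the gyro
  signal after an 18 Hz zero-phase low-pass (raw differentiation at
  1000 Hz amplifies the gyro white noise far beyond the modeled
  observation noise). Because the zero-phase filter needs future
  samples, its estimates inside the edge-settling window (~0.15 s at
  each end of a trial) are unreliable and the filter coasts on
  prediction there instead of updating.
* **Innovation gating.** During impacts and push-off the finite-difference
  $\dot\omega$ is briefly unreliable while the observation is numerically
  very informative (its Jacobian scales with the compensated acceleration).
  Updates whose normalized innovation squared exceeds a $\chi^2_6$ gate
  (99.9 %) are skipped, so the filter coasts on gyro integration — which is
  accurate at these durations — and resumes correcting in calm phases. A
  rescue counter prevents indefinite rejection.
* **Observability.** The pairwise observation constrains only the relative
  orientation: a common rotation of both links leaves the innovation
  unchanged (asserted as a test invariant). The state correction is
  therefore decomposed in the tangent basis of common, relative and
  radial directions and restricted to the relative part, so residual
  model error cannot push the absolute orientations, which rest on
  initialization plus gyro integration and drift only with gyro bias.
  In near-static, gravity-aligned postures the relative rotation about
  the gravity axis is itself only weakly observable and carries a
  degree-scale uncertainty floor; the strongly observed flexion
  component is recovered to fractions of a degree.
  Initialization comes from a static calibration posture
  (`init_from_calibration()`: roll/pitch from the time-averaged gravity
  direction, yaw defined as zero in the calibration heading). When the
  initial orientation is known to calibration quality, `grf_estimate()`
  shrinks $P_0$ to $\mathrm{diag}(10^{-3})$ — a large $P_0$ would let the
  first, least-settled samples overwrite a sub-degree initialization.
* **Chaining.** One filter runs per joint of the sensor tree; global
  segment orientations are composed outward from the pelvis (whose
  absolute estimate is taken from the pelvis–trunk pair). Segments without
  a sensor simply drop out of the orientation cost (reduced-sensor mode).

# Cost function and optimization

Reference angles are cubic splines (natural end conditions) through a
small node set: 2 nodes (start/end) for upper-body joints, 5 evenly spaced
nodes for jump-leg joints, 3 for any other joint; with both legs treated
as jump legs this gives 72 free node values. The cost is

$$I_{all} = \xi_1 I_Q + \xi_2 I_{a,pelvis} + \xi_3 I_{muscle},
\qquad \xi = (10^3, 10^3, 10),$$

where $I_Q$ integrates squared per-segment Euler-angle errors against the
EKF estimates (trapezoidal quadrature on a 100 Hz grid, angle differences
wrapped), $I_{a,pelvis}$ integrates the squared pelvis accelerometer error
(sensor frame, measured signal low-passed at 18 Hz), and $I_{muscle}$
integrates cubed active torques normalized by the maximum positive and
negative joint torques. The negative maximum is stored as a negative
number so that extension effort also yields a positive penalty — summing
cubes of a signed ratio would otherwise *reward* extension torque.
Maximum-torque values are a documented default table
(`default_torque_limits()`), overridable per DOF.

The optimizer is a real-coded genetic algorithm run steady-state with
greedy replacement (every child competes with the individual in its
slot, so the best is never lost). A quarter of each generation's budget
polishes the incumbent best with (1+1)-ES Gaussian steps whose scale
adapts by the 1/5th success rule; half produces differential best/1/bin
children; the rest applies simulated binary crossover with annealed
Gaussian mutation for diversity. The population is seeded around a warm
start — the measured joint angles (6 Hz-smoothed) sampled at the node
times, with first nodes anchored to the known initial posture, plus two
extra warm starts at 3 and 12 Hz smoothing. Search bounds are a ±0.6 rad
box around the warm start clipped to the joint limits. Identical seeds
give identical results and the best cost is non-increasing. On a convex
72-dimensional stub the optimizer recovers node values to about 0.02 rad
RMS within a population-40, 50-generation budget. Full-fidelity runs
default to population 60 over 100 generations; the bundled tests use
population 30 over 30 generations to keep the suite within desk-scale
budgets.

# Synthetic trials

Because the original recordings are not deposited, the package generates
its own ground truth (`make_fixture()`): scenario node sets
(`"calibration-pose"`, `"squat-jump"`, `"single-leg-hop"`) are simulated at
full fidelity, the exact sensor signals are synthesized from the motion
(specific force at each mounting point plus segment angular velocity, in
the sensor frame), and white noise plus a gyro bias random walk are added
(defaults 0.05 m/s², 0.005 rad/s, $10^{-4}$ rad/s/√s — plausible for a
consumer-grade MEMS unit, seeded and reproducible).

Scenario design choices:

* Trials open in a **quiet two-footed stance**: the initial state is
  settled to equilibrium by simulating a damped hold phase, and each
  spline's first node is adjusted so the reference starts at rest. This
  mirrors the calibration-first measurement protocol and gives the EKF a
  calm convergence window; it also avoids spurious contact impulses from
  inconsistent initial conditions.
* The **single-leg hop** crouches while tucking the right leg, then
  drives an explosive left-leg push that unloads the stance leg to a
  fraction of body weight; with the adopted virtual-torque gains the
  balance margin does not permit a sustained aerial phase at this
  movement scale, so the scenario is a hop *attempt* with a rich
  unload/reload force profile rather than a flight-and-landing.
  Whole-body balance under purely open-loop references is marginal: the
  crouched single-leg stance is an unstable configuration, which is why
  the scenarios dwell near neutral and pass through the crouch
  transiently.
* The generator is *first-class, tested code*: sensor synthesis is checked
  against numerical differentiation of the sensor-point trajectory, truth
  GRF against the whole-body Newton balance, and the noise model against
  its configured variance.

What passing the inverse-crime test does and does not show: the estimator
sees data produced by its own forward model, so the test verifies internal
consistency of the whole chain (sensor model → EKF → cost → GA → contact
GRF) under realistic sensor noise — not accuracy on real movements, where
soft-tissue artifact, model mismatch and mounting errors dominate.

# Validation metrics

`compare_series()` reports Pearson's ρ (classified as weak ≤ 0.35 <
moderate ≤ 0.67 < strong ≤ 0.9 < excellent; negative values fall in the
weak band by their signed value), RMSE, and relative RMSE — RMSE divided
by the mean of the two series' ranges, in percent. Curves are compared
after phase normalization to 101 points between heel strike and toe-off
(`detect_events()`, threshold 20 N with linearly interpolated crossings;
a series already above threshold at its first sample opens the phase
window there). Forces normalize to %BW and moments to %BW·BH
(`normalize_grf()`, `normalize_grm()`). Filtering uses a fourth-order
Butterworth (−3 dB at 18 Hz), zero-phase by default with a single-pass
mode for response checks.

# Worked example

```{r example}
library(grfimu)

fx <- make_fixture("single-leg-hop", noise = noise_model(seed = 1))
fit <- grf_estimate(fx$trial, model = fx$model, state0 = fx$state0,
                    init_orientation = fx$init_quat,
                    ga = ga_config(pop_size = 30, generations = 30,
                                   seed = 17))
summary(fit)

ev <- detect_events(fx$truth$grf["z", ], fx$truth$time)
compare_series(
  phase_normalize(fit$sim$grf["z", ], fit$sim$time, ev),
  phase_normalize(fx$truth$grf["z", ], fx$truth$time, ev))
```

# Known limitations

* Balance is maintained only by the virtual root torque and the PD
  references, with no feedback control; long quiet single-leg phases and
  deep crouches drift, and candidate references far from a feasible
  movement can topple the model (those candidates receive infinite cost).
* The regularized friction cannot represent true stiction; slow creep
  occurs under sustained shear.
* The spline node grid (evenly spaced, 2/5/3 per role) caps how fast a
  reference can change, which limits achievable push-off impulses at
  short trial durations.
* Absolute heading is unobservable without a magnetometer and relies on
  the calibration heading plus gyro integration.
* Estimation accuracy on *real* data is bounded by effects the synthetic
  trials deliberately omit: soft-tissue artifact, mounting uncertainty,
  and anthropometric mismatch.
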