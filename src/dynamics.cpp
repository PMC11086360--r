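// Articulated rigid-body dynamics core: spatial-vector algebra over the
// 27-joint kinematic tree (6-DOF floating base + 21 revolute joints),
// viscoelastic foot-ground contact, PD/passive/virtual torque model,
// and time integration (explicit Dormand-Prince 4(5) and L-stable TR-BDF2).
//
// Conventions:
//   - world frame: X lateral, Y anterior, Z up; gravity (0,0,-g).
//   - every multi-DOF anatomical joint is expanded into chained 1-DOF
//     joints (intrinsic X-Y-Z Euler sequence) with massless intermediate
//     bodies; segment inertia sits on the last body of each chain.
//   - generalized coordinates: q[0..2] root translation (m), q[3..5] root
//     X-Y-Z Euler rotation (rad), q[6..26] joint rotations (rad).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;


struct BodyDef {
  int parent;        // -1 = world
  int jtype;         // 0 prismatic, 1 revolute
  vec3 axis;         // joint axis in parent body frame (local, pre-rotation)
  vec3 offset;       // joint origin in parent body frame
  double mass;
  vec3 com;          // COM in body frame
  mat33 Icom;        // inertia about COM, body frame
};

struct Model {
  int nb;
  std::vector<BodyDef> body;
  std::vector<mat66> Isp;                // cached spatial inertias
  int left_foot, right_foot, pelvis;   // body indices (0-based)
  mat cpL, cpR;                        // 3 x ncp contact points, foot frame
  // control gains
  double KPD, DPD;
  vec3 Kv, Dv;
  // ground
  double KG, DG, mus, mud, rz0, vreg;
  // passive torque per joint coordinate (nj = nb - 6)
  vec pa, pb, pc, qmin, qmax;
  double grav;
};

// ---------- spatial algebra helpers (6x6 matrices, [angular; linear]) ----

static mat33 rot_axis(const vec3& a, double q) {
  // rotation matrix: rotates a vector by angle q about unit axis a
  double c = std::cos(q), s = std::sin(q);
  mat33 K = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  mat33 R; R.eye();
  R += s * K + (1.0 - c) * (K * K);
  return R;
}

static mat33 skew(const vec3& v) {
  mat33 S = {{0, -v(2), v(1)}, {v(2), 0, -v(0)}, {-v(1), v(0), 0}};
  return S;
}

// motion transform A->B from rotation E (vB = E vA) and r = origin of B in A
static mat66 xform(const mat33& E, const vec3& r) {
  mat66 X; X.zeros();
  X.submat(0, 0, 2, 2) = E;
  X.submat(3, 3, 5, 5) = E;
  X.submat(3, 0, 5, 2) = -E * skew(r);
  return X;
}

static mat66 crm(const vec6& v) {       // motion cross product v x
  mat66 M; M.zeros();
  vec3 w = v.subvec(0, 2), u = v.subvec(3, 5);
  M.submat(0, 0, 2, 2) = skew(w);
  M.submat(3, 3, 5, 5) = skew(w);
  M.submat(3, 0, 5, 2) = skew(u);
  return M;
}

static mat66 crf(const vec6& v) { return -crm(v).t(); }  // force cross v x*

static mat66 spatial_inertia(double m, const vec3& c, const mat33& Ic) {
  mat66 I; I.zeros();
  mat33 C = skew(c);
  I.submat(0, 0, 2, 2) = Ic + m * C * C.t();
  I.submat(0, 3, 2, 5) = m * C;
  I.submat(3, 0, 5, 2) = m * C.t();
  I.submat(3, 3, 5, 5) = m * eye(3, 3);
  return I;
}

// ---------- model parsing --------------------------------------------------

static Model parse_model(const Rcpp::List& ml) {
  Model m;
  Rcpp::IntegerVector parent = ml["parent"], jtype = ml["jtype"];
  Rcpp::NumericMatrix axis = ml["axis"], offset = ml["offset"],
                      com = ml["com"];
  Rcpp::NumericVector mass = ml["mass"];
  Rcpp::List inert = ml["inertia"];
  m.nb = parent.size();
  m.body.resize(m.nb);
  for (int i = 0; i < m.nb; i++) {
    BodyDef& b = m.body[i];
    b.parent = parent[i];
    b.jtype = jtype[i];
    for (int k = 0; k < 3; k++) {
      b.axis(k) = axis(k, i);
      b.offset(k) = offset(k, i);
      b.com(k) = com(k, i);
    }
    b.mass = mass[i];
    Rcpp::NumericMatrix Ic = inert[i];
    for (int r = 0; r < 3; r++)
      for (int c = 0; c < 3; c++) b.Icom(r, c) = Ic(r, c);
  }
  m.left_foot = Rcpp::as<int>(ml["left_foot"]);
  m.right_foot = Rcpp::as<int>(ml["right_foot"]);
  m.pelvis = Rcpp::as<int>(ml["pelvis"]);
  m.cpL = Rcpp::as<mat>(ml["cp_left"]);
  m.cpR = Rcpp::as<mat>(ml["cp_right"]);
  Rcpp::List gains = ml["gains"];
  m.KPD = Rcpp::as<double>(gains["K_PD"]);
  m.DPD = Rcpp::as<double>(gains["D_PD"]);
  m.Kv = Rcpp::as<vec>(gains["K_virtual"]);
  m.Dv = Rcpp::as<vec>(gains["D_virtual"]);
  Rcpp::List gr = ml["ground"];
  m.KG = Rcpp::as<double>(gr["K_G"]);
  m.DG = Rcpp::as<double>(gr["D_G"]);
  m.mus = Rcpp::as<double>(gr["mu_s"]);
  m.mud = Rcpp::as<double>(gr["mu_d"]);
  m.rz0 = Rcpp::as<double>(gr["rz0"]);
  m.vreg = Rcpp::as<double>(gr["friction_reg_speed"]);
  Rcpp::List ps = ml["passive"];
  m.pa = Rcpp::as<vec>(ps["a"]);
  m.pb = Rcpp::as<vec>(ps["b"]);
  m.pc = Rcpp::as<vec>(ps["c"]);
  m.qmin = Rcpp::as<vec>(ps["q_min"]);
  m.qmax = Rcpp::as<vec>(ps["q_max"]);
  m.grav = Rcpp::as<double>(ml["gravity"]);
  m.Isp.resize(m.nb);
  for (int i = 0; i < m.nb; i++)
    m.Isp[i] = spatial_inertia(m.body[i].mass, m.body[i].com,
                               m.body[i].Icom);
  return m;
}

// ---------- kinematics -----------------------------------------------------

// compact parent->child transform: E (coordinate rotation), r (joint
// origin in parent frame)
struct Xf { mat33 E; vec3 r; };

// motion vector, parent coords -> child coords
static inline vec6 xmot(const Xf& X, const vec6& mv) {
  vec3 w = mv.subvec(0, 2), v = mv.subvec(3, 5);
  vec6 out;
  out.subvec(0, 2) = X.E * w;
  out.subvec(3, 5) = X.E * (v - cross(X.r, w));
  return out;
}

// force vector, child coords -> parent coords (X^T f)
static inline vec6 xfrc_up(const Xf& X, const vec6& fv) {
  vec3 n = fv.subvec(0, 2), f = fv.subvec(3, 5);
  vec3 fp = X.E.t() * f;
  vec6 out;
  out.subvec(0, 2) = X.E.t() * n + cross(X.r, fp);
  out.subvec(3, 5) = fp;
  return out;
}

// symmetric spatial inertia, child coords -> parent coords (X^T Ia X)
static inline mat66 xinertia_up(const Xf& X, const mat66& Ia) {
  mat33 A = Ia.submat(0, 0, 2, 2), B = Ia.submat(0, 3, 2, 5),
        C = Ia.submat(3, 3, 5, 5);
  const mat33& E = X.E;
  mat33 At = E.t() * A * E, Bt = E.t() * B * E, Ct = E.t() * C * E;
  mat33 Rh = skew(X.r);
  mat33 TL = At - Bt * Rh + Rh * Bt.t() - Rh * Ct * Rh;
  mat33 TR = Bt + Rh * Ct;
  mat66 out;
  out.submat(0, 0, 2, 2) = TL;
  out.submat(0, 3, 2, 5) = TR;
  out.submat(3, 0, 5, 2) = TR.t();
  out.submat(3, 3, 5, 5) = Ct;
  return out;
}

static inline mat66 xform_full(const Xf& X) { return xform(X.E, X.r); }

static const int NB_MAX = 32;   // fixed workspace bound on body count

struct Kin {
  std::array<Xf, NB_MAX> Xup;      // parent -> body compact transform
  std::array<vec3, NB_MAX> axis;   // joint axis (body coords)
  std::array<int, NB_MAX> jtype;
  std::array<mat33, NB_MAX> R0;    // body -> world rotation
  std::array<vec3, NB_MAX> p0;     // body origin in world
  std::array<vec6, NB_MAX> v;      // spatial velocity, body coords
  vec6 S(int i) const {
    vec6 s; s.zeros();
    if (jtype[i] == 1) s.subvec(0, 2) = axis[i];
    else s.subvec(3, 5) = axis[i];
    return s;
  }
};

static void kinematics(const Model& m, const vec& q, const vec& qd, Kin& K) {
  int nb = m.nb;
  for (int i = 0; i < nb; i++) {
    const BodyDef& b = m.body[i];
    Xf X;
    X.r = b.offset;
    if (b.jtype == 1) {  // revolute: axis fixed under its own rotation
      X.E = rot_axis(b.axis, q(i)).t();
    } else {             // prismatic
      X.E.eye();
      X.r += b.axis * q(i);
    }
    K.Xup[i] = X;
    K.axis[i] = b.axis;
    K.jtype[i] = b.jtype;
    vec6 vJ; vJ.zeros();
    if (b.jtype == 1) vJ.subvec(0, 2) = b.axis * qd(i);
    else vJ.subvec(3, 5) = b.axis * qd(i);
    if (b.parent < 0) {
      K.R0[i] = X.E.t();
      K.p0[i] = X.r;
      K.v[i] = vJ;
    } else {
      K.R0[i] = K.R0[b.parent] * X.E.t();
      K.p0[i] = K.p0[b.parent] + K.R0[b.parent] * X.r;
      K.v[i] = xmot(X, K.v[b.parent]) + vJ;
    }
  }
}

// ---------- contact model --------------------------------------------------

// per-point forces for one foot; returns 3 x ncp world forces, fills wrench
// (spatial force in foot body coords)
static mat foot_contact(const Model& m, const Kin& K, int body, const mat& cp,
                        vec6& wrench, mat* pos_out, mat* vel_out) {
  int ncp = cp.n_cols;
  mat F(3, ncp, fill::zeros);
  const mat33& R = K.R0[body];
  const vec3& p = K.p0[body];
  vec3 w = K.v[body].subvec(0, 2), vl = K.v[body].subvec(3, 5);
  wrench.zeros();
  for (int k = 0; k < ncp; k++) {
    vec3 xl = cp.col(k);
    vec3 pw = p + R * xl;
    vec3 vw = R * (vl + cross(w, xl));
    if (pos_out) pos_out->col(k) = pw;
    if (vel_out) vel_out->col(k) = vw;
    double pen = pw(2) - m.rz0;
    if (pen >= 0) continue;
    double Fv = -m.KG * pen - m.DG * vw(2);
    if (Fv <= 0) continue;
    vec3 fw = {0, 0, Fv};
    double sv = std::sqrt(vw(0) * vw(0) + vw(1) * vw(1));
    if (sv > 1e-12) {
      double mu = m.mud + (m.mus - m.mud) * std::exp(-sv / m.vreg);
      double ramp = (sv < m.vreg) ? sv / m.vreg : 1.0;
      double Fh = mu * Fv * ramp;
      fw(0) = -Fh * vw(0) / sv;
      fw(1) = -Fh * vw(1) / sv;
    }
    F.col(k) = fw;
    vec3 fb = R.t() * fw;
    wrench.subvec(0, 2) += cross(xl, fb);
    wrench.subvec(3, 5) += fb;
  }
  return F;
}

// ---------- generalized forces --------------------------------------------

// active + passive + virtual torque; tau has length nb
static vec control_torque(const Model& m, const vec& q, const vec& qd,
                          const vec& qr, const vec& qrd, bool active) {
  int nb = m.nb;
  vec tau(nb, fill::zeros);
  // virtual balance torque on root Euler coordinates (3,4,5)
  for (int k = 0; k < 3; k++)
    tau(3 + k) = -m.Kv(k) * q(3 + k) - m.Dv(k) * qd(3 + k);
  for (int i = 6; i < nb; i++) {
    int j = i - 6;
    double ta = 0.0;
    if (active)
      ta = m.KPD * (qr(j) - q(i)) + m.DPD * (qrd(j) - qd(i));
    // exponent capped at 10 (linear continuation beyond) so that deep
    // transient overshoots produce strong but finite restoring torque
    double e1 = m.pb(j) * (q(i) - m.qmax(j));
    double e2 = m.pb(j) * (m.qmin(j) - q(i));
    double x1 = (e1 < 10) ? std::exp(e1) : std::exp(10.0) * (1 + e1 - 10);
    double x2 = (e2 < 10) ? std::exp(e2) : std::exp(10.0) * (1 + e2 - 10);
    double tp = -m.pa(j) * x1 + m.pa(j) * x2 - m.pc(j) * qd(i);
    tau(i) = ta + tp;
  }
  return tau;
}

// ---------- ABA forward dynamics -------------------------------------------

static vec aba(const Model& m, const Kin& K, const vec& qd, const vec& tau,
               const std::array<vec6, NB_MAX>& fext) {
  int nb = m.nb;
  std::array<vec6, NB_MAX> c, pA, U;
  std::array<mat66, NB_MAX> IA;
  std::array<double, NB_MAX> d, u;
  for (int i = 0; i < nb; i++) {
    vec3 w = K.v[i].subvec(0, 2), vl = K.v[i].subvec(3, 5);
    vec3 aq = K.axis[i] * qd(i);
    vec6 ci;
    if (K.jtype[i] == 1) {
      ci.subvec(0, 2) = cross(w, aq);
      ci.subvec(3, 5) = cross(vl, aq);
    } else {
      ci.subvec(0, 2).zeros();
      ci.subvec(3, 5) = cross(w, aq);
    }
    c[i] = ci;
    IA[i] = m.Isp[i];
    vec6 Iv = m.Isp[i] * K.v[i];
    vec3 n = Iv.subvec(0, 2), f = Iv.subvec(3, 5);
    vec6 pa;
    pa.subvec(0, 2) = cross(w, n) + cross(vl, f);
    pa.subvec(3, 5) = cross(w, f);
    pA[i] = pa - fext[i];
  }
  for (int i = nb - 1; i >= 0; i--) {
    bool rev = K.jtype[i] == 1;
    U[i] = rev ? vec6(IA[i].cols(0, 2) * K.axis[i])
               : vec6(IA[i].cols(3, 5) * K.axis[i]);
    d[i] = rev ? dot(K.axis[i], U[i].subvec(0, 2))
               : dot(K.axis[i], U[i].subvec(3, 5));
    double Spa = rev ? dot(K.axis[i], pA[i].subvec(0, 2))
                     : dot(K.axis[i], pA[i].subvec(3, 5));
    u[i] = tau(i) - Spa;
    int p = m.body[i].parent;
    if (p >= 0) {
      mat66 Ia = IA[i] - U[i] * U[i].t() / d[i];
      vec6 pa = pA[i] + Ia * c[i] + U[i] * (u[i] / d[i]);
      IA[p] += xinertia_up(K.Xup[i], Ia);
      pA[p] += xfrc_up(K.Xup[i], pa);
    }
  }
  // gravity as base acceleration: a0 = -a_grav = [0 0 0, 0 0 g]
  vec6 agrav; agrav.zeros(); agrav(5) = m.grav;
  std::array<vec6, NB_MAX> a;
  vec qdd(nb);
  for (int i = 0; i < nb; i++) {
    int p = m.body[i].parent;
    vec6 ap = (p < 0) ? vec6(agrav) : a[p];
    vec6 atmp = xmot(K.Xup[i], ap) + c[i];
    qdd(i) = (u[i] - dot(U[i], atmp)) / d[i];
    a[i] = atmp;
    if (K.jtype[i] == 1) a[i].subvec(0, 2) += K.axis[i] * qdd(i);
    else a[i].subvec(3, 5) += K.axis[i] * qdd(i);
  }
  return qdd;
}

// ---------- RNEA (inverse dynamics) & CRBA ---------------------------------

// tau = M qdd + bias - J' fext ; with qdd = 0 this is the Gamma of
// M qdd + Gamma = tau
static vec rnea(const Model& m, const Kin& K, const vec& qd, const vec& qdd,
                const std::vector<vec6>& fext) {
  int nb = m.nb;
  std::vector<vec6> a(nb), f(nb);
  vec6 agrav; agrav.zeros(); agrav(5) = m.grav;
  for (int i = 0; i < nb; i++) {
    int p = m.body[i].parent;
    vec6 S = K.S(i);
    vec6 ap = (p < 0) ? vec6(agrav) : a[p];
    a[i] = xform_full(K.Xup[i]) * ap + S * qdd(i) +
           crm(K.v[i]) * (S * qd(i));
    const mat66& I = m.Isp[i];
    f[i] = I * a[i] + crf(K.v[i]) * (I * K.v[i]) - fext[i];
  }
  vec tau(nb);
  for (int i = nb - 1; i >= 0; i--) {
    tau(i) = dot(K.S(i), f[i]);
    int p = m.body[i].parent;
    if (p >= 0) f[p] += xform_full(K.Xup[i]).t() * f[i];
  }
  return tau;
}

static mat crba(const Model& m, const Kin& K) {
  int nb = m.nb;
  std::vector<mat66> IC(nb);
  for (int i = 0; i < nb; i++) IC[i] = m.Isp[i];
  for (int i = nb - 1; i >= 0; i--) {
    int p = m.body[i].parent;
    if (p >= 0) {
      mat66 X = xform_full(K.Xup[i]);
      IC[p] += X.t() * IC[i] * X;
    }
  }
  mat M(nb, nb, fill::zeros);
  for (int i = 0; i < nb; i++) {
    vec6 F = IC[i] * K.S(i);
    M(i, i) = dot(K.S(i), F);
    int j = i;
    while (m.body[j].parent >= 0) {
      F = xform_full(K.Xup[j]).t() * F;
      j = m.body[j].parent;
      M(i, j) = dot(F, K.S(j));
      M(j, i) = M(i, j);
    }
  }
  return M;
}

// ---------- full derivative evaluation -------------------------------------

struct RefSpline {
  // natural cubic spline per controlled DOF
  vec t, y, y2;   // node times, values, second derivatives
};

static std::vector<RefSpline> parse_ref(const Rcpp::List& ref) {
  int n = ref.size();
  std::vector<RefSpline> out(n);
  for (int j = 0; j < n; j++) {
    Rcpp::List rj = ref[j];
    out[j].t = Rcpp::as<vec>(rj["times"]);
    out[j].y = Rcpp::as<vec>(rj["values"]);
    int m = out[j].t.n_elem;
    vec y2(m, fill::zeros);
    if (m > 2) {
      // tridiagonal solve for natural spline second derivatives
      vec u(m, fill::zeros);
      const vec& x = out[j].t; const vec& y = out[j].y;
      for (int i = 1; i < m - 1; i++) {
        double sig = (x(i) - x(i - 1)) / (x(i + 1) - x(i - 1));
        double pcoef = sig * y2(i - 1) + 2.0;
        y2(i) = (sig - 1.0) / pcoef;
        u(i) = (y(i + 1) - y(i)) / (x(i + 1) - x(i)) -
               (y(i) - y(i - 1)) / (x(i) - x(i - 1));
        u(i) = (6.0 * u(i) / (x(i + 1) - x(i - 1)) - sig * u(i - 1)) / pcoef;
      }
      for (int kk = m - 2; kk >= 1; kk--) y2(kk) = y2(kk) * y2(kk + 1) + u(kk);
      y2(m - 1) = 0; y2(0) = 0;
    }
    out[j].y2 = y2;
  }
  return out;
}

static void spline_eval(const RefSpline& s, double t, double& val,
                        double& deriv) {
  int m = s.t.n_elem;
  if (m == 1) { val = s.y(0); deriv = 0; return; }
  // clamp to span (integrator may poke epsilon outside)
  double tc = std::min(std::max(t, s.t(0)), s.t(m - 1));
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (s.t(mid) > tc) hi = mid; else lo = mid;
  }
  double h = s.t(hi) - s.t(lo);
  double A = (s.t(hi) - tc) / h, B = (tc - s.t(lo)) / h;
  val = A * s.y(lo) + B * s.y(hi) +
        ((A * A * A - A) * s.y2(lo) + (B * B * B - B) * s.y2(hi)) *
            (h * h) / 6.0;
  deriv = (s.y(hi) - s.y(lo)) / h -
          (3 * A * A - 1) / 6.0 * h * s.y2(lo) +
          (3 * B * B - 1) / 6.0 * h * s.y2(hi);
}

// ---------- fast raw-array derivative path ---------------------------------
// The adaptive integrators evaluate the derivative ~1e4-1e6 times per
// simulation; this path re-implements kinematics + contact + control +
// ABA with hand-written 3-vector/3x3 operations on plain doubles (the
// Armadillo-based single-state functions above stay as the reference
// implementation and are cross-checked in the test suite).

namespace fastdyn {

inline void f_cross(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
inline void m3_mul(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}
inline void m3_tmul(const double* A, const double* B, double* C) { // A^T B
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      C[3 * i + j] = A[i] * B[j] + A[3 + i] * B[3 + j] +
                     A[6 + i] * B[6 + j];
}
inline void m3_mul_nt(const double* A, const double* B, double* C) { // A B^T
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      C[3 * i + j] = A[3 * i] * B[3 * j] + A[3 * i + 1] * B[3 * j + 1] +
                     A[3 * i + 2] * B[3 * j + 2];
}
inline void m3v(const double* A, const double* x, double* y) {
  y[0] = A[0] * x[0] + A[1] * x[1] + A[2] * x[2];
  y[1] = A[3] * x[0] + A[4] * x[1] + A[5] * x[2];
  y[2] = A[6] * x[0] + A[7] * x[1] + A[8] * x[2];
}
inline void m3tv(const double* A, const double* x, double* y) {
  y[0] = A[0] * x[0] + A[3] * x[1] + A[6] * x[2];
  y[1] = A[1] * x[0] + A[4] * x[1] + A[7] * x[2];
  y[2] = A[2] * x[0] + A[5] * x[1] + A[8] * x[2];
}
inline void f_skew(const double* v, double* S) {
  S[0] = 0; S[1] = -v[2]; S[2] = v[1];
  S[3] = v[2]; S[4] = 0; S[5] = -v[0];
  S[6] = -v[1]; S[7] = v[0]; S[8] = 0;
}
inline void rot_axis_t(const double* a, double q, double* E) {
  // E = R(a, q)^T : coordinate transform for a rotation by q about a
  double c = std::cos(q), s = std::sin(q), omc = 1 - c;
  double R[9] = {
    c + a[0] * a[0] * omc, a[0] * a[1] * omc - a[2] * s,
    a[0] * a[2] * omc + a[1] * s,
    a[1] * a[0] * omc + a[2] * s, c + a[1] * a[1] * omc,
    a[1] * a[2] * omc - a[0] * s,
    a[2] * a[0] * omc - a[1] * s, a[2] * a[1] * omc + a[0] * s,
    c + a[2] * a[2] * omc};
  // transpose
  E[0] = R[0]; E[1] = R[3]; E[2] = R[6];
  E[3] = R[1]; E[4] = R[4]; E[5] = R[7];
  E[6] = R[2]; E[7] = R[5]; E[8] = R[8];
}

struct WS {
  double E[32][9], r[32][3], R0[32][9], p0[32][3], v[32][6];
  double c[32][6], pA[32][6], U[32][6], IA[32][36];
  double ddi[32], uu[32], a[32][6], fext[32][6];
  double Isp[32][36];
  bool isp_ready = false;
};

// 6-vector helpers: blocks w = x[0..2], l = x[3..5]
inline void xmot6(const double* E, const double* r, const double* x,
                  double* y) {
  double rxw[3], tmp[3];
  m3v(E, x, y);                       // angular
  f_cross(r, x, rxw);
  tmp[0] = x[3] - rxw[0]; tmp[1] = x[4] - rxw[1]; tmp[2] = x[5] - rxw[2];
  m3v(E, tmp, y + 3);
}
inline void xfrc_up6(const double* E, const double* r, const double* f,
                     double* out) {
  double fp[3], n2[3], rxf[3];
  m3tv(E, f + 3, fp);
  m3tv(E, f, n2);
  f_cross(r, fp, rxf);
  out[0] = n2[0] + rxf[0]; out[1] = n2[1] + rxf[1]; out[2] = n2[2] + rxf[2];
  out[3] = fp[0]; out[4] = fp[1]; out[5] = fp[2];
}
// out += X^T Ia X for symmetric Ia (6x6 row-major)
inline void xinertia_up6(const double* E, const double* r, const double* Ia,
                         double* out) {
  double A[9], B[9], C[9];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      A[3 * i + j] = Ia[6 * i + j];
      B[3 * i + j] = Ia[6 * i + j + 3];
      C[3 * i + j] = Ia[6 * (i + 3) + j + 3];
    }
  double T1[9], At[9], Bt[9], Ct[9], Rh[9];
  m3_tmul(E, A, T1); m3_mul(T1, E, At);
  m3_tmul(E, B, T1); m3_mul(T1, E, Bt);
  m3_tmul(E, C, T1); m3_mul(T1, E, Ct);
  f_skew(r, Rh);
  double BtRh[9], RhBtT[9], RhCt[9], RhCtRh[9];
  m3_mul(Bt, Rh, BtRh);
  m3_mul_nt(Rh, Bt, RhBtT);           // Rh * Bt^T
  m3_mul(Rh, Ct, RhCt);
  m3_mul(RhCt, Rh, RhCtRh);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double TL = At[3 * i + j] - BtRh[3 * i + j] + RhBtT[3 * i + j] -
                  RhCtRh[3 * i + j];
      double TR = Bt[3 * i + j] + RhCt[3 * i + j];
      out[6 * i + j] += TL;
      out[6 * i + j + 3] += TR;
      out[6 * (j + 3) + i] += TR;
      out[6 * (i + 3) + j + 3] += Ct[3 * i + j];
    }
}

// full derivative: y = [q; qd] -> dy; returns false on non-finite
static bool deriv_raw(const Model& m, const std::vector<RefSpline>& ref,
                      bool active, double t, const double* y, double* dy,
                      WS& w) {
  int nb = m.nb;
  const double* q = y;
  const double* qd = y + nb;
  if (!w.isp_ready) {
    for (int i = 0; i < nb; i++)
      for (int a2 = 0; a2 < 6; a2++)
        for (int b2 = 0; b2 < 6; b2++)
          w.Isp[i][6 * a2 + b2] = m.Isp[i](a2, b2);
    w.isp_ready = true;
  }
  // ---- kinematics ----
  for (int i = 0; i < nb; i++) {
    const BodyDef& b = m.body[i];
    double ax[3] = {b.axis(0), b.axis(1), b.axis(2)};
    double* E = w.E[i];
    double* r = w.r[i];
    r[0] = b.offset(0); r[1] = b.offset(1); r[2] = b.offset(2);
    if (b.jtype == 1) {
      rot_axis_t(ax, q[i], E);
    } else {
      E[0] = 1; E[1] = 0; E[2] = 0; E[3] = 0; E[4] = 1; E[5] = 0;
      E[6] = 0; E[7] = 0; E[8] = 1;
      r[0] += ax[0] * q[i]; r[1] += ax[1] * q[i]; r[2] += ax[2] * q[i];
    }
    int p = b.parent;
    if (p < 0) {
      // R0 = E^T, p0 = r
      w.R0[i][0] = E[0]; w.R0[i][1] = E[3]; w.R0[i][2] = E[6];
      w.R0[i][3] = E[1]; w.R0[i][4] = E[4]; w.R0[i][5] = E[7];
      w.R0[i][6] = E[2]; w.R0[i][7] = E[5]; w.R0[i][8] = E[8];
      w.p0[i][0] = r[0]; w.p0[i][1] = r[1]; w.p0[i][2] = r[2];
      for (int k = 0; k < 6; k++) w.v[i][k] = 0;
    } else {
      m3_mul_nt(w.R0[p], E, w.R0[i]);
      double tmp[3];
      m3v(w.R0[p], r, tmp);
      w.p0[i][0] = w.p0[p][0] + tmp[0];
      w.p0[i][1] = w.p0[p][1] + tmp[1];
      w.p0[i][2] = w.p0[p][2] + tmp[2];
      xmot6(E, r, w.v[p], w.v[i]);
    }
    if (b.jtype == 1) {
      w.v[i][0] += ax[0] * qd[i]; w.v[i][1] += ax[1] * qd[i];
      w.v[i][2] += ax[2] * qd[i];
    } else {
      w.v[i][3] += ax[0] * qd[i]; w.v[i][4] += ax[1] * qd[i];
      w.v[i][5] += ax[2] * qd[i];
    }
  }
  // ---- contact forces on the feet ----
  for (int i = 0; i < nb; i++)
    for (int k = 0; k < 6; k++) w.fext[i][k] = 0;
  int feet[2] = {m.left_foot, m.right_foot};
  const mat* cps[2] = {&m.cpL, &m.cpR};
  for (int s = 0; s < 2; s++) {
    int bi = feet[s];
    const mat& cp = *cps[s];
    const double* R = w.R0[bi];
    const double* p = w.p0[bi];
    const double* vb = w.v[bi];
    for (unsigned int k = 0; k < cp.n_cols; k++) {
      double xl[3] = {cp(0, k), cp(1, k), cp(2, k)};
      double pw[3], tmp[3], vw[3], wxl[3];
      m3v(R, xl, pw);
      pw[0] += p[0]; pw[1] += p[1]; pw[2] += p[2];
      double pen = pw[2] - m.rz0;
      if (pen >= 0) continue;
      f_cross(vb, xl, wxl);
      tmp[0] = vb[3] + wxl[0]; tmp[1] = vb[4] + wxl[1];
      tmp[2] = vb[5] + wxl[2];
      m3v(R, tmp, vw);
      double Fv = -m.KG * pen - m.DG * vw[2];
      if (Fv <= 0) continue;
      double fw[3] = {0, 0, Fv};
      double sv = std::sqrt(vw[0] * vw[0] + vw[1] * vw[1]);
      if (sv > 1e-12) {
        double mu = m.mud + (m.mus - m.mud) * std::exp(-sv / m.vreg);
        double ramp = (sv < m.vreg) ? sv / m.vreg : 1.0;
        double Fh = mu * Fv * ramp;
        fw[0] = -Fh * vw[0] / sv;
        fw[1] = -Fh * vw[1] / sv;
      }
      double fb[3], nb2[3];
      m3tv(R, fw, fb);
      f_cross(xl, fb, nb2);
      w.fext[bi][0] += nb2[0]; w.fext[bi][1] += nb2[1];
      w.fext[bi][2] += nb2[2];
      w.fext[bi][3] += fb[0]; w.fext[bi][4] += fb[1];
      w.fext[bi][5] += fb[2];
    }
  }
  // ---- generalized torques ----
  double tau[32];
  for (int k = 0; k < 3; k++) tau[k] = 0;
  for (int k = 0; k < 3; k++)
    tau[3 + k] = -m.Kv(k) * q[3 + k] - m.Dv(k) * qd[3 + k];
  for (int i = 6; i < nb; i++) {
    int j = i - 6;
    double ta = 0;
    if (active) {
      double qr, qrd;
      spline_eval(ref[j], t, qr, qrd);
      ta = m.KPD * (qr - q[i]) + m.DPD * (qrd - qd[i]);
    }
    double e1 = m.pb(j) * (q[i] - m.qmax(j));
    double e2 = m.pb(j) * (m.qmin(j) - q[i]);
    double x1 = (e1 < 10) ? std::exp(e1) : std::exp(10.0) * (1 + e1 - 10);
    double x2 = (e2 < 10) ? std::exp(e2) : std::exp(10.0) * (1 + e2 - 10);
    tau[i] = ta - m.pa(j) * x1 + m.pa(j) * x2 - m.pc(j) * qd[i];
  }
  // ---- ABA ----
  for (int i = 0; i < nb; i++) {
    const double* vi = w.v[i];
    const BodyDef& b = m.body[i];
    double aq[3] = {b.axis(0) * qd[i], b.axis(1) * qd[i],
                    b.axis(2) * qd[i]};
    double* ci = w.c[i];
    if (b.jtype == 1) {
      f_cross(vi, aq, ci);
      f_cross(vi + 3, aq, ci + 3);
    } else {
      ci[0] = ci[1] = ci[2] = 0;
      f_cross(vi, aq, ci + 3);
    }
    for (int k = 0; k < 36; k++) w.IA[i][k] = w.Isp[i][k];
    double Iv[6];
    for (int a2 = 0; a2 < 6; a2++) {
      Iv[a2] = 0;
      for (int b2 = 0; b2 < 6; b2++) Iv[a2] += w.Isp[i][6 * a2 + b2] * vi[b2];
    }
    double t1[3], t2[3], t3[3];
    f_cross(vi, Iv, t1);
    f_cross(vi + 3, Iv + 3, t2);
    f_cross(vi, Iv + 3, t3);
    w.pA[i][0] = t1[0] + t2[0] - w.fext[i][0];
    w.pA[i][1] = t1[1] + t2[1] - w.fext[i][1];
    w.pA[i][2] = t1[2] + t2[2] - w.fext[i][2];
    w.pA[i][3] = t3[0] - w.fext[i][3];
    w.pA[i][4] = t3[1] - w.fext[i][4];
    w.pA[i][5] = t3[2] - w.fext[i][5];
  }
  for (int i = nb - 1; i >= 0; i--) {
    const BodyDef& b = m.body[i];
    double ax[3] = {b.axis(0), b.axis(1), b.axis(2)};
    int off = (b.jtype == 1) ? 0 : 3;
    double* U = w.U[i];
    for (int a2 = 0; a2 < 6; a2++)
      U[a2] = w.IA[i][6 * a2 + off] * ax[0] +
              w.IA[i][6 * a2 + off + 1] * ax[1] +
              w.IA[i][6 * a2 + off + 2] * ax[2];
    double d = U[off] * ax[0] + U[off + 1] * ax[1] + U[off + 2] * ax[2];
    double Spa = w.pA[i][off] * ax[0] + w.pA[i][off + 1] * ax[1] +
                 w.pA[i][off + 2] * ax[2];
    w.ddi[i] = d;
    w.uu[i] = tau[i] - Spa;
    int p = b.parent;
    if (p >= 0) {
      double Ia[36];
      for (int a2 = 0; a2 < 6; a2++)
        for (int b2 = 0; b2 < 6; b2++)
          Ia[6 * a2 + b2] = w.IA[i][6 * a2 + b2] - U[a2] * U[b2] / d;
      double pa[6];
      for (int a2 = 0; a2 < 6; a2++) {
        double s = w.pA[i][a2] + U[a2] * (w.uu[i] / d);
        for (int b2 = 0; b2 < 6; b2++) s += Ia[6 * a2 + b2] * w.c[i][b2];
        pa[a2] = s;
      }
      xinertia_up6(w.E[i], w.r[i], Ia, w.IA[p]);
      double fup[6];
      xfrc_up6(w.E[i], w.r[i], pa, fup);
      for (int k = 0; k < 6; k++) w.pA[p][k] += fup[k];
    }
  }
  bool finite = true;
  for (int i = 0; i < nb; i++) {
    int p = m.body[i].parent;
    double ap[6];
    if (p < 0) { ap[0] = ap[1] = ap[2] = ap[3] = ap[4] = 0; ap[5] = m.grav; }
    else for (int k = 0; k < 6; k++) ap[k] = w.a[p][k];
    double at[6];
    xmot6(w.E[i], w.r[i], ap, at);
    for (int k = 0; k < 6; k++) at[k] += w.c[i][k];
    double Ua = 0;
    for (int k = 0; k < 6; k++) Ua += w.U[i][k] * at[k];
    double qdd = (w.uu[i] - Ua) / w.ddi[i];
    const BodyDef& b = m.body[i];
    int off = (b.jtype == 1) ? 0 : 3;
    for (int k = 0; k < 6; k++) w.a[i][k] = at[k];
    w.a[i][off] += b.axis(0) * qdd;
    w.a[i][off + 1] += b.axis(1) * qdd;
    w.a[i][off + 2] += b.axis(2) * qdd;
    dy[i] = qd[i];
    dy[nb + i] = qdd;
    if (!std::isfinite(qdd)) finite = false;
  }
  return finite;
}

}  // namespace fastdyn

struct DerivCtx {
  const Model* m;
  const std::vector<RefSpline>* ref;
  bool active;
  long nfev = 0;
  fastdyn::WS ws;
};

// y = [q; qd], length 2*nb
static vec deriv(DerivCtx& ctx, double t, const vec& y) {
  const Model& m = *ctx.m;
  int nb = m.nb;
  vec dy(2 * nb);
  fastdyn::deriv_raw(m, *ctx.ref, ctx.active, t, y.memptr(), dy.memptr(),
                     ctx.ws);
  ctx.nfev++;
  return dy;
}

// quaternion (w,x,y,z) from rotation matrix
static vec4 quat_from_R(const mat33& R) {
  vec4 q;
  double tr = R(0, 0) + R(1, 1) + R(2, 2);
  if (tr > 0) {
    double s = std::sqrt(tr + 1) * 2;
    q = {0.25 * s, (R(2, 1) - R(1, 2)) / s, (R(0, 2) - R(2, 0)) / s,
         (R(1, 0) - R(0, 1)) / s};
  } else if (R(0, 0) > R(1, 1) && R(0, 0) > R(2, 2)) {
    double s = std::sqrt(1 + R(0, 0) - R(1, 1) - R(2, 2)) * 2;
    q = {(R(2, 1) - R(1, 2)) / s, 0.25 * s, (R(0, 1) + R(1, 0)) / s,
         (R(0, 2) + R(2, 0)) / s};
  } else if (R(1, 1) > R(2, 2)) {
    double s = std::sqrt(1 + R(1, 1) - R(0, 0) - R(2, 2)) * 2;
    q = {(R(0, 2) - R(2, 0)) / s, (R(0, 1) + R(1, 0)) / s, 0.25 * s,
         (R(1, 2) + R(2, 1)) / s};
  } else {
    double s = std::sqrt(1 + R(2, 2) - R(0, 0) - R(1, 1)) * 2;
    q = {(R(1, 0) - R(0, 1)) / s, (R(0, 2) + R(2, 0)) / s,
         (R(1, 2) + R(2, 1)) / s, 0.25 * s};
  }
  return normalise(q);
}

// per-body orientation series: quaternions (scalar-first, global frame)
// and intrinsic X-Y-Z Euler angles
// [[Rcpp::export]]
Rcpp::List cpp_orient_series(Rcpp::List model, arma::mat Q,
                             arma::ivec bodies) {
  Model m = parse_model(model);
  int T = Q.n_cols, ns = bodies.n_elem;
  cube quat(4, T, ns), eul(3, T, ns);
  vec qd(m.nb, fill::zeros);
  Kin K;
  for (int s = 0; s < T; s++) {
    kinematics(m, Q.col(s), qd, K);
    for (int j = 0; j < ns; j++) {
      const mat33& R = K.R0[bodies(j)];
      quat.slice(j).col(s) = quat_from_R(R);
      double th = std::asin(std::max(-1.0, std::min(1.0, R(0, 2))));
      eul(0, s, j) = std::atan2(-R(1, 2), R(2, 2));
      eul(1, s, j) = th;
      eul(2, s, j) = std::atan2(-R(0, 1), R(0, 0));
    }
  }
  return Rcpp::List::create(Rcpp::Named("quat") = quat,
                            Rcpp::Named("euler") = eul);
}

// [[Rcpp::export]]
arma::vec cpp_deriv_bench(Rcpp::List model, Rcpp::List ref, arma::vec y,
                          double t, int n) {
  Model m = parse_model(model);
  std::vector<RefSpline> rs = parse_ref(ref);
  DerivCtx ctx{&m, &rs, true, 0};
  vec out;
  for (int i = 0; i < n; i++) out = deriv(ctx, t, y);
  return out;
}

// ---------- exported: single-state evaluations ------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_fk(Rcpp::List model, arma::vec q) {
  Model m = parse_model(model);
  vec qd(m.nb, fill::zeros);
  Kin K;
  kinematics(m, q, qd, K);
  cube R(3, 3, m.nb);
  mat p(3, m.nb);
  for (int i = 0; i < m.nb; i++) { R.slice(i) = K.R0[i]; p.col(i) = K.p0[i]; }
  return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("p") = p);
}

// [[Rcpp::export]]
Rcpp::List cpp_contact(Rcpp::List model, arma::vec q, arma::vec qd) {
  Model m = parse_model(model);
  Kin K;
  kinematics(m, q, qd, K);
  vec6 wl, wr;
  mat posL(3, m.cpL.n_cols), velL(3, m.cpL.n_cols);
  mat posR(3, m.cpR.n_cols), velR(3, m.cpR.n_cols);
  mat FL = foot_contact(m, K, m.left_foot, m.cpL, wl, &posL, &velL);
  mat FR = foot_contact(m, K, m.right_foot, m.cpR, wr, &posR, &velR);
  vec3 tot = sum(FL, 1) + sum(FR, 1);
  return Rcpp::List::create(
      Rcpp::Named("F_left") = FL, Rcpp::Named("F_right") = FR,
      Rcpp::Named("pos_left") = posL, Rcpp::Named("pos_right") = posR,
      Rcpp::Named("vel_left") = velL, Rcpp::Named("vel_right") = velR,
      Rcpp::Named("total") = tot);
}

// [[Rcpp::export]]
Rcpp::List cpp_eom(Rcpp::List model, arma::vec q, arma::vec qd,
                   bool include_external = true) {
  Model m = parse_model(model);
  Kin K;
  kinematics(m, q, qd, K);
  std::vector<vec6> fext(m.nb, vec6(fill::zeros));
  vec gamma_ext(m.nb, fill::zeros);
  if (include_external) {
    vec6 wl, wr;
    foot_contact(m, K, m.left_foot, m.cpL, wl, nullptr, nullptr);
    foot_contact(m, K, m.right_foot, m.cpR, wr, nullptr, nullptr);
    fext[m.left_foot] = wl;
    fext[m.right_foot] = wr;
    // virtual torque treated as an external generalized force inside Gamma
    for (int k = 0; k < 3; k++)
      gamma_ext(3 + k) = m.Kv(k) * q(3 + k) + m.Dv(k) * qd(3 + k);
  }
  mat M = crba(m, K);
  vec zero(m.nb, fill::zeros);
  vec Gamma = rnea(m, K, qd, zero, fext) + gamma_ext;
  return Rcpp::List::create(Rcpp::Named("M") = M, Rcpp::Named("Gamma") = Gamma);
}

// [[Rcpp::export]]
arma::vec cpp_qdd(Rcpp::List model, arma::vec q, arma::vec qd, arma::vec tau,
                  bool include_contact = true, bool include_virtual = true) {
  Model m = parse_model(model);
  Kin K;
  kinematics(m, q, qd, K);
  std::array<vec6, NB_MAX> fext;
  for (int i = 0; i < m.nb; i++) fext[i].zeros();
  if (include_contact) {
    vec6 wl, wr;
    foot_contact(m, K, m.left_foot, m.cpL, wl, nullptr, nullptr);
    foot_contact(m, K, m.right_foot, m.cpR, wr, nullptr, nullptr);
    fext[m.left_foot] = wl;
    fext[m.right_foot] = wr;
  }
  vec tau_full = tau;
  if (include_virtual)
    for (int k = 0; k < 3; k++)
      tau_full(3 + k) += -m.Kv(k) * q(3 + k) - m.Dv(k) * qd(3 + k);
  return aba(m, K, qd, tau_full, fext);
}

// classical kinematics of a body-fixed point over a trajectory
// [[Rcpp::export]]
Rcpp::List cpp_point_kin(Rcpp::List model, arma::mat Q, arma::mat Qd,
                         arma::mat Qdd, int body, arma::vec point) {
  Model m = parse_model(model);
  int T = Q.n_cols, nb = m.nb;
  mat pos(3, T), vel(3, T), acc(3, T), omw(3, T), omb(3, T);
  cube R(3, 3, T);
  vec3 xl = point;
  for (int s = 0; s < T; s++) {
    vec q = Q.col(s), qd = Qd.col(s), qdd = Qdd.col(s);
    Kin K;
    kinematics(m, q, qd, K);
    // true spatial accelerations (a0 = 0; gravity lives in qdd)
    std::vector<vec6> a(nb);
    for (int i = 0; i < nb; i++) {
      int p = m.body[i].parent;
      vec6 ap = (p < 0) ? vec6(fill::zeros) : a[p];
      vec6 S = K.S(i);
      a[i] = xmot(K.Xup[i], ap) + S * qdd(i) +
             crm(K.v[i]) * (S * qd(i));
    }
    const mat33& Rb = K.R0[body];
    vec3 w = K.v[body].subvec(0, 2), vl = K.v[body].subvec(3, 5);
    vec3 al = a[body].subvec(0, 2), av = a[body].subvec(3, 5);
    pos.col(s) = K.p0[body] + Rb * xl;
    vel.col(s) = Rb * (vl + cross(w, xl));
    acc.col(s) = Rb * (av + cross(al, xl) + cross(w, vl + cross(w, xl)));
    omw.col(s) = Rb * w;
    omb.col(s) = w;
    R.slice(s) = Rb;
  }
  return Rcpp::List::create(
      Rcpp::Named("pos") = pos, Rcpp::Named("vel") = vel,
      Rcpp::Named("acc") = acc, Rcpp::Named("R") = R,
      Rcpp::Named("omega_world") = omw, Rcpp::Named("omega_body") = omb);
}

// [[Rcpp::export]]
Rcpp::List cpp_spline_eval(arma::vec times, arma::vec values,
                           arma::vec tq) {
  RefSpline s;
  s.t = times; s.y = values;
  Rcpp::List holder = Rcpp::List::create(
      Rcpp::List::create(Rcpp::Named("times") = times,
                         Rcpp::Named("values") = values));
  std::vector<RefSpline> v = parse_ref(holder);
  vec val(tq.n_elem), der(tq.n_elem);
  for (size_t i = 0; i < tq.n_elem; i++)
    spline_eval(v[0], tq(i), val(i), der(i));
  return Rcpp::List::create(Rcpp::Named("value") = val,
                            Rcpp::Named("deriv") = der);
}

// ---------- integrators -----------------------------------------------------

struct SimOpts {
  double rtol, atol, hmax, hmin, qlim_slack;
  long max_steps;
  int method;   // 0 = rk45, 1 = trbdf2
  double out_hz;
  bool active;
};

static double err_norm(const vec& e, const vec& y, const vec& ynew,
                       double rtol, double atol) {
  double s = 0;
  int n = e.n_elem;
  for (int i = 0; i < n; i++) {
    double sc = atol + rtol * std::max(std::fabs(y(i)), std::fabs(ynew(i)));
    double r = e(i) / sc;
    s += r * r;
  }
  return std::sqrt(s / n);
}

static bool limits_ok(const Model& m, const vec& y, double slack) {
  for (int i = 6; i < m.nb; i++) {
    int j = i - 6;
    if (y(i) > m.qmax(j) + slack || y(i) < m.qmin(j) - slack) return false;
  }
  return y.is_finite();
}

// Dormand-Prince 5(4)
static const double DP_c[7] = {0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1, 1};
static const double DP_a[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
    {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
    {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
    {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656,
     0},
    {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double DP_e[7] = {
    35.0 / 384 - 5179.0 / 57600, 0, 500.0 / 1113 - 7571.0 / 16695,
    125.0 / 192 - 393.0 / 640, -2187.0 / 6784 + 92097.0 / 339200,
    11.0 / 84 - 187.0 / 2100, -1.0 / 40};

// integrate from t to t_target, updating y; returns false on failure
static bool rk45_advance(DerivCtx& ctx, const SimOpts& o, double& t,
                         double t_target, vec& y, double& h, long& nsteps,
                         std::string& msg) {
  const Model& m = *ctx.m;
  int n = y.n_elem;
  std::vector<vec> k(7, vec(n));
  k[0] = deriv(ctx, t, y);
  while (t < t_target - 1e-12) {
    if (nsteps++ > o.max_steps) { msg = "max step count exceeded"; return false; }
    h = std::min(h, t_target - t);
    vec ytmp(n);
    for (int s = 1; s < 7; s++) {
      ytmp = y;
      for (int j = 0; j < s; j++)
        if (DP_a[s][j] != 0) ytmp += h * DP_a[s][j] * k[j];
      k[s] = deriv(ctx, t + DP_c[s] * h, ytmp);
    }
    vec ynew = ytmp;   // stage 7 state is the 5th-order solution (FSAL)
    vec e(n, fill::zeros);
    for (int s = 0; s < 7; s++) e += h * DP_e[s] * k[s];
    double err = err_norm(e, y, ynew, o.rtol, o.atol);
    if (err <= 1.0 && ynew.is_finite()) {
      t += h;
      y = ynew;
      k[0] = k[6];   // FSAL
      if (!limits_ok(m, y, o.qlim_slack)) {
        msg = "joint limit exceeded at t=" + std::to_string(t);
        return false;
      }
      h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(err, 1e-10),
                                                      -0.2)));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
      if (!std::isfinite(err)) h *= 0.1;
      k[0] = deriv(ctx, t, y);
    }
    h = std::min(h, o.hmax);
    if (h < o.hmin) { msg = "step size underflow at t=" + std::to_string(t);
      return false; }
  }
  return true;
}

// TR-BDF2 (L-stable, 2nd order, lazy-Jacobian modified Newton)
struct TRBDF2State {
  mat J;        // df/dy
  mat L, U;     // LU of (I - d h J) via arma::lu
  uvec piv_dummy;
  mat W;        // factorized via solve each time (small system: use arma)
  double h_fact = -1;
  bool have_J = false;
};

static mat num_jac(DerivCtx& ctx, double t, const vec& y, const vec& f0) {
  int n = y.n_elem;
  mat J(n, n);
  vec yp = y;
  for (int j = 0; j < n; j++) {
    double dy = 1e-7 * std::max(1.0, std::fabs(y(j)));
    yp(j) = y(j) + dy;
    vec f1 = deriv(ctx, t, yp);
    J.col(j) = (f1 - f0) / dy;
    yp(j) = y(j);
  }
  return J;
}

static bool newton_solve(DerivCtx& ctx, const mat& Wfac_L, const mat& Wfac_U,
                         const mat& P, double t, double dh, const vec& rhs,
                         vec& z, vec& fz, double tolsc, int& iters) {
  // solve z = rhs + dh * f(t, z); modified Newton with a (possibly stale)
  // factorized iteration matrix — bail out early on slow contraction
  double prev = datum::inf;
  for (iters = 0; iters < 14; iters++) {
    fz = deriv(ctx, t, z);
    vec g = rhs + dh * fz - z;
    vec dz = solve(trimatu(Wfac_U),
                   solve(trimatl(Wfac_L), vec(P * g)));
    z += dz;
    double nrm = norm(dz, 2) / std::sqrt((double)z.n_elem);
    if (nrm < tolsc) { fz = deriv(ctx, t, z); return true; }
    if (iters >= 3 && nrm > 0.9 * prev) return false;
    prev = nrm;
  }
  return false;
}

static bool trbdf2_advance(DerivCtx& ctx, const SimOpts& o, double& t,
                           double t_target, vec& y, double& h, long& nsteps,
                           std::string& msg, TRBDF2State& st) {
  const Model& m = *ctx.m;
  int n = y.n_elem;
  const double gam = 2.0 - std::sqrt(2.0);
  const double d = gam / 2.0;
  const double a1 = -(1.0 - gam) * (1.0 - gam) / (gam * (2.0 - gam));
  const double a2 = 1.0 / (gam * (2.0 - gam));
  // embedded 3rd-order quadrature weights minus method weights
  const double b2 = 1.0 / (6.0 * gam * (1.0 - gam));
  const double b3 = 0.5 - b2 * gam;
  const double b1 = 1.0 - b2 - b3;
  const double w12 = std::sqrt(2.0) / 4.0, w3 = d;
  const double e1 = b1 - w12, e2 = b2 - w12, e3 = b3 - w3;

  vec f0 = deriv(ctx, t, y);
  mat Lm, Um, P;
  bool fact_ok = false;
  int jac_age = 1000;
  double h_fact = -1;

  auto refactor = [&](double hh) {
    mat W = eye(n, n) - d * hh * st.J;
    fact_ok = lu(Lm, Um, P, W);
    if (fact_ok) {
      vec ad = abs(Um.diag());
      if (ad.min() < 1e-13 * ad.max())
        fact_ok = false;   // numerically singular (e.g. gimbal lock)
    }
    h_fact = hh;
  };

  while (t < t_target - 1e-12) {
    if (nsteps++ > o.max_steps) { msg = "max step count exceeded"; return false; }
    h = std::min(h, std::min(o.hmax, t_target - t));
    if (!st.have_J || jac_age > 200) {
      st.J = num_jac(ctx, t, y, f0);
      st.have_J = true;
      jac_age = 0;
      refactor(h);
    } else if (std::fabs(h - h_fact) > 0.05 * h_fact || !fact_ok) {
      refactor(h);
    }
    if (!fact_ok) { msg = "Jacobian factorization failed"; return false; }

    double tolsc = 0.3 * (o.atol + o.rtol * norm(y, "inf"));
    // stage 1: trapezoid to t + gam*h
    vec rhs1 = y + d * h * f0;
    vec z = y + gam * h * f0;   // predictor
    vec fz;
    int it1;
    bool ok1 = newton_solve(ctx, Lm, Um, P, t + gam * h, d * h, rhs1, z, fz,
                            tolsc, it1);
    bool ok2 = false;
    vec ynew, fnew;
    int it2 = 0;
    if (ok1) {
      // stage 2: BDF2 to t + h
      vec rhs2 = a1 * y + a2 * z;
      ynew = z + (1.0 - gam) * h * fz;   // predictor
      fnew = f0;
      ok2 = newton_solve(ctx, Lm, Um, P, t + h, d * h, rhs2, ynew, fnew,
                         tolsc, it2);
    }
    if (!(ok1 && ok2)) {
      // refresh Jacobian if stale, else shrink step
      if (jac_age > 0) {
        st.J = num_jac(ctx, t, y, f0);
        jac_age = 0;
        refactor(h);
      } else {
        h *= 0.3;
        refactor(h);
        if (h < o.hmin) { msg = "step size underflow (Newton) at t=" +
          std::to_string(t); return false; }
      }
      continue;
    }
    jac_age++;
    vec est = h * (e1 * f0 + e2 * fz + e3 * fnew);
    // stiffly filter the error estimate through W^-1
    vec estf = solve(trimatu(Um), solve(trimatl(Lm), vec(P * est)));
    double err = err_norm(estf, y, ynew, o.rtol, o.atol);
    if (err <= 1.0 && ynew.is_finite()) {
      t += h;
      y = ynew;
      f0 = fnew;
      if (!limits_ok(m, y, o.qlim_slack)) {
        msg = "joint limit exceeded at t=" + std::to_string(t);
        return false;
      }
      double fac = std::min(3.0, std::max(0.3,
          0.85 * std::pow(std::max(err, 1e-10), -1.0 / 3.0)));
      h *= fac;
    } else {
      h *= std::max(0.1, 0.85 * std::pow(std::max(err, 1e-10), -1.0 / 3.0));
      if (!std::isfinite(err)) h *= 0.1;
      if (h < o.hmin) { msg = "step size underflow at t=" +
        std::to_string(t); return false; }
    }
  }
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(Rcpp::List model, Rcpp::List ref, arma::vec q0,
                        arma::vec qd0, double t0, double t1, double out_hz,
                        std::string method, double rtol, double atol,
                        double hmax, double hmin, double max_steps,
                        bool active_control) {
  Model m = parse_model(model);
  std::vector<RefSpline> rs = parse_ref(ref);
  DerivCtx ctx{&m, &rs, active_control, 0};
  SimOpts o;
  o.rtol = rtol; o.atol = atol; o.hmax = hmax; o.hmin = hmin;
  o.qlim_slack = 1.0;
  o.max_steps = (long)max_steps;
  o.method = (method == "trbdf2") ? 1 : 0;
  o.active = active_control;

  int nb = m.nb;
  int T = (int)std::round((t1 - t0) * out_hz) + 1;
  vec tout = linspace(t0, t0 + (T - 1) / out_hz, T);
  mat Q(nb, T), Qd(nb, T), Qdd(nb, T), GRF(3, T);
  vec y(2 * nb);
  y.subvec(0, nb - 1) = q0;
  y.subvec(nb, 2 * nb - 1) = qd0;

  double t = t0, h = std::min(1e-4, o.hmax);
  long nsteps = 0;
  std::string msg = "ok";
  bool ok = true;
  TRBDF2State st;
  int done = 0;
  for (int s = 0; s < T; s++) {
    if (s > 0) {
      if (o.method == 0)
        ok = rk45_advance(ctx, o, t, tout(s), y, h, nsteps, msg);
      else
        ok = trbdf2_advance(ctx, o, t, tout(s), y, h, nsteps, msg, st);
      if (!ok) break;
    }
    vec q = y.subvec(0, nb - 1), qd = y.subvec(nb, 2 * nb - 1);
    vec dy = deriv(ctx, tout(s), y);
    Q.col(s) = q;
    Qd.col(s) = qd;
    Qdd.col(s) = dy.subvec(nb, 2 * nb - 1);
    Kin K;
    kinematics(m, q, qd, K);
    vec6 wl, wr;
    mat FL = foot_contact(m, K, m.left_foot, m.cpL, wl, nullptr, nullptr);
    mat FR = foot_contact(m, K, m.right_foot, m.cpR, wr, nullptr, nullptr);
    GRF.col(s) = sum(FL, 1) + sum(FR, 1);
    done = s;
  }
  return Rcpp::List::create(
      Rcpp::Named("ok") = ok, Rcpp::Named("message") = msg,
      Rcpp::Named("time") = tout.subvec(0, done),
      Rcpp::Named("q") = Q.cols(0, done), Rcpp::Named("qd") = Qd.cols(0, done),
      Rcpp::Named("qdd") = Qdd.cols(0, done),
      Rcpp::Named("grf") = GRF.cols(0, done),
      Rcpp::Named("nsteps") = (double)nsteps,
      Rcpp::Named("nfev") = (double)ctx.nfev,
      Rcpp::Named("t_end") = t);
}
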