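// Compiled kernels for the PS-OCT simulator and reconstruction.
//
// Conventions (shared with the R level, see R/polarimetry.R):
//  - Stokes vectors s = (q, u, v); retarders act as proper rotations on them.
//  - q = (|h|^2-|v|^2)/I, u = 2 Re(conj(h) v)/I, v = -2 Im(conj(h) v)/I.
//  - The SU(2) half-angle lift U(n, phi) = cos(phi/2) I + i sin(phi/2) (n . sigma)
//    with sigma1 = diag(1,-1), sigma2 = [[0,1],[1,0]], sigma3 = [[0,i],[-i,0]]
//    satisfies stokes(U E) = R(n, phi) stokes(E) for the convention above.
//  - D-transpose: dT(A) = D A^T D with D = diag(1,1,-1).

#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

// ---------- 3x3 real matrices (row-major) ----------

struct M3 {
  double a[9];
};

static inline M3 m3_identity() {
  M3 m = {{1, 0, 0, 0, 1, 0, 0, 0, 1}};
  return m;
}

static inline M3 m3_mul(const M3 &A, const M3 &B) {
  M3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A.a[3 * i + k] * B.a[3 * k + j];
      C.a[3 * i + j] = s;
    }
  return C;
}

static inline M3 m3_t(const M3 &A) {
  M3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) C.a[3 * i + j] = A.a[3 * j + i];
  return C;
}

// dT(A) = D A^T D: transpose, then flip sign of entries with exactly one
// index equal to the third axis.
static inline M3 m3_dtranspose(const M3 &A) {
  M3 C = m3_t(A);
  C.a[2] = -C.a[2];
  C.a[5] = -C.a[5];
  C.a[6] = -C.a[6];
  C.a[7] = -C.a[7];
  return C;
}

// Rodrigues rotation about unit axis n by angle phi.
static inline M3 m3_axis_angle(double n1, double n2, double n3, double phi) {
  double c = std::cos(phi), s = std::sin(phi), t = 1.0 - c;
  M3 m;
  m.a[0] = c + n1 * n1 * t;
  m.a[1] = n1 * n2 * t - n3 * s;
  m.a[2] = n1 * n3 * t + n2 * s;
  m.a[3] = n2 * n1 * t + n3 * s;
  m.a[4] = c + n2 * n2 * t;
  m.a[5] = n2 * n3 * t - n1 * s;
  m.a[6] = n3 * n1 * t - n2 * s;
  m.a[7] = n3 * n2 * t + n1 * s;
  m.a[8] = c + n3 * n3 * t;
  return m;
}

// Axis-angle log of a rotation. Returns angle in [0, pi]; axis has the
// documented tie-break (first nonzero component positive) at angle ~pi,
// and defaults to (1,0,0) at angle ~0.
static inline void m3_log(const M3 &R, double axis[3], double *angle) {
  double tr = R.a[0] + R.a[4] + R.a[8];
  double carg = (tr - 1.0) / 2.0;
  if (carg > 1.0) carg = 1.0;
  if (carg < -1.0) carg = -1.0;
  double phi = std::acos(carg);
  *angle = phi;
  if (phi < 1e-12) {
    axis[0] = 1.0; axis[1] = 0.0; axis[2] = 0.0;
    return;
  }
  if (phi < M_PI - 1e-6) {
    double s2 = 2.0 * std::sin(phi);
    axis[0] = (R.a[7] - R.a[5]) / s2;
    axis[1] = (R.a[2] - R.a[6]) / s2;
    axis[2] = (R.a[3] - R.a[1]) / s2;
    double nn = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
    axis[0] /= nn; axis[1] /= nn; axis[2] /= nn;
    return;
  }
  // near pi: R ~ 2 n n^T - I
  double n1 = std::sqrt(std::max(0.0, (R.a[0] + 1.0) / 2.0));
  double n2 = std::sqrt(std::max(0.0, (R.a[4] + 1.0) / 2.0));
  double n3 = std::sqrt(std::max(0.0, (R.a[8] + 1.0) / 2.0));
  // fix relative signs from off-diagonal symmetric parts
  if (n1 >= n2 && n1 >= n3) {
    n2 = std::copysign(n2, R.a[1] + R.a[3]);
    n3 = std::copysign(n3, R.a[2] + R.a[6]);
  } else if (n2 >= n1 && n2 >= n3) {
    n1 = std::copysign(n1, R.a[1] + R.a[3]);
    n3 = std::copysign(n3, R.a[5] + R.a[7]);
  } else {
    n1 = std::copysign(n1, R.a[2] + R.a[6]);
    n2 = std::copysign(n2, R.a[5] + R.a[7]);
  }
  double nn = std::sqrt(n1 * n1 + n2 * n2 + n3 * n3);
  n1 /= nn; n2 /= nn; n3 /= nn;
  // tie-break: first nonzero component positive
  double first = (std::fabs(n1) > 1e-9) ? n1 : ((std::fabs(n2) > 1e-9) ? n2 : n3);
  if (first < 0) { n1 = -n1; n2 = -n2; n3 = -n3; }
  axis[0] = n1; axis[1] = n2; axis[2] = n3;
}

// ---------- 2x2 complex (SU(2)) ----------

struct U2 {
  cd a, b, c, d;  // [[a, b], [c, d]]
};

static inline U2 u2_identity() {
  U2 u; u.a = 1; u.b = 0; u.c = 0; u.d = 1; return u;
}

static inline U2 u2_mul(const U2 &X, const U2 &Y) {
  U2 Z;
  Z.a = X.a * Y.a + X.b * Y.c;
  Z.b = X.a * Y.b + X.b * Y.d;
  Z.c = X.c * Y.a + X.d * Y.c;
  Z.d = X.c * Y.b + X.d * Y.d;
  return Z;
}

// Half-angle lift of the rotation by phi about unit Poincare axis n.
static inline U2 u2_lift(double n1, double n2, double n3, double phi) {
  double ch = std::cos(phi / 2.0), sh = std::sin(phi / 2.0);
  U2 u;
  u.a = cd(ch, sh * n1);
  u.b = cd(-sh * n3, sh * n2);
  u.c = cd(sh * n3, sh * n2);
  u.d = cd(ch, -sh * n1);
  return u;
}

// ---------- exported kernels ----------

// Simulate detected complex fields for one block of A-lines.
//
// ret:  [nz, nA] single-pass retardance of the layer at each depth pixel (rad)
// az2:  [nz, nA] Poincare azimuth (= 2 * retarder orientation) of each layer (rad)
// psi:  [nA] catheter/system transmission rotation angle about the circular axis (rad)
// amp:  [nz, nA] field amplitude (class reflectivity x attenuation)
// gre/gim: [nz, nA] shared complex speckle factor (unit variance), 1/0 when disabled
// nhre/nhim/nvre/nvim: [nz, nA] additive detector noise per channel
// state_b: [nA] TRUE when the A-line uses input state 2 (u-axis), FALSE for state 1 (q-axis)
//
// Returns list(Eh, Ev): complex [nz, nA] matrices.
// [[Rcpp::export]]
List cpp_simulate_fields(NumericMatrix ret, NumericMatrix az2, NumericVector psi,
                         NumericMatrix amp, NumericMatrix gre, NumericMatrix gim,
                         NumericMatrix nhre, NumericMatrix nhim,
                         NumericMatrix nvre, NumericMatrix nvim,
                         LogicalVector state_b) {
  int nz = ret.nrow(), nA = ret.ncol();
  ComplexMatrix Eh(nz, nA), Ev(nz, nA);
  const double isq2 = 1.0 / std::sqrt(2.0);
  for (int j = 0; j < nA; ++j) {
    U2 uT = u2_lift(0, 0, 1, psi[j]);
    U2 uTd = u2_lift(0, 0, 1, -psi[j]);  // lift of dT(T) = R_v(-psi)
    cd e1, e2;
    if (state_b[j]) { e1 = isq2; e2 = isq2; } else { e1 = 1.0; e2 = 0.0; }
    U2 up = u2_identity(), ur = u2_identity();
    for (int z = 0; z < nz; ++z) {
      double d = ret(z, j);
      if (d != 0.0) {
        double a2 = az2(z, j);
        U2 ul = u2_lift(std::cos(a2), std::sin(a2), 0.0, d);
        up = u2_mul(up, ul);
        ur = u2_mul(ul, ur);
      }
      U2 uc = u2_mul(up, ur);                 // round trip C(z)
      U2 um = u2_mul(uTd, u2_mul(uc, uT));    // dT(T) C(z) T
      cd g(gre(z, j), gim(z, j));
      cd fh = amp(z, j) * g * (um.a * e1 + um.b * e2) + cd(nhre(z, j), nhim(z, j));
      cd fv = amp(z, j) * g * (um.c * e1 + um.d * e2) + cd(nvre(z, j), nvim(z, j));
      Eh(z, j) = Rcomplex{fh.real(), fh.imag()};
      Ev(z, j) = Rcomplex{fv.real(), fv.imag()};
    }
  }
  return List::create(Named("Eh") = Eh, Named("Ev") = Ev);
}

static inline M3 m3_from_slice(const NumericVector &C, int z) {
  // C has dim [3, 3, nz], column-major: entry (i, j, z) at i + 3*j + 9*z
  M3 m;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) m.a[3 * i + j] = C[i + 3 * j + 9 * z];
  return m;
}

// Depth-resolved layer peeling for one A-line.
//
// C: numeric array dim [3, 3, nz] of cumulative (compensated) rotations.
// valid: [nz] logical.
// Returns list(delta = per-pixel local double-pass retardance / 2 (rad, i.e. the
// single-pass layer retardance rate per pixel), az2 = Poincare azimuth of the
// local axis before halving (rad, NA where undefined), ok = logical.
// [[Rcpp::export]]
List cpp_peel(NumericVector C, LogicalVector valid) {
  IntegerVector dim = C.attr("dim");
  int nz = dim[2];
  NumericVector delta(nz, NA_REAL), az2(nz, NA_REAL);
  LogicalVector ok(nz);
  M3 P = m3_identity();
  M3 Cprev = m3_identity();
  int span = 1;
  for (int z = 0; z < nz; ++z) {
    if (!valid[z]) {
      ok[z] = false;
      span += 1;  // P carried forward; next valid N spans the gap
      continue;
    }
    M3 Cz = m3_from_slice(C, z);
    M3 N = m3_mul(Cz, m3_t(Cprev));
    double axis[3], phi;
    m3_log(N, axis, &phi);
    if (phi < 1e-11) {
      delta[z] = 0.0;
      ok[z] = true;
      Cprev = Cz;
      span = 1;
      continue;
    }
    // local axis in the sample frame: P^{-1} applied to axis of N
    M3 Pt = m3_t(P);
    double m1 = Pt.a[0] * axis[0] + Pt.a[1] * axis[1] + Pt.a[2] * axis[2];
    double m2 = Pt.a[3] * axis[0] + Pt.a[4] * axis[1] + Pt.a[5] * axis[2];
    double eq = std::sqrt(m1 * m1 + m2 * m2);
    if (eq < 1e-9) {
      // axis (numerically) circular: orientation undefined, carry P forward
      delta[z] = phi / 2.0 / span;
      ok[z] = false;
      Cprev = Cz;
      span = 1;
      continue;
    }
    double a2 = std::atan2(m2 / eq, m1 / eq);
    delta[z] = phi / 2.0 / span;  // per-pixel rate across any masked gap
    az2[z] = a2;
    ok[z] = true;
    // rebuild the one-way product with the equator-projected local retarder
    M3 L = m3_axis_angle(std::cos(a2), std::sin(a2), 0.0, phi / 2.0);
    P = m3_mul(P, L);
    Cprev = Cz;
    span = 1;
  }
  return List::create(Named("delta") = delta, Named("az2") = az2, Named("ok") = ok);
}

static inline M3 m3_from_vpar(const NumericVector &vpar) {
  double n = std::sqrt(vpar[0] * vpar[0] + vpar[1] * vpar[1] + vpar[2] * vpar[2]);
  if (n < 1e-14) return m3_identity();
  return m3_axis_angle(vpar[0] / n, vpar[1] / n, vpar[2] / n, n);
}

// Summed squared Frobenius D-transpose asymmetry of
// Chat(z) = dT(V)^{-1} C(z) V^{-1} over valid depths.
// dT(V)^{-1} = D V D and V^{-1} = V^T for V in SO(3).
// [[Rcpp::export]]
double cpp_asym_cost(NumericVector C, LogicalVector valid, NumericVector vpar) {
  IntegerVector dim = C.attr("dim");
  int nz = dim[2];
  M3 V = m3_from_vpar(vpar);
  M3 Vt = m3_t(V);
  M3 DVD = V;
  DVD.a[2] = -DVD.a[2]; DVD.a[5] = -DVD.a[5];
  DVD.a[6] = -DVD.a[6]; DVD.a[7] = -DVD.a[7];
  double cost = 0.0;
  for (int z = 0; z < nz; ++z) {
    if (!valid[z]) continue;
    M3 Cz = m3_from_slice(C, z);
    M3 Ch = m3_mul(DVD, m3_mul(Cz, Vt));
    M3 A = m3_dtranspose(Ch);
    for (int k = 0; k < 9; ++k) {
      double d = A.a[k] - Ch.a[k];
      cost += d * d;
    }
  }
  return cost;
}

// Apply the compensation Chat(z) = dT(V)^{-1} C(z) V^{-1} to a [3,3,nz] stack.
// [[Rcpp::export]]
NumericVector cpp_apply_compensation(NumericVector C, NumericVector vpar) {
  IntegerVector dim = C.attr("dim");
  int nz = dim[2];
  M3 V = m3_from_vpar(vpar);
  M3 Vt = m3_t(V);
  M3 DVD = V;
  DVD.a[2] = -DVD.a[2]; DVD.a[5] = -DVD.a[5];
  DVD.a[6] = -DVD.a[6]; DVD.a[7] = -DVD.a[7];
  NumericVector out(C.size());
  out.attr("dim") = dim;
  for (int z = 0; z < nz; ++z) {
    M3 Cz = m3_from_slice(C, z);
    M3 Ch = m3_mul(DVD, m3_mul(Cz, Vt));
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) out[i + 3 * j + 9 * z] = Ch.a[3 * i + j];
  }
  return out;
}

// Mean Frobenius asymmetry norm per depth of a [3,3,nz] stack over valid depths.
// [[Rcpp::export]]
double cpp_mean_asymmetry(NumericVector C, LogicalVector valid) {
  IntegerVector dim = C.attr("dim");
  int nz = dim[2];
  double s = 0.0;
  int n = 0;
  for (int z = 0; z < nz; ++z) {
    if (!valid[z]) continue;
    M3 Cz = m3_from_slice(C, z);
    M3 A = m3_dtranspose(Cz);
    double f = 0.0;
    for (int k = 0; k < 9; ++k) {
      double d = A.a[k] - Cz.a[k];
      f += d * d;
    }
    s += std::sqrt(f);
    n += 1;
  }
  return n > 0 ? s / n : 0.0;
}

// Rotation angle (rad, in [0, pi]) of every slice of a [3,3,nz] stack.
// [[Rcpp::export]]
NumericVector cpp_rotation_angles(NumericVector C) {
  IntegerVector dim = C.attr("dim");
  int nz = dim[2];
  NumericVector out(nz);
  for (int z = 0; z < nz; ++z) {
    M3 Cz = m3_from_slice(C, z);
    double axis[3], phi;
    m3_log(Cz, axis, &phi);
    out[z] = phi;
  }
  return out;
}
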