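// Planar double-inverted-pendulum occupant surrogate on a decelerating base.
//
// Generalised coordinates are the absolute sagittal angles of the two links
// (pelvis->T1, T1->head CG) from vertical, forward positive. Each joint
// carries a passive spring-damper about the initial pose, a feedforward
// torque balancing gravity at the initial pose, and a delayed, saturated
// proportional-derivative active torque (the postural controller). The base
// acceleration enters as a forward pseudo-force during braking. Integration
// is fixed-step semi-implicit Euler, which is bit-reproducible and stable
// for the stiff spring-dampers used here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct State {
  double L1, L2, th1_0, th2_0, m1, m2;
  double k1, c1, k2, c2, kp1, kd1, kp2, kd2, tmax1, tmax2;
  int d1, d2;  // delays in whole steps (lumbar, neck)
  // forward hard stops: belt restraint on the torso joint, soft tissue /
  // chin stop on the neck joint (engage angle, stiffness, damping)
  double be1, bk1, bc1, be2, bk2, bc2;
};

const double G = 9.81;

State unpack(const NumericVector& s) {
  State st;
  st.L1 = s[0];  st.L2 = s[1];  st.th1_0 = s[2]; st.th2_0 = s[3];
  st.m1 = s[4];  st.m2 = s[5];
  st.k1 = s[6];  st.c1 = s[7];  st.k2 = s[8];  st.c2 = s[9];
  st.kp1 = s[10]; st.kd1 = s[11]; st.kp2 = s[12]; st.kd2 = s[13];
  st.tmax1 = s[14]; st.tmax2 = s[15];
  st.d1 = (int)std::lround(s[16]); st.d2 = (int)std::lround(s[17]);
  st.be1 = s[18]; st.bk1 = s[19]; st.bc1 = s[20];
  st.be2 = s[21]; st.bk2 = s[22]; st.bc2 = s[23];
  return st;
}

inline double clampt(double x, double lim) {
  if (x > lim) return lim;
  if (x < -lim) return -lim;
  return x;
}

// integrate one run; traj (if non-null) receives per-step displacements
// [head_x, head_z_down, t1_x, t1_z_down] in mm relative to t = 0.
// returns false on instability (non-finite state or |angle| > 2.5 rad).
bool integrate(const State& st, const NumericVector& pulse, double dt,
               NumericMatrix* traj,
               std::vector<double>* hx, std::vector<double>* hz,
               std::vector<double>* tx, std::vector<double>* tz) {
  const int n = pulse.size();
  double th1 = st.th1_0, th2 = st.th2_0, v1 = 0.0, v2 = 0.0;
  const double phi0 = st.th2_0 - st.th1_0;
  // feedforward gravity balance at the initial pose
  const double g2 = G * st.m2 * st.L2 * std::sin(st.th2_0);
  const double g1 = G * (st.m1 + st.m2) * st.L1 * std::sin(st.th1_0);
  const double ff2 = -g2;
  const double ff1 = -g1 + ff2;
  const int dmax = std::max(st.d1, st.d2);
  std::vector<double> h1(n + 1, st.th1_0), h2(n + 1, st.th2_0),
      hv1(n + 1, 0.0), hv2(n + 1, 0.0);
  const double hx0 = st.L1 * std::sin(st.th1_0) + st.L2 * std::sin(st.th2_0);
  const double hz0 = st.L1 * std::cos(st.th1_0) + st.L2 * std::cos(st.th2_0);
  const double tx0 = st.L1 * std::sin(st.th1_0);
  const double tz0 = st.L1 * std::cos(st.th1_0);
  for (int i = 0; i < n; ++i) {
    // delayed states (pre-history = initial rest pose)
    const int j1 = i - st.d1, j2 = i - st.d2;
    const double th1d = (j1 >= 0) ? h1[j1] : st.th1_0;
    const double v1d = (j1 >= 0) ? hv1[j1] : 0.0;
    const double th2d = (j2 >= 0) ? h2[j2] : st.th2_0;
    const double v2d = (j2 >= 0) ? hv2[j2] : 0.0;
    const double phi = th2 - th1, phid = th2d - th1d;
    const double dphi = v2 - v1, dphid = v2d - v1d;
    // joint torques: feedforward + passive + delayed saturated PD
    const double tau1 = ff1 - st.k1 * (th1 - st.th1_0) - st.c1 * v1 -
        clampt(st.kp1 * (th1d - st.th1_0) + st.kd1 * v1d, st.tmax1);
    double tau2 = ff2 - st.k2 * (phi - phi0) - st.c2 * dphi -
        clampt(st.kp2 * (phid - phi0) + st.kd2 * dphid, st.tmax2);
    // one-sided forward hard stops (belt on torso, chin/tissue on neck)
    double tau1b = tau1;
    const double ex1 = (th1 - st.th1_0) - st.be1;
    if (ex1 > 0.0) tau1b -= st.bk1 * ex1 + st.bc1 * std::max(v1, 0.0);
    const double ex2 = (phi - phi0) - st.be2;
    if (ex2 > 0.0) tau2 -= st.bk2 * ex2 + st.bc2 * std::max(dphi, 0.0);
    const double a = pulse[i];
    const double s1 = std::sin(th1), c1_ = std::cos(th1);
    const double s2 = std::sin(th2), c2_ = std::cos(th2);
    const double sd = std::sin(th1 - th2);
    const double M11 = (st.m1 + st.m2) * st.L1 * st.L1;
    const double M12 = st.m2 * st.L1 * st.L2 * std::cos(th1 - th2);
    const double M22 = st.m2 * st.L2 * st.L2;
    const double Q1 = G * (st.m1 + st.m2) * st.L1 * s1 +
        (st.m1 + st.m2) * a * st.L1 * c1_ + tau1b - tau2 -
        st.m2 * st.L1 * st.L2 * sd * v2 * v2;
    const double Q2 = G * st.m2 * st.L2 * s2 + st.m2 * a * st.L2 * c2_ +
        tau2 + st.m2 * st.L1 * st.L2 * sd * v1 * v1;
    const double det = M11 * M22 - M12 * M12;
    const double a1 = (M22 * Q1 - M12 * Q2) / det;
    const double a2 = (M11 * Q2 - M12 * Q1) / det;
    v1 += a1 * dt; v2 += a2 * dt;
    th1 += v1 * dt; th2 += v2 * dt;
    if (!std::isfinite(th1) || !std::isfinite(th2) ||
        std::fabs(th1) > 2.5 || std::fabs(th2) > 2.5)
      return false;
    h1[i + 1] = th1; h2[i + 1] = th2; hv1[i + 1] = v1; hv2[i + 1] = v2;
    const double hx_m = st.L1 * std::sin(th1) + st.L2 * std::sin(th2);
    const double hz_m = st.L1 * std::cos(th1) + st.L2 * std::cos(th2);
    const double tx_m = st.L1 * std::sin(th1);
    const double tz_m = st.L1 * std::cos(th1);
    // vehicle frame: x forward, z downward
    const double vals[4] = {(hx_m - hx0) * 1000.0, -(hz_m - hz0) * 1000.0,
                            (tx_m - tx0) * 1000.0, -(tz_m - tz0) * 1000.0};
    if (traj)
      for (int k = 0; k < 4; ++k) (*traj)(i + 1, k) = vals[k];
    if (hx) {
      (*hx)[i + 1] = vals[0]; (*hz)[i + 1] = vals[1];
      (*tx)[i + 1] = vals[2]; (*tz)[i + 1] = vals[3];
    }
  }
  (void)dmax;
  return true;
}

// first interior local maximum with the given prominence inside
// [i_lo, i_hi]; falls back to the window maximum.
double first_peak(const std::vector<double>& x, int i_lo, int i_hi,
                  double prominence) {
  for (int i = i_lo + 1; i < i_hi; ++i) {
    if (!(x[i] >= x[i - 1] && x[i] > x[i + 1])) continue;
    double minL = x[i];
    for (int j = i - 1; j >= i_lo; --j) {
      if (x[j] > x[i]) break;
      if (x[j] < minL) minL = x[j];
    }
    double minR = x[i];
    for (int j = i + 1; j <= i_hi; ++j) {
      if (x[j] > x[i]) break;
      if (x[j] < minR) minR = x[j];
    }
    const double prom = x[i] - std::max(minL, minR);
    if (prom >= prominence) return x[i];
  }
  double mx = x[i_lo];
  for (int i = i_lo + 1; i <= i_hi; ++i) mx = std::max(mx, x[i]);
  return mx;
}

double trapz_mean(const std::vector<double>& x, int i_lo, int i_hi) {
  double s = 0.0;
  for (int i = i_lo; i < i_hi; ++i) s += 0.5 * (x[i] + x[i + 1]);
  return s / (i_hi - i_lo);
}

}  // namespace

// [[Rcpp::export(name = ".sim_traj_cpp")]]
NumericMatrix sim_traj_cpp(NumericVector state, NumericVector pulse,
                           double dt) {
  const State st = unpack(state);
  NumericMatrix traj(pulse.size() + 1, 4);
  colnames(traj) = CharacterVector::create("head_x_mm", "head_z_mm",
                                           "t1_x_mm", "t1_z_mm");
  if (!integrate(st, pulse, dt, &traj, nullptr, nullptr, nullptr, nullptr))
    stop("occupant simulation unstable");
  return traj;
}

// [[Rcpp::export(name = ".sim_metrics_cpp")]]
NumericMatrix sim_metrics_cpp(NumericMatrix states, NumericVector pulse,
                              double dt, double peak_lo, double peak_hi,
                              double avg_hi, double prominence) {
  const int nrun = states.nrow();
  const int n = pulse.size();
  NumericMatrix out(nrun, 4);
  colnames(out) = CharacterVector::create("head_peak_fwd_mm", "t1_peak_fwd_mm",
                                          "head_avg_vert_mm", "t1_avg_vert_mm");
  const int i_lo = std::max(0, (int)std::lround(peak_lo / dt));
  const int i_hi = std::min(n, (int)std::lround(peak_hi / dt));
  const int i_avg = std::min(n, (int)std::lround(avg_hi / dt));
  std::vector<double> hx(n + 1, 0.0), hz(n + 1, 0.0), tx(n + 1, 0.0),
      tz(n + 1, 0.0);
  for (int r = 0; r < nrun; ++r) {
    const State st = unpack(states(r, _));
    std::fill(hx.begin(), hx.end(), 0.0);
    std::fill(hz.begin(), hz.end(), 0.0);
    std::fill(tx.begin(), tx.end(), 0.0);
    std::fill(tz.begin(), tz.end(), 0.0);
    if (!integrate(st, pulse, dt, nullptr, &hx, &hz, &tx, &tz))
      stop("occupant simulation unstable at run %d", r + 1);
    out(r, 0) = first_peak(hx, i_lo, i_hi, prominence);
    out(r, 1) = first_peak(tx, i_lo, i_hi, prominence);
    out(r, 2) = trapz_mean(hz, 0, i_avg);
    out(r, 3) = trapz_mean(tz, 0, i_avg);
  }
  return out;
}
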