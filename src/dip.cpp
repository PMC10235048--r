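#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hartigan's dip statistic computed from its definition: the smallest d such
// that some unimodal CDF G (convex below the mode, concave above it, with an
// atom allowed at the mode) stays within sup-distance d of the empirical
// CDF; d is located by bisection.
//
// Band constraints at the j-th distinct value (cumulative count C_j of n):
//   lower  lo_j = C_j / n - d      (the CDF value after the jump)
//   upper  hi_j = C_{j-1} / n + d  (the left limit before the jump)
//
// Convex side machinery. For a convex nondecreasing function g through
// vertical bands at v_0 < ... < v_{J-1}, a left-to-right closure gives the
// forced floor f_j of g(v_j): every pair i < j yields the ray
//   g(t) >= f_j + (f_j - hi_i) / (v_j - v_i) * (t - v_j),   t >= v_j,
// because g's slope past v_j is at least the chord slope from (v_i, g_i),
// with g_i <= hi_i and g_j >= f_j. The floors are exact: when f_j <= hi_j
// for all j, the upper envelope of all rays (plus flat rays, g >= 0) is
// itself a feasible convex selection attaining every floor, so prefix
// feasibility, minimal values and minimal extension values past the prefix
// all come from the same pass. The concave side reuses the pass through the
// reflection x -> -x, z -> 1 - z. The two sides couple across the mode:
// with the mode in the gap (v_s, v_{s+1}), the fit exists iff the convex
// side's minimal extension to v_{s+1} stays below the concave side's
// maximal start there, or the convex side's minimal end stays below the
// concave side's maximal extension back to v_s (slopes across the modal gap
// must interleave, which reduces to this pair of conditions at the gap's
// endpoints). A mode placed at a data point assigns the point's jump to the
// concave side and relaxes its upper bound to C_t/n + d.

static const double EPS = 1e-11;

struct SidePass {
  std::vector<char> feas;    // feas[s]: bands 0..s-1 admit a convex function
  std::vector<double> f;     // forced floor at each point
  std::vector<double> smax;  // steepest forced ray slope out of each point
};

static SidePass side_pass(const std::vector<double>& v,
                          const std::vector<double>& lo,
                          const std::vector<double>& hi) {
  int J = (int)v.size();
  SidePass out;
  out.feas.assign(J + 1, 0);
  out.f.assign(J, 0.0);
  out.smax.assign(J, 0.0);
  out.feas[0] = 1;
  bool ok = true;
  for (int j = 0; j < J; ++j) {
    double fj = std::max(lo[j], 0.0);
    for (int k = 0; k < j; ++k) {
      fj = std::max(fj, out.f[k]);
      fj = std::max(fj, out.f[k] + out.smax[k] * (v[j] - v[k]));
    }
    out.f[j] = fj;
    double s = 0.0;
    for (int i = 0; i < j; ++i)
      s = std::max(s, (fj - hi[i]) / (v[j] - v[i]));
    out.smax[j] = s;
    ok = ok && (fj <= hi[j] + EPS);
    out.feas[j + 1] = ok;
  }
  return out;
}

// Minimal extension value at t of a convex selection through the first s
// bands (t beyond v_{s-1}).
static double side_ext(const SidePass& sp, const std::vector<double>& v,
                       int s, double t) {
  double e = 0.0;
  for (int k = 0; k < s; ++k) {
    e = std::max(e, sp.f[k]);
    e = std::max(e, sp.f[k] + sp.smax[k] * (t - v[k]));
  }
  return e;
}

static bool unimodal_feasible(const std::vector<double>& v,
                              const std::vector<double>& C,
                              double n, double d) {
  int J = (int)v.size();
  std::vector<double> lo(J), hi(J);
  for (int j = 0; j < J; ++j) {
    double Cprev = (j == 0) ? 0.0 : C[j - 1];
    lo[j] = C[j] / n - d;
    hi[j] = std::min(Cprev / n + d, 1.0);
  }
  SidePass pre = side_pass(v, lo, hi);
  if (pre.feas[J]) return true; // mode above the largest value
  // reflection for the concave side
  std::vector<double> vr(J), lor(J), hir(J);
  for (int j = 0; j < J; ++j) {
    int r = J - 1 - j;
    vr[j] = -v[r];
    lor[j] = 1.0 - hi[r];
    hir[j] = 1.0 - lo[r];
  }
  SidePass suf = side_pass(vr, lor, hir);
  if (suf.feas[J]) return true; // mode below the smallest value

  // suffix t..J (1-based t) is the reflected prefix of length J - t + 1
  // gap-mode splits between v_s and v_{s+1} (1-based s)
  for (int s = 1; s <= J - 1; ++s) {
    if (!pre.feas[s]) break;
    if (!suf.feas[J - s]) continue;
    // minimal convex extension to v_{s+1} vs maximal concave start there
    double e_conv = side_ext(pre, v, s, v[s]);
    double z_max = 1.0 - suf.f[J - s - 1];
    if (e_conv <= z_max + EPS) return true;
    // minimal convex end at v_s vs maximal concave extension back to v_s
    double y_min = pre.f[s - 1];
    double e_conc = 1.0 - side_ext(suf, vr, J - s, -v[s - 1]);
    if (y_min <= e_conc + EPS) return true;
  }
  // mode at a data point v_t (1-based): the jump joins the concave side,
  // whose band at v_t relaxes to [lo_t, C_t/n + d]
  for (int t = 1; t <= J; ++t) {
    if (!pre.feas[t - 1]) break;
    if (t < J && !suf.feas[J - t]) continue;
    double z_cap = std::min(C[t - 1] / n + d, 1.0);
    if (t < J)
      z_cap = std::min(z_cap, 1.0 - side_ext(suf, vr, J - t, -v[t - 1]));
    if (lo[t - 1] > z_cap + EPS) continue;
    // left limit at v_t: minimal convex extension must fit under both the
    // left-limit band and the concave side's value
    double w_floor = (t >= 2) ? side_ext(pre, v, t - 1, v[t - 1]) : 0.0;
    if (w_floor <= std::min(hi[t - 1], z_cap) + EPS) return true;
  }
  return false;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector values, NumericVector counts, double tol) {
  int J = values.size();
  if (J == 0) return 0.0;
  std::vector<double> C(J);
  double acc = 0;
  for (int j = 0; j < J; ++j) { acc += counts[j]; C[j] = acc; }
  double n = acc;
  if (J == 1) return 0.5 / n;
  std::vector<double> v(values.begin(), values.end());
  double dlo = 0.5 / n, dhi = 0.25;
  if (unimodal_feasible(v, C, n, dlo + 1e-12)) return dlo;
  while (dhi - dlo > tol) {
    double mid = 0.5 * (dlo + dhi);
    if (unimodal_feasible(v, C, n, mid)) dhi = mid; else dlo = mid;
  }
  return 0.5 * (dlo + dhi);
}
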