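#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dip statistic via a band formulation of unimodal (convex-then-concave)
// CDF fitting. Inputs: u = sorted unique values, c = empirical CDF at u
// (cumulative fractions, last element 1). For each candidate modal atom k
// the greatest convex minorant of the upper band on the left and the least
// concave majorant of the lower band on the right are built incrementally;
// the dip is half the smallest achievable worst-case band violation.
//
// [[Rcpp::export]]
double dip_stat_cpp(NumericVector u, NumericVector c) {
  int m = u.size();
  if (m < 2) return 0.0;
  std::vector<double> c0(m);           // c_{j-1}: CDF just below u_j
  for (int j = 0; j < m; ++j) c0[j] = (j == 0) ? 0.0 : c[j - 1];
  std::vector<double> dl(m, 0.0), dr(m, 0.0);

  // left side: lower convex hull of (u_j, c0_j) over the prefix 1..k;
  // violation is how far the lower band c_j pokes above the hull
  {
    std::vector<int> hull;
    for (int k = 0; k < m; ++k) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cross = (u[b] - u[a]) * (c0[k] - c0[a]) -
                       (u[k] - u[a]) * (c0[b] - c0[a]);
        if (cross <= 0) hull.pop_back(); else break;
      }
      hull.push_back(k);
      double v = 0.0;
      int t = 0;
      for (int j = 0; j < k; ++j) {
        while (t + 1 < (int)hull.size() && hull[t + 1] <= j) ++t;
        double hv;
        if (hull[t] == j) {
          hv = c0[j];
        } else {
          int a = hull[t], b = hull[t + 1];
          hv = c0[a] + (c0[b] - c0[a]) * (u[j] - u[a]) / (u[b] - u[a]);
        }
        double viol = c[j] - hv;
        if (viol > v) v = viol;
      }
      dl[k] = v / 2.0;
    }
  }

  // right side: upper concave hull of (u_j, c_j) over the suffix k..m;
  // violation is how far the hull pokes above the upper band c0_j
  {
    std::vector<int> hull;  // indices stored in decreasing order
    for (int k = m - 1; k >= 0; --k) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        double cross = (u[b] - u[a]) * (c[k] - c[a]) -
                       (u[k] - u[a]) * (c[b] - c[a]);
        if (cross <= 0) hull.pop_back(); else break;
      }
      hull.push_back(k);
      double v = 0.0;
      int t = 0;
      for (int j = m - 1; j > k; --j) {
        while (t + 1 < (int)hull.size() && hull[t + 1] >= j) ++t;
        double hv;
        if (hull[t] == j) {
          hv = c[j];
        } else {
          int a = hull[t], b = hull[t + 1];
          hv = c[a] + (c[b] - c[a]) * (u[j] - u[a]) / (u[b] - u[a]);
        }
        double viol = hv - c0[j];
        if (viol > v) v = viol;
      }
      dr[k] = v / 2.0;
    }
  }

  double dip = R_PosInf;
  for (int k = 0; k < m; ++k) {
    double d = dl[k] > dr[k] ? dl[k] : dr[k];
    if (d < dip) dip = d;
  }
  return dip;
}
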