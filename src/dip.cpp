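#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic.
//
// For an empirical cdf F_n with distinct sorted values v_1..v_m and
// cumulative proportions F_i, the dip is
//
//   dip = (1/2) * min_k max( gapL(k), gapR(k) )
//
// where, for a candidate mode at v_k,
//   gapL(k) = sup_{x <= v_k} ( F_n(x) - gcm(x) ),   gcm = greatest convex
//             minorant of F_n on (-inf, v_k]  (an atom at the mode is
//             allowed, so the minorant is constrained by the left limits
//             F_{i-1} at each v_i),
//   gapR(k) = sup_{x >= v_k} ( lcm(x) - F_n(x) ),   lcm = least concave
//             majorant of F_n on [v_k, inf), constrained by F_i at v_i.
// Halving the worst one-sided band gap is exactly the sup-norm distance to
// the nearest unimodal cdf with mode at v_k (shift the hull by half the
// gap); minimising over candidate modes gives the dip. Modes between data
// points are never better than modes at data points.

static double cross(double x0, double y0, double x1, double y1,
                    double x2, double y2) {
  return (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector v, NumericVector Fcum) {
  const int m = v.size();
  if (m <= 1) return 0.0;
  std::vector<double> Flo(m);       // left limits F_{i-1}
  Flo[0] = 0.0;
  for (int i = 1; i < m; ++i) Flo[i] = Fcum[i - 1];

  // gapL[k]: lower convex hull of (v_i, Flo_i), i = 0..k, evaluated under
  // each interior point; deviation measured against F_i there.
  std::vector<double> gapL(m, 0.0), gapR(m, 0.0);
  {
    std::vector<int> hull;
    std::vector<double> segmax;     // max deviation under hull edge ending at hull[j]
    hull.reserve(m); segmax.reserve(m);
    for (int k = 0; k < m; ++k) {
      // grow hull with point k
      while (hull.size() >= 2) {
        int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
        if (cross(v[a], Flo[a], v[b], Flo[b], v[k], Flo[k]) <= 0.0) {
          hull.pop_back(); segmax.pop_back();
        } else break;
      }
      // deviation of interior points under the new edge (hull.back(), k)
      double mx = 0.0;
      if (!hull.empty()) {
        int a = hull.back();
        double slope = (v[k] > v[a]) ? (Flo[k] - Flo[a]) / (v[k] - v[a]) : 0.0;
        for (int j = a; j < k; ++j) {
          double hy = Flo[a] + slope * (v[j] - v[a]);
          double dev = Fcum[j] - hy;
          if (dev > mx) mx = dev;
        }
      }
      hull.push_back(k); segmax.push_back(mx);
      // gapL(k) = max over all edges currently on the hull
      double g = 0.0;
      for (double s : segmax) if (s > g) g = s;
      gapL[k] = g;
    }
  }
  // gapR[k]: mirror image, scanning from the right with the upper concave
  // hull of (v_i, Fcum_i); deviation measured against left limits Flo_i.
  {
    std::vector<int> hull;
    std::vector<double> segmax;
    hull.reserve(m); segmax.reserve(m);
    for (int k = m - 1; k >= 0; --k) {
      while (hull.size() >= 2) {
        int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
        // scanning right-to-left along an upper hull
        if (cross(v[a], Fcum[a], v[b], Fcum[b], v[k], Fcum[k]) <= 0.0) {
          hull.pop_back(); segmax.pop_back();
        } else break;
      }
      double mx = 0.0;
      if (!hull.empty()) {
        int a = hull.back();               // a > k
        double slope = (v[a] > v[k]) ? (Fcum[a] - Fcum[k]) / (v[a] - v[k]) : 0.0;
        for (int j = k + 1; j <= a; ++j) {
          double hy = Fcum[k] + slope * (v[j] - v[k]);
          double dev = hy - Flo[j];
          if (dev > mx) mx = dev;
        }
      }
      hull.push_back(k); segmax.push_back(mx);
      double g = 0.0;
      for (double s : segmax) if (s > g) g = s;
      gapR[k] = g;
    }
  }
  double best = R_PosInf;
  for (int k = 0; k < m; ++k) {
    double e = std::max(gapL[k], gapR[k]);
    if (e < best) best = e;
  }
  return 0.5 * best;
}

// Reversal ("zigzag") extrema filter on a possibly gappy series.
// d, t: values and times at the non-missing samples, in time order.
// Emits strictly alternating minima/maxima such that consecutive extrema
// differ by more than min_change; first and last samples are eligible
// boundary extrema. Returns indices (1-based) into the input, with +1 for
// maxima and -1 for minima encoded in `type`.
// [[Rcpp::export]]
List zigzag_cpp(NumericVector d, double min_change) {
  const int n = d.size();
  std::vector<int> idx; std::vector<int> typ;
  if (n >= 3) {
    int dir = 0;                    // 0 unknown, +1 seeking max, -1 seeking min
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (dir == 0) {
        if (d[i] > d[imax]) imax = i;
        if (d[i] < d[imin]) imin = i;
        if (d[i] - d[imin] > min_change) {      // rose: first extremum is a min
          idx.push_back(imin); typ.push_back(-1);
          dir = +1; imax = i;
        } else if (d[imax] - d[i] > min_change) { // fell: first extremum is a max
          idx.push_back(imax); typ.push_back(+1);
          dir = -1; imin = i;
        }
      } else if (dir > 0) {
        if (d[i] > d[imax]) imax = i;
        else if (d[imax] - d[i] > min_change) {
          idx.push_back(imax); typ.push_back(+1);
          dir = -1; imin = i;
        }
      } else {
        if (d[i] < d[imin]) imin = i;
        else if (d[i] - d[imin] > min_change) {
          idx.push_back(imin); typ.push_back(-1);
          dir = +1; imax = i;
        }
      }
    }
    // boundary extremum at the end
    if (dir > 0) { idx.push_back(imax); typ.push_back(+1); }
    else if (dir < 0) { idx.push_back(imin); typ.push_back(-1); }
  }
  IntegerVector out_i(idx.size()), out_t(typ.size());
  for (size_t j = 0; j < idx.size(); ++j) { out_i[j] = idx[j] + 1; out_t[j] = typ[j]; }
  return List::create(_["index"] = out_i, _["type"] = out_t);
}
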