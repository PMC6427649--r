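#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Internal cost-volume layout is (y, x, d) with d contiguous; the R-facing
// array layout is column-major (h, w, D). Costs are in 8-bit gray levels
// (callers scale [0,1] images by 255). Candidates with no valid window
// sample carry BIGCOST internally and NA in the exported array.
static const double BIGCOST = 1e6;

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Windowed SAD/SSD matching cost, normalized by the number of in-range
// samples. A sample is valid when both the left pixel and its d-shifted
// right partner fall inside the image.
static void cost_volume_internal(const double* L, const double* Rg,
                                 int h, int w, int window, int D,
                                 int metric, std::vector<double>& C) {
  const int hw = window / 2;
  C.assign(static_cast<size_t>(h) * w * D, BIGCOST);
  std::vector<double> sat(static_cast<size_t>(h + 1) * (w + 1));
  std::vector<double> diff(static_cast<size_t>(h) * w);
  for (int d = 0; d < D; ++d) {
    // per-pixel |L - R shifted| (or squared), zero where x - d < 0
    for (int y = 0; y < h; ++y) {
      for (int x = 0; x < w; ++x) {
        double v = 0.0;
        if (x - d >= 0) {
          double e = L[y + x * h] - Rg[y + (x - d) * h];
          v = metric == 0 ? std::fabs(e) : e * e;
        }
        diff[static_cast<size_t>(y) * w + x] = v;
      }
    }
    // summed-area table
    for (int x = 0; x <= w; ++x) sat[x] = 0.0;
    for (int y = 1; y <= h; ++y) {
      sat[static_cast<size_t>(y) * (w + 1)] = 0.0;
      double rowsum = 0.0;
      for (int x = 1; x <= w; ++x) {
        rowsum += diff[static_cast<size_t>(y - 1) * w + (x - 1)];
        sat[static_cast<size_t>(y) * (w + 1) + x] =
          sat[static_cast<size_t>(y - 1) * (w + 1) + x] + rowsum;
      }
    }
    for (int y = 0; y < h; ++y) {
      int r0 = std::max(0, y - hw), r1 = std::min(h - 1, y + hw);
      int nrow = r1 - r0 + 1;
      for (int x = 0; x < w; ++x) {
        int c0 = std::max(std::max(0, x - hw), d);
        int c1 = std::min(w - 1, x + hw);
        if (c1 < c0) continue;  // no valid sample: stays BIGCOST
        double s = sat[static_cast<size_t>(r1 + 1) * (w + 1) + (c1 + 1)]
                 - sat[static_cast<size_t>(r0) * (w + 1) + (c1 + 1)]
                 - sat[static_cast<size_t>(r1 + 1) * (w + 1) + c0]
                 + sat[static_cast<size_t>(r0) * (w + 1) + c0];
        C[(static_cast<size_t>(y) * w + x) * D + d] =
          s / (static_cast<double>(nrow) * (c1 - c0 + 1));
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_cost_volume(NumericMatrix left, NumericMatrix right,
                              int window, int max_disp, int metric) {
  int h = left.nrow(), w = left.ncol(), D = max_disp + 1;
  std::vector<double> C;
  cost_volume_internal(left.begin(), right.begin(), h, w, window, D,
                       metric, C);
  NumericVector out(static_cast<R_xlen_t>(h) * w * D);
  out.attr("dim") = IntegerVector::create(h, w, D);
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        double v = C[(static_cast<size_t>(y) * w + x) * D + d];
        out[y + static_cast<R_xlen_t>(x) * h +
            static_cast<R_xlen_t>(d) * h * w] = v >= BIGCOST ? NA_REAL : v;
      }
  return out;
}

// Winner-take-all with 3-point parabolic subpixel refinement and a
// uniqueness check: the best cost must beat every candidate further than
// 1 disparity step by the relative margin `uniq`. Ties go to the smaller
// disparity.
static void wta(const std::vector<double>& C, int h, int w, int D,
                double uniq, std::vector<double>& disp,
                std::vector<int>& ivalid) {
  disp.assign(static_cast<size_t>(h) * w,
              std::numeric_limits<double>::quiet_NaN());
  ivalid.assign(static_cast<size_t>(h) * w, 0);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      const double* c = &C[(static_cast<size_t>(y) * w + x) * D];
      int best = -1; double bc = BIGCOST;
      for (int d = 0; d < D; ++d)
        if (c[d] < bc) { bc = c[d]; best = d; }
      if (best < 0) continue;
      double second = BIGCOST;
      for (int d = 0; d < D; ++d)
        if (std::abs(d - best) > 1 && c[d] < second) second = c[d];
      if (D > 2 && !(second > bc * (1.0 + uniq))) continue;
      double dd = best;
      if (best > 0 && best < D - 1 && c[best - 1] < BIGCOST &&
          c[best + 1] < BIGCOST) {
        double den = c[best - 1] - 2.0 * c[best] + c[best + 1];
        if (den > 0) {
          double delta = (c[best - 1] - c[best + 1]) / (2.0 * den);
          if (delta > 0.5) delta = 0.5;
          if (delta < -0.5) delta = -0.5;
          dd += delta;
        }
      }
      disp[static_cast<size_t>(y) * w + x] = dd;
      ivalid[static_cast<size_t>(y) * w + x] = 1;
    }
}

// Right-view WTA from the left cost volume: C_R(y, x, d) = C_L(y, x+d, d).
static void wta_right(const std::vector<double>& C, int h, int w, int D,
                      std::vector<double>& dispR) {
  dispR.assign(static_cast<size_t>(h) * w,
               std::numeric_limits<double>::quiet_NaN());
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      int best = -1; double bc = BIGCOST;
      for (int d = 0; d < D && x + d < w; ++d) {
        double v = C[(static_cast<size_t>(y) * w + (x + d)) * D + d];
        if (v < bc) { bc = v; best = d; }
      }
      if (best >= 0) dispR[static_cast<size_t>(y) * w + x] = best;
    }
}

static void lr_check(std::vector<double>& disp, std::vector<int>& ivalid,
                     const std::vector<double>& dispR, int h, int w,
                     double tol) {
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      size_t i = static_cast<size_t>(y) * w + x;
      if (!ivalid[i]) continue;
      int dl = static_cast<int>(std::lround(disp[i]));
      int xr = x - dl;
      bool ok = false;
      if (xr >= 0 && xr < w) {
        double dr = dispR[static_cast<size_t>(y) * w + xr];
        if (std::isfinite(dr) && std::fabs(disp[i] - dr) <= tol) ok = true;
      }
      if (!ok) {
        ivalid[i] = 0;
        disp[i] = std::numeric_limits<double>::quiet_NaN();
      }
    }
}

static List disparity_result(const std::vector<double>& disp,
                             const std::vector<int>& ivalid, int h, int w) {
  NumericMatrix dm(h, w);
  LogicalMatrix vm(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      size_t i = static_cast<size_t>(y) * w + x;
      dm(y, x) = ivalid[i] ? disp[i] : NA_REAL;
      vm(y, x) = ivalid[i] != 0;
    }
  return List::create(_["values"] = dm, _["valid"] = vm);
}

// [[Rcpp::export]]
List cpp_block_match(NumericMatrix left, NumericMatrix right, int window,
                     int max_disp, int metric, double uniq, double lr_tol) {
  int h = left.nrow(), w = left.ncol(), D = max_disp + 1;
  std::vector<double> C;
  cost_volume_internal(left.begin(), right.begin(), h, w, window, D,
                       metric, C);
  std::vector<double> disp, dispR;
  std::vector<int> ivalid;
  wta(C, h, w, D, uniq, disp, ivalid);
  wta_right(C, h, w, D, dispR);
  lr_check(disp, ivalid, dispR, h, w, lr_tol);
  return disparity_result(disp, ivalid, h, w);
}

// Path order for num_paths = 2/4/8: horizontal pair first, then vertical,
// then the two diagonal pairs.
static const int DIRS[8][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1},
                               {1, 1}, {-1, -1}, {1, -1}, {-1, 1}};

// One SGM path direction, streamed with a one-row (or one-pixel) history.
// L_r(p, d) = C(p, d) + min(L(p-r, d), L(p-r, d±1) + P1, min_k L(p-r, k)
// + P2) - min_k L(p-r, k); pixels without a predecessor start at C.
static void aggregate_dir(const std::vector<double>& C, int h, int w, int D,
                          double p1, double p2, int dx, int dy,
                          std::vector<double>& S) {
  std::vector<double> Lprev, Lcur(static_cast<size_t>(w) * D);
  if (dy != 0) Lprev.assign(static_cast<size_t>(w) * D, 0.0);
  int y0 = dy >= 0 ? 0 : h - 1, ystep = dy >= 0 ? 1 : -1;
  int x0 = dx >= 0 ? 0 : w - 1, xstep = dx >= 0 ? 1 : -1;
  for (int yi = 0; yi < h; ++yi) {
    int y = y0 + yi * ystep;
    for (int xi = 0; xi < w; ++xi) {
      int x = x0 + xi * xstep;
      const double* c = &C[(static_cast<size_t>(y) * w + x) * D];
      double* lc = &Lcur[static_cast<size_t>(x) * D];
      int px = x - dx, py = y - dy;
      const double* lp = NULL;
      if (px >= 0 && px < w && py >= 0 && py < h) {
        if (dy == 0) lp = &Lcur[static_cast<size_t>(px) * D];
        else lp = &Lprev[static_cast<size_t>(px) * D];
      }
      if (lp == NULL || (dy != 0 && yi == 0)) {
        for (int d = 0; d < D; ++d) lc[d] = c[d];
      } else {
        double minp = lp[0];
        for (int d = 1; d < D; ++d) if (lp[d] < minp) minp = lp[d];
        for (int d = 0; d < D; ++d) {
          double m = lp[d];
          if (d > 0 && lp[d - 1] + p1 < m) m = lp[d - 1] + p1;
          if (d < D - 1 && lp[d + 1] + p1 < m) m = lp[d + 1] + p1;
          if (minp + p2 < m) m = minp + p2;
          lc[d] = c[d] + m - minp;
        }
      }
      double* s = &S[(static_cast<size_t>(y) * w + x) * D];
      for (int d = 0; d < D; ++d) s[d] += lc[d];
    }
    if (dy != 0) Lprev.swap(Lcur);
  }
}

static void aggregate_all(const std::vector<double>& C, int h, int w, int D,
                          double p1, double p2, int num_paths,
                          std::vector<double>& S) {
  S.assign(C.size(), 0.0);
  for (int r = 0; r < num_paths; ++r)
    aggregate_dir(C, h, w, D, p1, p2, DIRS[r][0], DIRS[r][1], S);
}

// [[Rcpp::export]]
NumericVector cpp_sgm_aggregate(NumericVector costvol, double p1, double p2,
                                int num_paths) {
  IntegerVector dim = costvol.attr("dim");
  int h = dim[0], w = dim[1], D = dim[2];
  std::vector<double> C(static_cast<size_t>(h) * w * D);
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        double v = costvol[y + static_cast<R_xlen_t>(x) * h +
                           static_cast<R_xlen_t>(d) * h * w];
        C[(static_cast<size_t>(y) * w + x) * D + d] =
          ISNAN(v) ? BIGCOST : v;
      }
  std::vector<double> S;
  aggregate_all(C, h, w, D, p1, p2, num_paths, S);
  NumericVector out(costvol.size());
  out.attr("dim") = dim;
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y)
        out[y + static_cast<R_xlen_t>(x) * h +
            static_cast<R_xlen_t>(d) * h * w] =
          S[(static_cast<size_t>(y) * w + x) * D + d];
  return out;
}

// [[Rcpp::export]]
List cpp_sgm_match(NumericMatrix left, NumericMatrix right, int window,
                   int max_disp, double p1, double p2, int num_paths,
                   double uniq, double lr_tol) {
  int h = left.nrow(), w = left.ncol(), D = max_disp + 1;
  std::vector<double> C;
  cost_volume_internal(left.begin(), right.begin(), h, w, window, D,
                       /*metric SAD*/ 0, C);
  std::vector<double> S;
  aggregate_all(C, h, w, D, p1, p2, num_paths, S);
  C.clear(); C.shrink_to_fit();
  std::vector<double> disp, dispR;
  std::vector<int> ivalid;
  wta(S, h, w, D, uniq, disp, ivalid);
  wta_right(S, h, w, D, dispR);
  lr_check(disp, ivalid, dispR, h, w, lr_tol);
  return disparity_result(disp, ivalid, h, w);
}
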