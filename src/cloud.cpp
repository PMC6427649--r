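#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Bilinear resampling of an (h, w) or (h, w, c) image through per-pixel
// source-coordinate maps (0-based pixel centers). Samples falling outside
// the source raster, or with a non-finite map entry, produce black (0).
// [[Rcpp::export]]
NumericVector cpp_remap_bilinear(NumericVector img, NumericMatrix mapx,
                                 NumericMatrix mapy) {
  IntegerVector dim = img.attr("dim");
  int h = dim[0], w = dim[1], nc = dim.size() == 3 ? dim[2] : 1;
  int ho = mapx.nrow(), wo = mapx.ncol();
  NumericVector out(static_cast<R_xlen_t>(ho) * wo * nc);
  if (nc > 1) out.attr("dim") = IntegerVector::create(ho, wo, nc);
  else out.attr("dim") = IntegerVector::create(ho, wo);
  for (int j = 0; j < wo; ++j)
    for (int i = 0; i < ho; ++i) {
      double sx = mapx(i, j), sy = mapy(i, j);
      if (!std::isfinite(sx) || !std::isfinite(sy)) continue;
      if (sx < 0 || sx > w - 1 || sy < 0 || sy > h - 1) continue;
      int x0 = static_cast<int>(std::floor(sx));
      int y0 = static_cast<int>(std::floor(sy));
      int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
      double fx = sx - x0, fy = sy - y0;
      for (int c = 0; c < nc; ++c) {
        R_xlen_t off = static_cast<R_xlen_t>(c) * h * w;
        double v00 = img[off + y0 + static_cast<R_xlen_t>(x0) * h];
        double v10 = img[off + y1 + static_cast<R_xlen_t>(x0) * h];
        double v01 = img[off + y0 + static_cast<R_xlen_t>(x1) * h];
        double v11 = img[off + y1 + static_cast<R_xlen_t>(x1) * h];
        double v = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                   fy * ((1 - fx) * v10 + fx * v11);
        out[static_cast<R_xlen_t>(c) * ho * wo + i +
            static_cast<R_xlen_t>(j) * ho] = v;
      }
    }
  return out;
}

// Mean distance from each point to its k nearest neighbours (self
// excluded), by exhaustive search. Intended for clouds of a few thousand
// points (the down-sampled budget).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  NumericVector out(n);
  std::vector<double> d2(n);
  const double* X = pts.begin();
  for (int i = 0; i < n; ++i) {
    double xi = X[i], yi = X[i + n], zi = X[i + 2 * n];
    for (int j = 0; j < n; ++j) {
      double dx = X[j] - xi, dy = X[j + n] - yi, dz = X[j + 2 * n] - zi;
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    d2[i] = std::numeric_limits<double>::infinity();  // exclude self
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d2[j]);
    // nth_element leaves the k smallest in the first k slots
    out[i] = s / k;
  }
  return out;
}

namespace {

struct Leaf {
  std::vector<int> idx;           // 0-based point indices, ascending
  double lo[3], hi[3];
  std::vector<uint8_t> path;      // child codes from the root (Morton order)
  bool splittable;
};

// Lexicographic path order; a shorter path that is a prefix sorts first.
bool path_less(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b) {
  size_t n = std::min(a.size(), b.size());
  for (size_t i = 0; i < n; ++i)
    if (a[i] != b[i]) return a[i] < b[i];
  return a.size() < b.size();
}

}  // namespace

// Non-uniform box-grid (octree) down-sampling: starting from the bounding
// box, repeatedly split the occupied box holding the most points into its
// 8 octants until the number of occupied leaves reaches `target`, then
// emit one representative per leaf. Ties in "most points" are broken by
// the lowest Morton path. When the final split would overshoot the
// budget, the largest octants become leaves and the remainder are kept
// together so the leaf count lands exactly on `target`.
// [[Rcpp::export]]
List cpp_octree_sample(NumericMatrix pts, int target, bool member_rep) {
  int n = pts.nrow();
  const double* X = pts.begin();
  std::vector<Leaf> leaves;
  {
    Leaf root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    for (int a = 0; a < 3; ++a) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double v = X[i + static_cast<R_xlen_t>(a) * n];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      root.lo[a] = lo; root.hi[a] = hi;
    }
    root.splittable = n >= 2;
    leaves.push_back(root);
  }
  const int MAX_DEPTH = 64;
  while (static_cast<int>(leaves.size()) < target) {
    int pick = -1;
    for (int i = 0; i < static_cast<int>(leaves.size()); ++i) {
      if (!leaves[i].splittable || leaves[i].idx.size() < 2) continue;
      if (pick < 0 || leaves[i].idx.size() > leaves[pick].idx.size() ||
          (leaves[i].idx.size() == leaves[pick].idx.size() &&
           path_less(leaves[i].path, leaves[pick].path)))
        pick = i;
    }
    if (pick < 0) break;
    Leaf& L = leaves[pick];
    double ext = 0.0;
    for (int a = 0; a < 3; ++a) ext = std::max(ext, L.hi[a] - L.lo[a]);
    if (ext < 1e-12 || static_cast<int>(L.path.size()) >= MAX_DEPTH) {
      L.splittable = false;
      continue;
    }
    double c[3];
    for (int a = 0; a < 3; ++a) c[a] = 0.5 * (L.lo[a] + L.hi[a]);
    std::vector<std::vector<int> > buckets(8);
    for (size_t t = 0; t < L.idx.size(); ++t) {
      int i = L.idx[t];
      int code = (X[i] >= c[0] ? 1 : 0) |
                 (X[i + n] >= c[1] ? 2 : 0) |
                 (X[i + 2 * static_cast<R_xlen_t>(n)] >= c[2] ? 4 : 0);
      buckets[code].push_back(i);
    }
    std::vector<int> occ;
    for (int b = 0; b < 8; ++b)
      if (!buckets[b].empty()) occ.push_back(b);
    Leaf parent = L;  // copy before mutating the vector
    if (occ.size() == 1) {
      // all points in one octant: shrink the box and retry
      int b = occ[0];
      Leaf nw = parent;
      for (int a = 0; a < 3; ++a) {
        bool hiHalf = (b >> a) & 1;
        nw.lo[a] = hiHalf ? c[a] : parent.lo[a];
        nw.hi[a] = hiHalf ? parent.hi[a] : c[a];
      }
      nw.path.push_back(static_cast<uint8_t>(b));
      leaves[pick] = nw;
      continue;
    }
    int needed = target - static_cast<int>(leaves.size()) + 1;
    std::vector<Leaf> children;
    if (static_cast<int>(occ.size()) <= needed) {
      for (size_t t = 0; t < occ.size(); ++t) {
        int b = occ[t];
        Leaf ch;
        ch.idx = buckets[b];
        for (int a = 0; a < 3; ++a) {
          bool hiHalf = (b >> a) & 1;
          ch.lo[a] = hiHalf ? c[a] : parent.lo[a];
          ch.hi[a] = hiHalf ? parent.hi[a] : c[a];
        }
        ch.path = parent.path;
        ch.path.push_back(static_cast<uint8_t>(b));
        ch.splittable = ch.idx.size() >= 2;
        children.push_back(ch);
      }
    } else {
      // final split would overshoot: keep the largest octants, merge the rest
      std::vector<int> order(occ);
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        if (buckets[a].size() != buckets[b].size())
          return buckets[a].size() > buckets[b].size();
        return a < b;
      });
      std::vector<int> merged;
      for (size_t t = 0; t < order.size(); ++t) {
        int b = order[t];
        if (static_cast<int>(t) < needed - 1) {
          Leaf ch;
          ch.idx = buckets[b];
          for (int a = 0; a < 3; ++a) {
            bool hiHalf = (b >> a) & 1;
            ch.lo[a] = hiHalf ? c[a] : parent.lo[a];
            ch.hi[a] = hiHalf ? parent.hi[a] : c[a];
          }
          ch.path = parent.path;
          ch.path.push_back(static_cast<uint8_t>(b));
          ch.splittable = false;
          children.push_back(ch);
        } else {
          merged.insert(merged.end(), buckets[b].begin(), buckets[b].end());
        }
      }
      std::sort(merged.begin(), merged.end());
      Leaf rest = parent;
      rest.idx = merged;
      rest.path.push_back(static_cast<uint8_t>(255));
      rest.splittable = false;
      children.push_back(rest);
    }
    leaves.erase(leaves.begin() + pick);
    leaves.insert(leaves.end(), children.begin(), children.end());
  }
  std::sort(leaves.begin(), leaves.end(), [](const Leaf& a, const Leaf& b) {
    return path_less(a.path, b.path);
  });
  int m = static_cast<int>(leaves.size());
  NumericMatrix outpts(m, 3);
  IntegerVector outidx(m);
  for (int i = 0; i < m; ++i) {
    const std::vector<int>& ix = leaves[i].idx;
    double cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < ix.size(); ++t) {
      cx += X[ix[t]];
      cy += X[ix[t] + n];
      cz += X[ix[t] + 2 * static_cast<R_xlen_t>(n)];
    }
    cx /= ix.size(); cy /= ix.size(); cz /= ix.size();
    if (member_rep) {
      int best = ix[0]; double bd = R_PosInf;
      for (size_t t = 0; t < ix.size(); ++t) {
        double dx = X[ix[t]] - cx, dy = X[ix[t] + n] - cy,
               dz = X[ix[t] + 2 * static_cast<R_xlen_t>(n)] - cz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < bd) { bd = d2; best = ix[t]; }
      }
      outidx[i] = best + 1;  // 1-based for R
      outpts(i, 0) = X[best];
      outpts(i, 1) = X[best + n];
      outpts(i, 2) = X[best + 2 * static_cast<R_xlen_t>(n)];
    } else {
      outidx[i] = NA_INTEGER;
      outpts(i, 0) = cx; outpts(i, 1) = cy; outpts(i, 2) = cz;
    }
  }
  return List::create(_["points"] = outpts, _["index"] = outidx);
}
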