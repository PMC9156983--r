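// Voxel-level primitives for 3D bone image analysis: separable truncated
// Gaussian filtering, connected-component labeling (6/26), exact squared
// Euclidean distance transform (Felzenszwalb & Huttenlocher), local
// thickness by largest inscribed spheres, face-connected erosion, and a
// chamfer geodesic distance for 2D band parameterization.
//
// All arrays are R column-major with dims (d0, d1, d2); a 2D image is
// passed with one singleton axis.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline int reflect_index(int j, int n) {
  // symmetric (mirror) boundary: -1 -> 0, n -> n-1
  while (j < 0 || j >= n) {
    if (j < 0) j = -j - 1;
    if (j >= n) j = 2 * n - j - 1;
  }
  return j;
}

static void blur_axis(const std::vector<double>& in, std::vector<double>& out,
                      const int n[3], int axis,
                      const std::vector<double>& w, int S) {
  const long s[3] = {1L, (long)n[0], (long)n[0] * n[1]};
  const long stride = s[axis];
  const int na = n[axis];
  for (int i2 = 0; i2 < n[2]; ++i2) {
    for (int i1 = 0; i1 < n[1]; ++i1) {
      for (int i0 = 0; i0 < n[0]; ++i0) {
        const int idx3[3] = {i0, i1, i2};
        const long base = i0 + s[1] * (long)i1 + s[2] * (long)i2;
        const int ia = idx3[axis];
        double acc = 0.0;
        for (int k = -S; k <= S; ++k) {
          const int j = reflect_index(ia + k, na);
          acc += w[k + S] * in[base + (long)(j - ia) * stride];
        }
        out[base] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dims,
                                double sigma, int support) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n[3] = {dims[0], dims[1], dims[2]};
  const long ntot = (long)n[0] * n[1] * n[2];
  if ((long)x.size() != ntot) stop("data length does not match dims");
  if (sigma < 0) stop("sigma must be non-negative");
  if (support < 1) stop("support must be >= 1");

  NumericVector res(clone(x));
  if (sigma == 0.0) return res;

  const int S = support;
  std::vector<double> w(2 * S + 1);
  double tot = 0.0;
  for (int k = -S; k <= S; ++k) {
    w[k + S] = std::exp(-(double)(k * k) / (2.0 * sigma * sigma));
    tot += w[k + S];
  }
  for (double& v : w) v /= tot;

  std::vector<double> a(x.begin(), x.end()), b(ntot);
  for (int axis = 0; axis < 3; ++axis) {
    if (n[axis] > 1) {
      blur_axis(a, b, n, axis, w, S);
      std::swap(a, b);
    }
  }
  std::copy(a.begin(), a.end(), res.begin());
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const long ntot = (long)n0 * n1 * n2;
  if ((long)mask.size() != ntot) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbor coordinate deltas
  std::vector<int> d0, d1, d2;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        const int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        d0.push_back(a); d1.push_back(b); d2.push_back(c);
      }
  const int nn = (int)d0.size();

  IntegerVector labels(ntot, 0);
  std::vector<long> stack;
  int current = 0;
  const long s1 = n0, s2 = (long)n0 * n1;

  for (long i = 0; i < ntot; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int i2 = (int)(v / s2);
      const int rem = (int)(v - (long)i2 * s2);
      const int i1 = rem / n0;
      const int i0 = rem - i1 * n0;
      for (int k = 0; k < nn; ++k) {
        const int j0 = i0 + d0[k], j1 = i1 + d1[k], j2 = i2 + d2[k];
        if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
          continue;
        const long u = j0 + s1 * (long)j1 + s2 * (long)j2;
        if (mask[u] && labels[u] == 0) {
          labels[u] = current;
          stack.push_back(u);
        }
      }
    }
  }
  return labels;
}

// "no background on this line yet" sentinel: far above any reachable
// squared distance (dims are bounded by array memory, so true squared
// distances stay below ~1e10) but small enough that parabola arithmetic
// stays exact-ordered in doubles.
static const double HUGEV = 1e12;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012), lower envelope of parabolas.
static void dt1d(std::vector<double>& f, int n,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
          (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    const double dq = (double)q - p;
    d[q] = dq * dq + f[p];
  }
}

static void edt_sq_core(const LogicalVector& mask, const int n[3],
                        std::vector<double>& g) {
  const long ntot = (long)n[0] * n[1] * n[2];
  g.resize(ntot);
  for (long i = 0; i < ntot; ++i) g[i] = mask[i] ? HUGEV : 0.0;

  const long s[3] = {1L, (long)n[0], (long)n[0] * n[1]};
  const int nmax = std::max(n[0], std::max(n[1], n[2]));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int axis = 0; axis < 3; ++axis) {
    const int na = n[axis];
    if (na <= 1) continue;
    const long stride = s[axis];
    const int ob = (axis == 0) ? 1 : 0;
    const int oc = (axis == 2) ? 1 : 2;
    for (int ib = 0; ib < n[ob]; ++ib) {
      for (int ic = 0; ic < n[oc]; ++ic) {
        const long base = s[ob] * (long)ib + s[oc] * (long)ic;
        for (int q = 0; q < na; ++q) f[q] = g[base + stride * q];
        dt1d(f, na, d, v, z);
        for (int q = 0; q < na; ++q)
          g[base + stride * q] = std::min(d[q], HUGEV);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n[3] = {dims[0], dims[1], dims[2]};
  const long ntot = (long)n[0] * n[1] * n[2];
  if ((long)mask.size() != ntot) stop("mask length does not match dims");
  std::vector<double> g;
  edt_sq_core(mask, n, g);
  // volumes with no background voxel at all: report the (unreachable)
  // full-diagonal distance instead of the internal sentinel
  const double big = (double)(n[0] + n[1] + n[2]);
  NumericVector out(ntot);
  for (long i = 0; i < ntot; ++i) out[i] = (g[i] >= HUGEV) ? big * big : g[i];
  return out;
}

// Local thickness (Hildebrand & Rüegsegger): for every foreground voxel,
// the diameter (in voxel units) of the largest sphere that contains the
// voxel and fits entirely in the foreground. Spheres are centered at every
// foreground voxel with radius = Euclidean distance to the nearest
// background voxel center; a sphere covers voxels strictly closer than r.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n[3] = {dims[0], dims[1], dims[2]};
  const long ntot = (long)n[0] * n[1] * n[2];
  if ((long)mask.size() != ntot) stop("mask length does not match dims");

  std::vector<double> r2;
  edt_sq_core(mask, n, r2);
  const double big = (double)(n[0] + n[1] + n[2]);
  for (long i = 0; i < ntot; ++i) if (r2[i] >= HUGEV) r2[i] = big * big;

  // Distance ridge: a sphere centered at v is redundant when a
  // 26-neighbor u satisfies r(u) >= r(v) + |u - v|, since sphere(v) is
  // then contained in sphere(u); only non-redundant centers are drawn.
  // This is containment-exact pruning, not an approximation.
  const long ss1 = n[0], ss2 = (long)n[0] * n[1];
  std::vector<long> fg;
  for (long i = 0; i < ntot; ++i) {
    if (!mask[i]) continue;
    const double rv = std::sqrt(r2[i]);
    const int i2 = (int)(i / ss2);
    const int rem = (int)(i - (long)i2 * ss2);
    const int i1 = rem / n[0];
    const int i0 = rem - i1 * n[0];
    bool redundant = false;
    for (int a = -1; a <= 1 && !redundant; ++a)
      for (int b = -1; b <= 1 && !redundant; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          const int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
          if (j0 < 0 || j0 >= n[0] || j1 < 0 || j1 >= n[1] ||
              j2 < 0 || j2 >= n[2]) continue;
          const long u = j0 + ss1 * (long)j1 + ss2 * (long)j2;
          if (!mask[u]) continue;
          const double duv = std::sqrt((double)(a * a + b * b + c * c));
          if (std::sqrt(r2[u]) >= rv + duv - 1e-9) {
            redundant = true;
            break;
          }
        }
    if (!redundant) fg.push_back(i);
  }
  std::sort(fg.begin(), fg.end(),
            [&](long a, long b) { return r2[a] > r2[b]; });

  NumericVector th(ntot, 0.0);
  const long s1 = n[0], s2 = (long)n[0] * n[1];
  for (const long v : fg) {
    const double rr2 = r2[v];
    const double r = std::sqrt(rr2);
    const double diam = 2.0 * r;
    const int i2 = (int)(v / s2);
    const int rem = (int)(v - (long)i2 * s2);
    const int i1 = rem / n[0];
    const int i0 = rem - i1 * n[0];
    const int R = (int)std::ceil(r);
    for (int a = std::max(0, i0 - R); a <= std::min(n[0] - 1, i0 + R); ++a) {
      const double da = (double)(a - i0) * (a - i0);
      if (da > rr2 + 1e-9) continue;
      for (int b = std::max(0, i1 - R); b <= std::min(n[1] - 1, i1 + R); ++b) {
        const double dab = da + (double)(b - i1) * (b - i1);
        if (dab > rr2 + 1e-9) continue;
        const long rowbase = a + s1 * (long)b;
        for (int c = std::max(0, i2 - R); c <= std::min(n[2] - 1, i2 + R); ++c) {
          const double dd = dab + (double)(c - i2) * (c - i2);
          if (dd <= rr2 + 1e-9) {
            const long u = rowbase + s2 * (long)c;
            if (mask[u] && th[u] < diam) th[u] = diam;
          }
        }
      }
    }
  }
  return th;
}

// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask, IntegerVector dims,
                         int iterations) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const long ntot = (long)n0 * n1 * n2;
  if ((long)mask.size() != ntot) stop("mask length does not match dims");
  if (iterations < 0) stop("iterations must be non-negative");

  std::vector<char> cur(ntot), nxt(ntot);
  for (long i = 0; i < ntot; ++i) cur[i] = mask[i] ? 1 : 0;
  const long s1 = n0, s2 = (long)n0 * n1;

  for (int it = 0; it < iterations; ++it) {
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        for (int i0 = 0; i0 < n0; ++i0) {
          const long v = i0 + s1 * (long)i1 + s2 * (long)i2;
          char keep = cur[v];
          if (keep) {
            // outside the array counts as background: surfaces at the
            // array edge recede like any other surface
            if (i0 == 0 || i0 == n0 - 1 || !cur[v - 1] || !cur[v + 1] ||
                i1 == 0 || i1 == n1 - 1 || !cur[v - s1] || !cur[v + s1] ||
                i2 == 0 || i2 == n2 - 1 || !cur[v - s2] || !cur[v + s2])
              keep = 0;
          }
          nxt[v] = keep;
        }
      }
    }
    std::swap(cur, nxt);
  }
  LogicalVector out(ntot);
  for (long i = 0; i < ntot; ++i) out[i] = cur[i] != 0;
  return out;
}

// Geodesic (within-mask) distance from a seed pixel by iterated chamfer
// sweeps with weights 1 / sqrt(2); pixels outside the mask get NA.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_2d(LogicalMatrix mask, int seed_r, int seed_c) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (seed_r < 0 || seed_r >= nr || seed_c < 0 || seed_c >= nc)
    stop("seed out of bounds");
  if (!mask(seed_r, seed_c)) stop("seed must lie inside the mask");
  const double SQ2 = std::sqrt(2.0);
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = mask(r, c) ? INF : -1.0;
  d(seed_r, seed_c) = 0.0;

  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10000) {
    changed = false;
    // forward sweep
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (d(r, c) < 0) continue;
        double best = d(r, c);
        if (r > 0 && d(r - 1, c) >= 0) best = std::min(best, d(r - 1, c) + 1);
        if (c > 0 && d(r, c - 1) >= 0) best = std::min(best, d(r, c - 1) + 1);
        if (r > 0 && c > 0 && d(r - 1, c - 1) >= 0)
          best = std::min(best, d(r - 1, c - 1) + SQ2);
        if (r < nr - 1 && c > 0 && d(r + 1, c - 1) >= 0)
          best = std::min(best, d(r + 1, c - 1) + SQ2);
        if (best < d(r, c)) { d(r, c) = best; changed = true; }
      }
    }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c) {
      for (int r = nr - 1; r >= 0; --r) {
        if (d(r, c) < 0) continue;
        double best = d(r, c);
        if (r < nr - 1 && d(r + 1, c) >= 0) best = std::min(best, d(r + 1, c) + 1);
        if (c < nc - 1 && d(r, c + 1) >= 0) best = std::min(best, d(r, c + 1) + 1);
        if (r < nr - 1 && c < nc - 1 && d(r + 1, c + 1) >= 0)
          best = std::min(best, d(r + 1, c + 1) + SQ2);
        if (r > 0 && c < nc - 1 && d(r - 1, c + 1) >= 0)
          best = std::min(best, d(r - 1, c + 1) + SQ2);
        if (best < d(r, c)) { d(r, c) = best; changed = true; }
      }
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (d(r, c) < 0 || d(r, c) == INF) d(r, c) = NA_REAL;
  return d;
}
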