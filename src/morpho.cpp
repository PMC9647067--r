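// 3D morphology primitives for nucleus segmentation.
// Volumes arrive as R arrays with dim = (nz, ny, nx); linear index
// i = z + nz*(y + ny*x), i.e. column-major over (z, y, x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  Grid(const IntegerVector &dim) : nz(dim[0]), ny(dim[1]), nx(dim[2]) {}
  R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
  R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
};

// neighbour offsets for 6- or 26-connectivity
static void neighbour_offsets(int conn, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int d = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (d == 0) continue;
        if (conn == 6 && d > 1) continue;
        off.push_back({dz, dy, dx});
      }
}

} // namespace

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  if (mask.size() != g.n()) stop("mask length does not match dim");
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);

  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z) {
        R_xlen_t i0 = g.idx(z, y, x);
        if (!mask[i0] || lab[i0] != 0) continue;
        ++cur;
        lab[i0] = cur;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int zz = (int)(i % g.nz);
          R_xlen_t r = i / g.nz;
          int yy = (int)(r % g.ny);
          int xx = (int)(r / g.ny);
          for (auto &o : off) {
            int z2 = zz + o[0], y2 = yy + o[1], x2 = xx + o[2];
            if (z2 < 0 || z2 >= g.nz || y2 < 0 || y2 >= g.ny ||
                x2 < 0 || x2 >= g.nx) continue;
            R_xlen_t j = g.idx(z2, y2, x2);
            if (mask[j] && lab[j] == 0) { lab[j] = cur; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing s; f holds squared distances, INF for "not yet reached".
static void dt1d(std::vector<double> &f, double s, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  d.assign(n, 0.0);
  v.assign(n, 0);
  zb.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;             // never a source parabola
    double sq = (double)q * s;
    double ss;
    while (true) {
      if (f[v[k]] == INF) {
        ss = -INF;                         // finite parabola dominates everywhere
      } else {
        double sv = (double)v[k] * s;
        ss = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      }
      if (k > 0 && ss <= zb[k]) { --k; } else break;
    }
    if (ss == -INF) {                      // replace the lone INF parabola
      v[0] = q;
      zb[0] = -INF;
      zb[1] = INF;
      k = 0;
      continue;
    }
    ++k;
    v[k] = q;
    zb[k] = ss;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zb[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
  f = d;
}

// Exact anisotropic Euclidean distance transform: distance (in the units of
// `spacing`) from each foreground voxel to the nearest background voxel.
// Volume faces are treated as background-adjacent (distance to the face).
// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector mask, IntegerVector dim, NumericVector spacing_zyx) {
  Grid g(dim);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> f((size_t)g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) f[i] = mask[i] ? INF : 0.0;

  std::vector<double> line, d, zb;
  std::vector<int> v;

  // pass along z
  double sz = spacing_zyx[0];
  line.resize(g.nz);
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y) {
      for (int z = 0; z < g.nz; ++z) line[z] = f[g.idx(z, y, x)];
      dt1d(line, sz, d, v, zb);
      for (int z = 0; z < g.nz; ++z) {
        // face clamp: squared distance to the open boundary just outside
        double face = std::min((double)(z + 1), (double)(g.nz - z)) * sz;
        f[g.idx(z, y, x)] = std::min(line[z], face * face);
      }
    }
  // pass along y
  double sy = spacing_zyx[1];
  line.resize(g.ny);
  for (int x = 0; x < g.nx; ++x)
    for (int z = 0; z < g.nz; ++z) {
      for (int y = 0; y < g.ny; ++y) line[y] = f[g.idx(z, y, x)];
      dt1d(line, sy, d, v, zb);
      for (int y = 0; y < g.ny; ++y) {
        double face = std::min((double)(y + 1), (double)(g.ny - y)) * sy;
        f[g.idx(z, y, x)] = std::min(line[y], face * face);
      }
    }
  // pass along x
  double sx = spacing_zyx[2];
  line.resize(g.nx);
  for (int y = 0; y < g.ny; ++y)
    for (int z = 0; z < g.nz; ++z) {
      for (int x = 0; x < g.nx; ++x) line[x] = f[g.idx(z, y, x)];
      dt1d(line, sx, d, v, zb);
      for (int x = 0; x < g.nx; ++x) {
        double face = std::min((double)(x + 1), (double)(g.nx - x)) * sx;
        f[g.idx(z, y, x)] = std::min(line[x], face * face);
      }
    }

  NumericVector out(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) out[i] = std::sqrt(f[i]);
  out.attr("dim") = dim;
  return out;
}

// Seeded watershed by priority flooding on -priority (higher priority floods
// first). Seeds carry positive labels; flooding is restricted to mask.
// Ties in priority resolve by insertion order; seeds are enqueued in
// ascending label order, so equidistant voxels go to the lower seed label.
// [[Rcpp::export(name = ".watershed")]]
IntegerVector watershed_seeded(NumericVector priority, LogicalVector mask,
                               IntegerVector seeds, IntegerVector dim) {
  Grid g(dim);
  if (priority.size() != g.n() || mask.size() != g.n() || seeds.size() != g.n())
    stop("input lengths do not match dim");
  std::vector<std::array<int,3>> off;
  neighbour_offsets(26, off);

  IntegerVector lab(g.n(), 0);
  struct QE { double p; long long ord; R_xlen_t i; int l; };
  struct Cmp {
    bool operator()(const QE &a, const QE &b) const {
      if (a.p != b.p) return a.p < b.p;       // larger priority first
      return a.ord > b.ord;                   // then FIFO
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  long long ord = 0;

  // collect seed voxels grouped by label, ascending
  std::vector<std::pair<int, R_xlen_t>> sv;
  for (R_xlen_t i = 0; i < g.n(); ++i)
    if (seeds[i] > 0 && mask[i]) sv.push_back({seeds[i], i});
  std::sort(sv.begin(), sv.end());
  for (auto &p : sv) {
    lab[p.second] = p.first;
    pq.push({priority[p.second], ord++, p.second, p.first});
  }

  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    int zz = (int)(e.i % g.nz);
    R_xlen_t r = e.i / g.nz;
    int yy = (int)(r % g.ny);
    int xx = (int)(r / g.ny);
    for (auto &o : off) {
      int z2 = zz + o[0], y2 = yy + o[1], x2 = xx + o[2];
      if (z2 < 0 || z2 >= g.nz || y2 < 0 || y2 >= g.ny ||
          x2 < 0 || x2 >= g.nx) continue;
      R_xlen_t j = g.idx(z2, y2, x2);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = e.l;
      pq.push({priority[j], ord++, j, e.l});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Local maxima of `img` within mask under 26-connectivity (>= all neighbours).
// Returns 1-based linear indices.
// [[Rcpp::export(name = ".local_maxima")]]
IntegerVector local_maxima(NumericVector img, LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(26, off);
  std::vector<int> out;
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z) {
        R_xlen_t i = g.idx(z, y, x);
        if (!mask[i]) continue;
        double v0 = img[i];
        bool ismax = true;
        for (auto &o : off) {
          int z2 = z + o[0], y2 = y + o[1], x2 = x + o[2];
          if (z2 < 0 || z2 >= g.nz || y2 < 0 || y2 >= g.ny ||
              x2 < 0 || x2 >= g.nx) continue;
          R_xlen_t j = g.idx(z2, y2, x2);
          if (mask[j] && img[j] > v0) { ismax = false; break; }
        }
        if (ismax) out.push_back((int)(i + 1));
      }
  return wrap(out);
}
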