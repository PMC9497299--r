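#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform (lower envelope of parabolas), sample
// spacing w. f holds squared distances on input, overwritten on output.
static void dt1d(std::vector<double>& f, double w, std::vector<int>& v,
                 std::vector<double>& z, std::vector<double>& d) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // empty column contributes no parabola
    double s = 0.0;
    while (k >= 0) {
      // abscissa where the parabola from q overtakes the one from v[k]
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w * (q - v[k])); // in mm, comparable with w*q below
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no sites on this scanline
    for (int q = 0; q < n; ++q) f[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < w * q) ++j;
    d[q] = w2 * (q - v[j]) * (q - v[j]) + f[v[j]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance transform of a 3-D site set on an anisotropic
// grid. sites: logical array (column-major) of length nx*ny*nz; spacing in
// mm per axis. Returns squared distance (mm^2) from every voxel centre to
// the nearest site centre; Inf if there are no sites.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      f.assign(out.begin() + base, out.begin() + base + nx);
      dt1d(f, spacing[0], v, z, d);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      f.resize(ny);
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, spacing[1], v, z, d);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      f.resize(nz);
      for (int k = 0; k < nz; ++k) f[k] = out[base + k * slab];
      dt1d(f, spacing[2], v, z, d);
      for (int k = 0; k < nz; ++k) out[base + k * slab] = f[k];
    }
  return out;
}

struct HeapNode {
  double cap;
  R_xlen_t idx;
  bool operator<(const HeapNode& o) const { return cap < o.cap; }
};

// Bottleneck (max-min) capacity from a seed voxel: cap[v] is the largest
// tau such that v lies in the connected component, under the given
// neighbourhood, of { voxels with value >= tau } containing the seed.
// Unreachable voxels (and voxels outside 'mask', if given) get -Inf.
// seed is a 1-based linear index; connectivity is 6 or 26.
// [[Rcpp::export(name = ".bottleneck_capacity")]]
NumericVector bottleneck_capacity(NumericVector values, IntegerVector dims,
                                  double seed1, int connectivity,
                                  Nullable<LogicalVector> mask = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cap(n, -INF);
  std::vector<bool> done(n, false);
  std::vector<bool> allowed(n, true);
  if (mask.isNotNull()) {
    LogicalVector m(mask);
    for (R_xlen_t i = 0; i < n; ++i) allowed[i] = m[i];
  }

  // neighbourhood offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }

  R_xlen_t seed = (R_xlen_t)seed1 - 1;
  if (seed < 0 || seed >= n) stop("seed index out of range");
  if (!allowed[seed]) stop("seed voxel lies outside the growth region");

  std::priority_queue<HeapNode> pq;
  cap[seed] = values[seed];
  pq.push({cap[seed], seed});

  while (!pq.empty()) {
    HeapNode top = pq.top();
    pq.pop();
    if (done[top.idx]) continue;
    done[top.idx] = true;
    int i = (int)(top.idx % nx);
    int j = (int)((top.idx / nx) % ny);
    int k = (int)(top.idx / ((R_xlen_t)nx * ny));
    for (size_t m = 0; m < dx.size(); ++m) {
      int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t vi = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
      if (done[vi] || !allowed[vi]) continue;
      double c2 = std::min(top.cap, values[vi]);
      if (c2 > cap[vi]) {
        cap[vi] = c2;
        pq.push({c2, vi});
      }
    }
  }
  return cap;
}
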