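// Core numerical kernels: isosurface extraction, spherical-harmonic fitting,
// attraction-repulsion updates, co-occurrence accumulation, phantom voxelization.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Normalized associated Legendre functions.
// Fills P (size (N+1)*(N+1), index l*(N+1)+m) with Pbar_l^m(cos theta) such
// that Y_{l,0} = Pbar_l^0 and Y_{l,m} = sqrt(2) * Pbar_l^m * cos(m phi)
// (sin for negative orders) form an orthonormal real basis on the sphere.
// The recurrence is stable to degrees of several hundred.
static void legendre_bar(int N, double x, double s, std::vector<double> &P) {
  const int stride = N + 1;
  double pmm = 1.0 / std::sqrt(4.0 * PI_);
  P[0] = pmm;
  for (int m = 1; m <= N; ++m) {
    pmm *= std::sqrt((2.0 * m + 1.0) / (2.0 * m)) * s;
    P[m * stride + m] = pmm;
  }
  for (int m = 0; m < N; ++m)
    P[(m + 1) * stride + m] = std::sqrt(2.0 * m + 3.0) * x * P[m * stride + m];
  for (int m = 0; m <= N; ++m) {
    for (int l = m + 2; l <= N; ++l) {
      double ll = (double)l, mm = (double)m;
      double a = std::sqrt((4.0 * ll * ll - 1.0) / (ll * ll - mm * mm));
      double b = std::sqrt(((ll - 1.0) * (ll - 1.0) - mm * mm) /
                           (4.0 * (ll - 1.0) * (ll - 1.0) - 1.0));
      P[l * stride + m] = a * (x * P[(l - 1) * stride + m] - b * P[(l - 2) * stride + m]);
    }
  }
}

// Fill one basis row for a single direction. row must have (N+1)^2 entries.
// Column layout: degree tau occupies columns tau^2 .. tau^2 + 2*tau (0-based),
// ordered by beta = -tau ... tau.
template <typename T>
static void sh_row(int N, double theta, double phi, std::vector<double> &P,
                   std::vector<double> &cosb, std::vector<double> &sinb, T *row) {
  const int stride = N + 1;
  legendre_bar(N, std::cos(theta), std::sin(theta), P);
  cosb[0] = 1.0; sinb[0] = 0.0;
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int m = 1; m <= N; ++m) {
    cosb[m] = cosb[m - 1] * cp - sinb[m - 1] * sp;
    sinb[m] = sinb[m - 1] * cp + cosb[m - 1] * sp;
  }
  const double s2 = std::sqrt(2.0);
  for (int l = 0; l <= N; ++l) {
    int base = l * l + l; // column of beta = 0
    row[base] = (T)P[l * stride];
    for (int m = 1; m <= l; ++m) {
      double p = P[l * stride + m];
      row[base + m] = (T)(s2 * p * cosb[m]);
      row[base - m] = (T)(s2 * p * sinb[m]);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sh_basis(NumericVector theta, NumericVector phi, int N) {
  int m = theta.size(), n = (N + 1) * (N + 1);
  NumericMatrix B(m, n);
  std::vector<double> P((N + 1) * (N + 1)), cb(N + 1), sb(N + 1), row(n);
  for (int i = 0; i < m; ++i) {
    sh_row<double>(N, theta[i], phi[i], P, cb, sb, row.data());
    for (int j = 0; j < n; ++j) B(i, j) = row[j];
  }
  return B;
}

// [[Rcpp::export]]
NumericVector cpp_sh_eval(NumericVector theta, NumericVector phi,
                          NumericVector coef, int N) {
  int m = theta.size(), n = (N + 1) * (N + 1);
  if (coef.size() != n) stop("coefficient length must be (N+1)^2");
  NumericVector out(m);
  std::vector<double> P((N + 1) * (N + 1)), cb(N + 1), sb(N + 1), row(n);
  for (int i = 0; i < m; ++i) {
    sh_row<double>(N, theta[i], phi[i], P, cb, sb, row.data());
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += row[j] * coef[j];
    out[i] = acc;
  }
  return out;
}

// Direct BLAS/LAPACK bindings in both precisions (OpenBLAS provides all).
extern "C" {
  void dsyrk_(const char*, const char*, const int*, const int*, const double*,
              const double*, const int*, const double*, double*, const int*);
  void ssyrk_(const char*, const char*, const int*, const int*, const float*,
              const float*, const int*, const float*, float*, const int*);
  void dpotrf_(const char*, const int*, double*, const int*, int*);
  void spotrf_(const char*, const int*, float*, const int*, int*);
  void dgemv_(const char*, const int*, const int*, const double*, const double*,
              const int*, const double*, const int*, const double*, double*, const int*);
  void sgemv_(const char*, const int*, const int*, const float*, const float*,
              const int*, const float*, const int*, const float*, float*, const int*);
  void dtrsv_(const char*, const char*, const char*, const int*, const double*,
              const int*, double*, const int*);
  void strsv_(const char*, const char*, const char*, const int*, const float*,
              const int*, float*, const int*);
}
// C = A'A for A (k x n column-major, lda = k), upper triangle
static void xsyrk(int n, int k, const double *a, double *c) {
  const double one = 1.0, zero = 0.0;
  dsyrk_("U", "T", &n, &k, &one, a, &k, &zero, c, &n);
}
static void xsyrk(int n, int k, const float *a, float *c) {
  const float one = 1.0f, zero = 0.0f;
  ssyrk_("U", "T", &n, &k, &one, a, &k, &zero, c, &n);
}
static int xpotrf(int n, double *a) { int info; dpotrf_("U", &n, a, &n, &info); return info; }
static int xpotrf(int n, float *a) { int info; spotrf_("U", &n, a, &n, &info); return info; }
// y = B'x for B (m x n column-major)
static void xgemtv(int m, int n, const double *a, const double *x, double *y) {
  const double one = 1.0, zero = 0.0; const int ione = 1;
  dgemv_("T", &m, &n, &one, a, &m, x, &ione, &zero, y, &ione);
}
static void xgemtv(int m, int n, const float *a, const float *x, float *y) {
  const float one = 1.0f, zero = 0.0f; const int ione = 1;
  sgemv_("T", &m, &n, &one, a, &m, x, &ione, &zero, y, &ione);
}
static void xtrsv(const char *trans, int n, const double *a, double *x) {
  const int ione = 1; dtrsv_("U", trans, "N", &n, a, &n, x, &ione);
}
static void xtrsv(const char *trans, int n, const float *a, float *x) {
  const int ione = 1; strsv_("U", trans, "N", &n, a, &n, x, &ione);
}

// Nested least-squares SH fit via normal equations + Cholesky.  With columns
// ordered by ascending degree, the partial sums of the squared forward-solve
// give the residual sum of squares of every truncated (nested) model from one
// factorization: RSS_p = y'y - sum_{i<=p} z_i^2, z = L^{-1} B'y, G = L L'
// (here computed with the upper factor, G = R'R, z = R'^{-1} B'y).
template <typename T>
static List nested_fit_impl(const arma::vec &theta, const arma::vec &phi,
                            const arma::vec &r, int N, double ridge) {
  int m = theta.n_elem, n = (N + 1) * (N + 1);
  // fill the m x n column-major design in 64-point strips: rows are built
  // contiguously, then block-transposed so the scattered writes amortize to
  // full cache lines per column
  std::vector<T> B((size_t)m * n);
  {
    const int STRIP = 64;
    std::vector<double> P((N + 1) * (N + 1)), cb(N + 1), sb(N + 1);
    std::vector<T> strip((size_t)STRIP * n);
    for (int i0 = 0; i0 < m; i0 += STRIP) {
      int len = std::min(STRIP, m - i0);
      for (int t = 0; t < len; ++t) {
        sh_row<T>(N, theta[i0 + t], phi[i0 + t], P, cb, sb, strip.data() + (size_t)t * n);
      }
      for (int j = 0; j < n; ++j) {
        T *col = B.data() + (size_t)j * m + i0;
        for (int t = 0; t < len; ++t) col[t] = strip[(size_t)t * n + j];
      }
    }
  }
  std::vector<T> y(m);
  for (int i = 0; i < m; ++i) y[i] = (T)r[i];
  std::vector<T> G((size_t)n * n), b(n);
  // BLAS expects A as k x n with lda = k for "T": our B (m x n, ld m) fits
  xsyrk(n, m, B.data(), G.data());
  xgemtv(m, n, B.data(), y.data(), b.data());
  B.clear(); B.shrink_to_fit();
  double scale = 0.0;
  for (int j = 0; j < n; ++j) scale += (double)G[(size_t)j * n + j];
  scale /= n;
  // a ridge below the working precision cannot stabilize the factorization;
  // floor it at ~50 ulp of the diagonal scale
  double eps_T = (sizeof(T) == 4) ? 6e-8 : 1.1e-16;
  double lam = std::max(ridge, 50.0 * eps_T * scale);
  std::vector<T> R;
  bool ok = false;
  for (int attempt = 0; attempt < 8 && !ok; ++attempt) {
    R = G;
    for (int j = 0; j < n; ++j) R[(size_t)j * n + j] += (T)lam;
    ok = (xpotrf(n, R.data()) == 0);
    if (!ok) lam = (lam <= 0.0 ? 1e-12 * scale : lam * 100.0);
  }
  if (!ok) stop("spherical-harmonic normal equations are singular");
  std::vector<T> z(b);
  xtrsv("T", n, R.data(), z.data()); // R' z = b
  std::vector<T> coef(z);
  xtrsv("N", n, R.data(), coef.data()); // R coef = z
  double yty = arma::dot(r, r);
  NumericVector rss(N + 1);
  double acc = 0.0;
  int j = 0;
  for (int k = 0; k <= N; ++k) {
    int pk = (k + 1) * (k + 1);
    for (; j < pk; ++j) acc += (double)z[j] * (double)z[j];
    double v = yty - acc;
    rss[k] = v > 0.0 ? v : 0.0;
  }
  // running-sum construction already implies monotone non-increasing RSS up
  // to the clamp; make it explicit
  for (int k = 1; k <= N; ++k) if (rss[k] > rss[k - 1]) rss[k] = rss[k - 1];
  NumericVector coef_out(n);
  for (int i = 0; i < n; ++i) coef_out[i] = (double)coef[i];
  return List::create(_["coefficients"] = coef_out,
                      _["rss"] = rss, _["yty"] = yty, _["ridge_used"] = lam);
}

// [[Rcpp::export]]
List cpp_sh_nested_fit(arma::vec theta, arma::vec phi, arma::vec r, int N,
                       double ridge, bool single_prec) {
  if (single_prec) return nested_fit_impl<float>(theta, phi, r, N, ridge);
  return nested_fit_impl<double>(theta, phi, r, N, ridge);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a binary lattice (values at voxel centers, iso 0.5).
// Each cube of 8 neighboring voxel centers is split into 6 tetrahedra sharing
// the main diagonal; crossing edges get a vertex at the edge midpoint.  The
// decomposition has no ambiguous configurations, so the surface is watertight.

static inline int64_t edge_key(int64_t a, int64_t b) {
  if (a > b) std::swap(a, b);
  return a * 2000000000LL + b; // corner ids < 2^30 in practice
}

// [[Rcpp::export]]
List cpp_mesh_from_mask(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *v = LOGICAL(mask);
  auto val = [&](int x, int y, int z) -> int {
    return v[(int64_t)x + (int64_t)nx * (y + (int64_t)ny * z)] != 0;
  };
  auto gid = [&](int x, int y, int z) -> int64_t {
    return (int64_t)x + (int64_t)nx * (y + (int64_t)ny * z);
  };
  // cube corner offsets, bit order (x,y,z)
  static const int off[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                                {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {{0,1,3,7},{0,3,2,7},{0,2,6,7},
                                 {0,6,4,7},{0,4,5,7},{0,5,1,7}};
  std::unordered_map<int64_t, int> vmap;
  vmap.reserve(1 << 16);
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;
  F.reserve(1 << 17);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  auto vertex_on = [&](int64_t ga, int64_t gb, const double *pa, const double *pb) -> int {
    int64_t key = edge_key(ga, gb);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)VX.size();
    vmap.emplace(key, id);
    VX.push_back(0.5 * (pa[0] + pb[0]) * sx);
    VY.push_back(0.5 * (pa[1] + pb[1]) * sy);
    VZ.push_back(0.5 * (pa[2] + pb[2]) * sz);
    return id;
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int cv[8];
        int64_t cg[8];
        double cp[8][3];
        int sum = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = x + off[c][0], cy = y + off[c][1], cz = z + off[c][2];
          cv[c] = val(cx, cy, cz);
          cg[c] = gid(cx, cy, cz);
          cp[c][0] = cx; cp[c][1] = cy; cp[c][2] = cz;
          sum += cv[c];
        }
        if (sum == 0 || sum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T4 = tets[t];
          int in[4], ni = 0, nin = 0;
          int out4[4], no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T4[c]]) { in[ni++] = T4[c]; ++nin; }
            else out4[no++] = T4[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int a = in[0];
            int p1 = vertex_on(cg[a], cg[out4[0]], cp[a], cp[out4[0]]);
            int p2 = vertex_on(cg[a], cg[out4[1]], cp[a], cp[out4[1]]);
            int p3 = vertex_on(cg[a], cg[out4[2]], cp[a], cp[out4[2]]);
            F.push_back(p1); F.push_back(p2); F.push_back(p3);
          } else if (nin == 3) {
            int a = out4[0];
            int p1 = vertex_on(cg[a], cg[in[0]], cp[a], cp[in[0]]);
            int p2 = vertex_on(cg[a], cg[in[1]], cp[a], cp[in[1]]);
            int p3 = vertex_on(cg[a], cg[in[2]], cp[a], cp[in[2]]);
            F.push_back(p1); F.push_back(p2); F.push_back(p3);
          } else { // 2 in, 2 out -> quad
            int a = in[0], b = in[1], c = out4[0], d = out4[1];
            int p1 = vertex_on(cg[a], cg[c], cp[a], cp[c]);
            int p2 = vertex_on(cg[a], cg[d], cp[a], cp[d]);
            int p3 = vertex_on(cg[b], cg[d], cp[b], cp[d]);
            int p4 = vertex_on(cg[b], cg[c], cp[b], cp[c]);
            F.push_back(p1); F.push_back(p2); F.push_back(p3);
            F.push_back(p1); F.push_back(p3); F.push_back(p4);
          }
        }
      }
  int nv = VX.size(), nf = F.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0)=VX[i]; V(i,1)=VY[i]; V(i,2)=VZ[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i,0)=F[3*i]+1; Fm(i,1)=F[3*i+1]+1; Fm(i,2)=F[3*i+2]+1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// 26-connected component count of the foreground.
// [[Rcpp::export]]
int cpp_n_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int64_t n = (int64_t)nx * ny * nz;
  const int *v = LOGICAL(mask);
  std::vector<char> seen(n, 0);
  int comps = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (!v[s] || seen[s]) continue;
    ++comps;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((int64_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            int64_t q = X + (int64_t)nx * (Y + (int64_t)ny * Z);
            if (v[q] && !seen[q]) { seen[q] = 1; stack.push_back(q); }
          }
    }
  }
  return comps;
}

// Morphological closing with a 3x3x3 box (outside treated as background).
// [[Rcpp::export]]
LogicalVector cpp_closing(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int64_t n = (int64_t)nx * ny * nz;
  const int *v = LOGICAL(mask);
  std::vector<char> dil(n, 0);
  auto at = [&](const auto &a, int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return a[x + (int64_t)nx * (y + (int64_t)ny * z)] != 0;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int hit = 0;
        for (int dz = -1; dz <= 1 && !hit; ++dz)
          for (int dy = -1; dy <= 1 && !hit; ++dy)
            for (int dx = -1; dx <= 1 && !hit; ++dx)
              if (at(v, x + dx, y + dy, z + dz)) hit = 1;
        dil[x + (int64_t)nx * (y + (int64_t)ny * z)] = hit;
      }
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int all = 1;
        for (int dz = -1; dz <= 1 && all; ++dz)
          for (int dy = -1; dy <= 1 && all; ++dy)
            for (int dx = -1; dx <= 1 && all; ++dx)
              if (!at(dil, x + dx, y + dy, z + dz)) all = 0;
        out[x + (int64_t)nx * (y + (int64_t)ny * z)] = all;
      }
  out.attr("dim") = dim;
  return out;
}

// Foreground voxel with maximal chamfer distance to the background
// (multi-source BFS, 26-neighborhood).  1-based voxel index.
// [[Rcpp::export]]
IntegerVector cpp_interior_point(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int64_t n = (int64_t)nx * ny * nz;
  const int *v = LOGICAL(mask);
  std::vector<int> dist(n, -1);
  std::queue<int64_t> q;
  for (int64_t s = 0; s < n; ++s) {
    if (v[s]) continue;
    dist[s] = 0;
    q.push(s);
  }
  // voxels on the volume border count as touching background
  int64_t best = -1; int bestd = -1;
  while (!q.empty()) {
    int64_t cur = q.front(); q.pop();
    int x = cur % nx, y = (cur / nx) % ny, z = cur / ((int64_t)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
          int64_t p = X + (int64_t)nx * (Y + (int64_t)ny * Z);
          if (dist[p] < 0) {
            dist[p] = dist[cur] + 1;
            q.push(p);
          }
        }
  }
  for (int64_t s = 0; s < n; ++s)
    if (v[s] && dist[s] > bestd) { bestd = dist[s]; best = s; }
  if (best < 0) stop("mask has no foreground voxel");
  int x = best % nx, y = (best / nx) % ny, z = best / ((int64_t)nx * ny);
  return IntegerVector::create(x + 1, y + 1, z + 1);
}

// ---------------------------------------------------------------------------
// Attraction step (Eq. 1).  nbr_ptr/nbr_idx is a 0-based CSR adjacency.
// product form: force_j = d*||d||^2 + ca2 * d/||d||
// quotient form: force_j = d/||d||^2 + ca2 * d/||d||
// [[Rcpp::export]]
List cpp_attraction(NumericMatrix C, IntegerVector nbr_ptr, IntegerVector nbr_idx,
                    double ca1, double ca2, bool product) {
  int I = C.nrow();
  NumericMatrix out(I, 3);
  int skipped = 0;
  for (int i = 0; i < I; ++i) {
    double fx = 0, fy = 0, fz = 0;
    for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; ++k) {
      int j = nbr_idx[k];
      double dx = C(j,0) - C(i,0), dy = C(j,1) - C(i,1), dz = C(j,2) - C(i,2);
      double n2 = dx*dx + dy*dy + dz*dz;
      if (n2 < 1e-24) { ++skipped; continue; }
      double nn = std::sqrt(n2);
      double w = product ? n2 : 1.0 / n2;
      double w2 = ca2 / nn;
      fx += dx * w + dx * w2;
      fy += dy * w + dy * w2;
      fz += dz * w + dz * w2;
    }
    out(i,0) = C(i,0) + ca1 * fx;
    out(i,1) = C(i,1) + ca1 * fy;
    out(i,2) = C(i,2) + ca1 * fz;
  }
  return List::create(_["coords"] = out, _["skipped"] = skipped);
}

// Repulsion step (Eq. 2, repulsive sign): all-pairs inverse-square push.
// [[Rcpp::export]]
List cpp_repulsion(NumericMatrix C, double cr) {
  int I = C.nrow();
  std::vector<double> dx_(I, 0.0), dy_(I, 0.0), dz_(I, 0.0);
  std::vector<double> X(I), Y(I), Z(I);
  for (int i = 0; i < I; ++i) { X[i]=C(i,0); Y[i]=C(i,1); Z[i]=C(i,2); }
  int skipped = 0;
  for (int i = 0; i < I; ++i) {
    double xi = X[i], yi = Y[i], zi = Z[i];
    double ax = 0, ay = 0, az = 0;
    for (int j = i + 1; j < I; ++j) {
      double dx = xi - X[j], dy = yi - Y[j], dz = zi - Z[j];
      double n2 = dx*dx + dy*dy + dz*dz;
      if (n2 < 1e-24) { ++skipped; continue; }
      double w = 1.0 / n2;
      dx *= w; dy *= w; dz *= w;
      ax += dx; ay += dy; az += dz;
      dx_[j] -= dx; dy_[j] -= dy; dz_[j] -= dz;
    }
    dx_[i] += ax; dy_[i] += ay; dz_[i] += az;
  }
  double f = cr / (2.0 * I);
  NumericMatrix out(I, 3);
  for (int i = 0; i < I; ++i) {
    out(i,0) = X[i] + f * dx_[i];
    out(i,1) = Y[i] + f * dy_[i];
    out(i,2) = Z[i] + f * dz_[i];
  }
  return List::create(_["coords"] = out, _["skipped"] = skipped);
}

// ---------------------------------------------------------------------------
// GLCM accumulation.  g: stretched gray levels 0..255 inside the mask, -1
// outside.  offsets: K x 3 integer half-neighborhood; each in-mask pair
// contributes symmetrically to (a,b) and (b,a).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector g, IntegerVector dim, IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *gv = INTEGER(g);
  int K = offsets.nrow();
  NumericMatrix counts(256, 256);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = gv[x + (int64_t)nx * (y + (int64_t)ny * z)];
        if (a < 0) continue;
        for (int k = 0; k < K; ++k) {
          int X = x + offsets(k,0), Y = y + offsets(k,1), Z = z + offsets(k,2);
          if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
          int b = gv[X + (int64_t)nx * (Y + (int64_t)ny * Z)];
          if (b < 0) continue;
          counts(a,b) += 1.0;
          counts(b,a) += 1.0;
        }
      }
  return counts;
}

// ---------------------------------------------------------------------------
// Voxelize a star-shaped region with SH radius function r(theta,phi) given by
// coef (degree N, same layout as cpp_sh_basis), centered at `center` (mm).
// [[Rcpp::export]]
LogicalVector cpp_radial_mask(IntegerVector dim, NumericVector spacing,
                              NumericVector center, NumericVector coef, int N,
                              double rmax_bound, double rmin_clamp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int64_t n = (int64_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<double> P((N + 1) * (N + 1)), cb(N + 1), sb(N + 1), row((N + 1) * (N + 1));
  int nc = (N + 1) * (N + 1);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double px = x * spacing[0] - center[0];
        double py = y * spacing[1] - center[1];
        double pz = z * spacing[2] - center[2];
        double rho = std::sqrt(px*px + py*py + pz*pz);
        int64_t at = x + (int64_t)nx * (y + (int64_t)ny * z);
        if (rho > rmax_bound) { out[at] = FALSE; continue; }
        if (rho < 1e-9) { out[at] = TRUE; continue; }
        double theta = std::acos(std::min(1.0, std::max(-1.0, pz / rho)));
        double phi = std::atan2(py, px);
        sh_row<double>(N, theta, phi, P, cb, sb, row.data());
        double r = 0.0;
        for (int j = 0; j < nc; ++j) r += row[j] * coef[j];
        if (r < rmin_clamp) r = rmin_clamp;
        out[at] = (rho <= r);
      }
  out.attr("dim") = dim;
  return out;
}
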