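// Scattered-data local polynomial kernel regression on 3D point clouds,
// evaluated either on a regular voxel grid or at arbitrary query points,
// plus nearest-neighbour search used by the interpolation baseline and the
// bandwidth heuristic. A uniform cell table (cell edge >= truncation radius)
// gives the O(P) build / O(k) query neighbourhood gathers; within a cell,
// points keep ascending input order so neighbour sets are deterministic.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <algorithm>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int basis_size(int order) { return order == 0 ? 1 : (order == 1 ? 4 : 10); }

// Monomials of (dx, dy, dz) up to `order`, in the documented column order:
// 1, dx, dy, dz, dx^2, dx*dy, dx*dz, dy^2, dy*dz, dz^2.
inline void fill_basis(double dx, double dy, double dz, int order, double* b) {
  b[0] = 1.0;
  if (order >= 1) { b[1] = dx; b[2] = dy; b[3] = dz; }
  if (order >= 2) {
    b[4] = dx * dx; b[5] = dx * dy; b[6] = dx * dz;
    b[7] = dy * dy; b[8] = dy * dz; b[9] = dz * dz;
  }
}

struct CellIndex {
  int P;
  double cell;
  double lo[3];
  int nc[3];
  std::vector<int> start;   // CSR offsets per cell
  std::vector<int> pt;      // point indices grouped by cell, ascending within cell
  const double *px, *py, *pz;

  void build(const NumericMatrix& pts, double cell_len) {
    P = pts.nrow();
    px = &pts(0, 0); py = &pts(0, 1); pz = &pts(0, 2);
    double hi[3];
    for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
    for (int i = 0; i < P; ++i) {
      lo[0] = std::min(lo[0], px[i]); hi[0] = std::max(hi[0], px[i]);
      lo[1] = std::min(lo[1], py[i]); hi[1] = std::max(hi[1], py[i]);
      lo[2] = std::min(lo[2], pz[i]); hi[2] = std::max(hi[2], pz[i]);
    }
    double maxext = 0.0;
    for (int a = 0; a < 3; ++a) maxext = std::max(maxext, hi[a] - lo[a]);
    // cap the table at ~256 cells per axis so tiny bandwidths stay bounded
    cell = std::max(cell_len, maxext / 256.0);
    if (!(cell > 0.0) || !R_finite(cell)) cell = 1.0;
    long long tot = 1;
    for (int a = 0; a < 3; ++a) {
      nc[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
      tot *= nc[a];
    }
    std::vector<int> cid(P);
    std::vector<int> cnt((size_t)tot + 1, 0);
    for (int i = 0; i < P; ++i) {
      int cx = coord(px[i], 0), cy = coord(py[i], 1), cz = coord(pz[i], 2);
      cid[i] = cx + nc[0] * (cy + (long long)nc[1] * cz);
      cnt[cid[i] + 1]++;
    }
    start.assign((size_t)tot + 1, 0);
    for (long long c = 0; c < tot; ++c) start[c + 1] = start[c] + cnt[c + 1];
    pt.assign(P, 0);
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int i = 0; i < P; ++i) pt[cur[cid[i]]++] = i;
  }

  inline int coord(double x, int a) const {
    int c = (int)std::floor((x - lo[a]) / cell);
    if (c < 0) c = 0;
    if (c >= nc[a]) c = nc[a] - 1;
    return c;
  }

  void gather(const double q[3], double r, double r2,
              std::vector<int>& idx, std::vector<double>& d2s) const {
    idx.clear(); d2s.clear();
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      double qa = (a == 0 ? q[0] : (a == 1 ? q[1] : q[2]));
      c0[a] = std::max(0, (int)std::floor((qa - r - lo[a]) / cell));
      c1[a] = std::min(nc[a] - 1, (int)std::floor((qa + r - lo[a]) / cell));
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx) {
          long long c = cx + (long long)nc[0] * (cy + (long long)nc[1] * cz);
          for (int s = start[c]; s < start[c + 1]; ++s) {
            int i = pt[s];
            double dx = px[i] - q[0], dy = py[i] - q[1], dz = pz[i] - q[2];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= r2) { idx.push_back(i); d2s.push_back(d2); }
          }
        }
  }

  // Nearest point to q (optionally excluding one index), expanding-ring
  // search with index-order tie breaking; returns -1 only when P == 0
  // (or P == 1 with that point excluded).
  int nearest(const double q[3], int exclude) const {
    int cx = coord(q[0], 0), cy = coord(q[1], 1), cz = coord(q[2], 2);
    int best = -1;
    double bestd2 = R_PosInf;
    int rmax = std::max(std::max(nc[0], nc[1]), nc[2]) + 1;
    for (int rr = 0; rr <= rmax; ++rr) {
      if (best >= 0) {
        double lb = (double)(rr - 1) * cell;
        if (lb > 0 && lb * lb > bestd2) break;
      }
      for (int dz = -rr; dz <= rr; ++dz) {
        int z = cz + dz;
        if (z < 0 || z >= nc[2]) continue;
        for (int dy = -rr; dy <= rr; ++dy) {
          int y = cy + dy;
          if (y < 0 || y >= nc[1]) continue;
          bool face = (std::abs(dz) == rr) || (std::abs(dy) == rr);
          int stepx = face ? 1 : 2 * rr;
          if (stepx == 0) stepx = 1;
          for (int dx = -rr; dx <= rr; dx += stepx) {
            int x = cx + dx;
            if (x < 0 || x >= nc[0]) continue;
            long long c = x + (long long)nc[0] * (y + (long long)nc[1] * z);
            for (int s = start[c]; s < start[c + 1]; ++s) {
              int i = pt[s];
              if (i == exclude) continue;
              double ddx = px[i] - q[0], ddy = py[i] - q[1], ddz = pz[i] - q[2];
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < bestd2 || (d2 == bestd2 && i < best)) { bestd2 = d2; best = i; }
            }
          }
        }
      }
    }
    return best;
  }
};

// cell edge for pure NN searches: ~2 mean inter-point spacings
double density_cell(const NumericMatrix& pts) {
  int P = pts.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < P; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], pts(i, a));
      hi[a] = std::max(hi[a], pts(i, a));
    }
  double vol = 1.0, maxext = 0.0;
  for (int a = 0; a < 3; ++a) {
    double e = hi[a] - lo[a];
    maxext = std::max(maxext, e);
    vol *= std::max(e, 1e-12);
  }
  double c = 2.0 * std::cbrt(vol / std::max(P, 1));
  c = std::max(c, maxext / 256.0);
  if (!(c > 0.0) || !R_finite(c)) c = 1.0;
  return c;
}

struct KrWorker {
  const CellIndex* ci;
  const double* vals;
  double r, r2, inv2h2, ridge_eps;
  int order, min_neighbors;
  std::vector<int> nbr;
  std::vector<double> d2s;

  double estimate(const double q[3], int* n_used, int* order_used) {
    ci->gather(q, r, r2, nbr, d2s);
    int n = (int)nbr.size();
    *n_used = n;
    *order_used = NA_INTEGER;
    if (n == 0) return NA_REAL;
    // sparse-neighbourhood fallback: degrade 2 -> 1 -> 0
    int eff = order;
    while (eff > 0 && n < std::max(min_neighbors, basis_size(eff) + 2)) --eff;
    int k = basis_size(eff);
    double M[100], v[10], b[10];
    std::fill(M, M + k * k, 0.0);
    std::fill(v, v + k, 0.0);
    for (int s = 0; s < n; ++s) {
      int i = nbr[s];
      double w = std::exp(-d2s[s] * inv2h2);
      fill_basis(ci->px[i] - q[0], ci->py[i] - q[1], ci->pz[i] - q[2], eff, b);
      double wy = w * vals[i];
      for (int a = 0; a < k; ++a) {
        v[a] += b[a] * wy;
        double wba = w * b[a];
        for (int c = a; c < k; ++c) M[a * k + c] += wba * b[c];
      }
    }
    for (int a = 0; a < k; ++a)
      for (int c = 0; c < a; ++c) M[a * k + c] = M[c * k + a];
    arma::mat Mm(&M[0], k, k, false, true);
    arma::vec vv(&v[0], k, false, true);
    arma::vec beta;
    bool ok = arma::solve(beta, Mm, vv, arma::solve_opts::no_approx);
    if (!ok || !beta.is_finite()) {
      // rank-deficient neighbourhood: ridge on the normal equations
      double eps = (ridge_eps > 0 ? ridge_eps : 1e-10) * arma::trace(Mm);
      arma::mat M2 = Mm;
      M2.diag() += eps;
      ok = arma::solve(beta, M2, vv, arma::solve_opts::no_approx);
      if (!ok || !beta.is_finite()) return NA_REAL;
    }
    *order_used = eff;
    return beta(0);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_kr_query(NumericMatrix pts, NumericVector vals, NumericMatrix query,
                  double h, int order, double support_factor, int min_neighbors,
                  double ridge_eps) {
  CellIndex ci;
  double r = support_factor * h;
  ci.build(pts, r);
  KrWorker w;
  w.ci = &ci; w.vals = REAL(vals);
  w.r = r; w.r2 = r * r; w.inv2h2 = 1.0 / (2.0 * h * h);
  w.ridge_eps = ridge_eps; w.order = order; w.min_neighbors = min_neighbors;
  int m = query.nrow();
  NumericVector est(m);
  IntegerVector nused(m), oused(m);
  for (int j = 0; j < m; ++j) {
    double q[3] = {query(j, 0), query(j, 1), query(j, 2)};
    int nu, ou;
    est[j] = w.estimate(q, &nu, &ou);
    nused[j] = nu;
    oused[j] = ou;
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["estimate"] = est, _["n_used"] = nused,
                      _["order_used"] = oused);
}

// [[Rcpp::export]]
List cpp_kr_grid(NumericMatrix pts, NumericVector vals, NumericVector origin,
                 NumericVector spacing, IntegerVector dims, double h, int order,
                 double support_factor, int min_neighbors, double ridge_eps) {
  CellIndex ci;
  double r = support_factor * h;
  ci.build(pts, r);
  KrWorker w;
  w.ci = &ci; w.vals = REAL(vals);
  w.r = r; w.r2 = r * r; w.inv2h2 = 1.0 / (2.0 * h * h);
  w.ridge_eps = ridge_eps; w.order = order; w.min_neighbors = min_neighbors;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector est(nvox);
  IntegerVector nused(nvox), oused(nvox);
  R_xlen_t p = 0;
  for (int kz = 0; kz < nz; ++kz) {
    Rcpp::checkUserInterrupt();
    double qz = origin[2] + kz * spacing[2];
    for (int jy = 0; jy < ny; ++jy) {
      double qy = origin[1] + jy * spacing[1];
      for (int ix = 0; ix < nx; ++ix, ++p) {
        double q[3] = {origin[0] + ix * spacing[0], qy, qz};
        int nu, ou;
        est[p] = w.estimate(q, &nu, &ou);
        nused[p] = nu;
        oused[p] = ou;
      }
    }
  }
  return List::create(_["estimate"] = est, _["n_used"] = nused,
                      _["order_used"] = oused);
}

// [[Rcpp::export]]
NumericVector cpp_nn_grid(NumericMatrix pts, NumericVector vals,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector dims) {
  CellIndex ci;
  ci.build(pts, density_cell(pts));
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  R_xlen_t p = 0;
  for (int kz = 0; kz < nz; ++kz) {
    Rcpp::checkUserInterrupt();
    double qz = origin[2] + kz * spacing[2];
    for (int jy = 0; jy < ny; ++jy) {
      double qy = origin[1] + jy * spacing[1];
      for (int ix = 0; ix < nx; ++ix, ++p) {
        double q[3] = {origin[0] + ix * spacing[0], qy, qz};
        int i = ci.nearest(q, -1);
        out[p] = (i >= 0) ? vals[i] : NA_REAL;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_nn_query(NumericMatrix pts, NumericMatrix query) {
  CellIndex ci;
  ci.build(pts, density_cell(pts));
  int m = query.nrow();
  IntegerVector out(m);
  for (int j = 0; j < m; ++j) {
    double q[3] = {query(j, 0), query(j, 1), query(j, 2)};
    int i = ci.nearest(q, -1);
    out[j] = (i >= 0) ? i + 1 : NA_INTEGER;  // 1-based for R
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix pts) {
  CellIndex ci;
  ci.build(pts, density_cell(pts));
  int P = pts.nrow();
  NumericVector out(P);
  for (int j = 0; j < P; ++j) {
    double q[3] = {pts(j, 0), pts(j, 1), pts(j, 2)};
    int i = ci.nearest(q, j);
    if (i >= 0) {
      double dx = pts(i, 0) - q[0], dy = pts(i, 1) - q[1], dz = pts(i, 2) - q[2];
      out[j] = std::sqrt(dx * dx + dy * dy + dz * dz);
    } else {
      out[j] = NA_REAL;
    }
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
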