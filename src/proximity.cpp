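#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Capped nearest-neighbour Euclidean distances from each query point to the
// closest target point, using a uniform grid with an expanding ring search.
// Targets farther than `cap`, or an empty target set, yield exactly `cap`.
// Distances are sqrt((qx-tx)^2 + (qy-ty)^2), bit-identical to a brute-force
// scan (same IEEE operations; the grid only prunes candidates).
// [[Rcpp::export(name = ".nn_capped_cpp")]]
NumericVector nn_capped_cpp(NumericVector qx, NumericVector qy,
                            NumericVector tx, NumericVector ty,
                            double cap) {
  const int nq = qx.size(), nt = tx.size();
  NumericVector out(nq, cap);
  if (nt == 0 || nq == 0) return out;

  double xmin = tx[0], xmax = tx[0], ymin = ty[0], ymax = ty[0];
  for (int j = 1; j < nt; ++j) {
    xmin = std::min(xmin, tx[j]); xmax = std::max(xmax, tx[j]);
    ymin = std::min(ymin, ty[j]); ymax = std::max(ymax, ty[j]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  double h = span > 0 ? span / std::max(1.0, std::sqrt((double) nt)) : 1.0;
  if (!(h > 0)) h = 1.0;
  const int nx = (int) std::floor((xmax - xmin) / h) + 1;
  const int ny = (int) std::floor((ymax - ymin) / h) + 1;

  std::vector<int> head((size_t) nx * ny, -1), nxt(nt);
  for (int j = 0; j < nt; ++j) {
    int bi = (int) ((tx[j] - xmin) / h); if (bi >= nx) bi = nx - 1; if (bi < 0) bi = 0;
    int bj = (int) ((ty[j] - ymin) / h); if (bj >= ny) bj = ny - 1; if (bj < 0) bj = 0;
    size_t b = (size_t) bj * nx + bi;
    nxt[j] = head[b]; head[b] = j;
  }

  // rings beyond cap/h never hold a candidate closer than cap; +2 covers the
  // query's own partial bucket and rounding
  const int rmax = (int) (cap / h) + nx + ny + 2;

  for (int i = 0; i < nq; ++i) {
    double best2 = cap * cap;
    bool found = false;
    const int bi = (int) std::floor((qx[i] - xmin) / h);
    const int bj = (int) std::floor((qy[i] - ymin) / h);
    for (int r = 0; r <= rmax; ++r) {
      if (r > 0) {
        // any point in a bucket at Chebyshev ring r is at least (r-1)*h away
        double lb = (double) (r - 1) * h;
        if (lb * lb >= best2) break;
      }
      int i0 = std::max(bi - r, 0), i1 = std::min(bi + r, nx - 1);
      int j0 = std::max(bj - r, 0), j1 = std::min(bj + r, ny - 1);
      if (i0 > i1 || j0 > j1) continue;
      for (int cj = j0; cj <= j1; ++cj) {
        bool edge_row = (cj == bj - r || cj == bj + r);
        for (int ci = i0; ci <= i1; ++ci) {
          if (!edge_row && ci != bi - r && ci != bi + r) continue;
          for (int j = head[(size_t) cj * nx + ci]; j != -1; j = nxt[j]) {
            double dx = qx[i] - tx[j], dy = qy[i] - ty[j];
            double d2 = dx * dx + dy * dy;
            if (d2 < best2) { best2 = d2; found = true; }
          }
        }
      }
    }
    out[i] = found ? std::sqrt(best2) : cap;
  }
  return out;
}

// Permutation null of RD scores for one image under shared shuffles: each
// permutation shuffles the non-cancer type labels over the fixed non-cancer
// positions (Fisher-Yates on R's RNG, so set.seed() governs it) and scores
// every requested pair on that same shuffle.
//
// D:        n_ref x n_noncancer matrix of capped distances (entries <= cap)
// type_id:  1-based label code per non-cancer cell; codes > n_types are
//           labels outside the pair universe (still shuffled, never scored)
// pair_x/y: 1-based type codes per requested pair
// Returns per-pair mean and sample sd of RD over n_perm shuffles
// (sd = 0 when n_perm == 1).
// [[Rcpp::export(name = ".rd_null_perm_cpp")]]
List rd_null_perm_cpp(NumericMatrix D, IntegerVector type_id, int n_types,
                      IntegerVector pair_x, IntegerVector pair_y,
                      int n_perm, double cap) {
  const int nc = D.nrow(), nn = D.ncol(), np = pair_x.size();
  const double *Dp = D.begin();
  std::vector<int> labels(type_id.begin(), type_id.end());
  std::vector<double> dmin((size_t) nc * n_types);
  std::vector<double> dbar(n_types);
  std::vector<double> sum(np, 0.0), sumsq(np, 0.0);

  for (int p = 0; p < n_perm; ++p) {
    for (int i = nn - 1; i > 0; --i) {
      int j = (int) (unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(labels[i], labels[j]);
    }
    // initialising at cap realises both the per-cell cap and the
    // absent-type -> dbar = cap rule in one pass
    std::fill(dmin.begin(), dmin.end(), cap);
    for (int j = 0; j < nn; ++j) {
      int t = labels[j] - 1;
      if (t < 0 || t >= n_types) continue;
      const double *col = Dp + (size_t) j * nc;
      double *dm = &dmin[(size_t) t * nc];
      for (int k = 0; k < nc; ++k) if (col[k] < dm[k]) dm[k] = col[k];
    }
    for (int t = 0; t < n_types; ++t) {
      double s = 0.0; const double *dm = &dmin[(size_t) t * nc];
      for (int k = 0; k < nc; ++k) s += dm[k];
      dbar[t] = s / nc;
    }
    for (int q = 0; q < np; ++q) {
      double dx = dbar[pair_x[q] - 1], dy = dbar[pair_y[q] - 1];
      double rd = dx / (dx + dy);
      sum[q] += rd; sumsq[q] += rd * rd;
    }
  }

  NumericVector m(np), s(np);
  for (int q = 0; q < np; ++q) {
    m[q] = sum[q] / n_perm;
    if (n_perm > 1) {
      double v = (sumsq[q] - sum[q] * sum[q] / n_perm) / (n_perm - 1);
      s[q] = v > 0 ? std::sqrt(v) : 0.0;
    } else {
      s[q] = 0.0;
    }
  }
  return List::create(_["mean_null"] = m, _["sd_null"] = s);
}
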