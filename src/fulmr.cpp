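#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stamp Gaussian point-spread echoes into a (nz, nx, nf) frame stack.
// Positions are in pixel units: pixel k covers [k, k+1), centre k + 0.5.
// [[Rcpp::export]]
NumericVector cpp_stamp_bubbles(int nz, int nx, int nf,
                                IntegerVector frame, NumericVector z_px,
                                NumericVector x_px, NumericVector amp,
                                double sigma_z_px, double sigma_x_px,
                                double halfwidth_sd) {
  NumericVector out(static_cast<R_xlen_t>(nz) * nx * nf);
  out.attr("dim") = IntegerVector::create(nz, nx, nf);
  const double hz = halfwidth_sd * sigma_z_px, hx = halfwidth_sd * sigma_x_px;
  for (R_xlen_t i = 0; i < frame.size(); ++i) {
    const int f = frame[i];
    if (f < 0 || f >= nf) continue;
    const double cz = z_px[i], cx = x_px[i], a = amp[i];
    int r0 = std::max(0, (int)std::floor(cz - hz - 0.5));
    int r1 = std::min(nz - 1, (int)std::ceil(cz + hz - 0.5));
    int c0 = std::max(0, (int)std::floor(cx - hx - 0.5));
    int c1 = std::min(nx - 1, (int)std::ceil(cx + hx - 0.5));
    const R_xlen_t base = static_cast<R_xlen_t>(f) * nz * nx;
    for (int c = c0; c <= c1; ++c) {
      const double dx = (c + 0.5 - cx) / sigma_x_px;
      const double ex = std::exp(-0.5 * dx * dx);
      for (int r = r0; r <= r1; ++r) {
        const double dz = (r + 0.5 - cz) / sigma_z_px;
        out[base + static_cast<R_xlen_t>(c) * nz + r] +=
          a * ex * std::exp(-0.5 * dz * dz);
      }
    }
  }
  return out;
}

// Supercover rasterization: every grid cell crossed by each segment,
// coordinates in cell units (cell k covers [k, k+1)). Returns 0-based
// (col, row) cells with the index of the generating segment (1-based).
// [[Rcpp::export]]
List cpp_supercover(NumericVector x0, NumericVector z0,
                    NumericVector x1, NumericVector z1,
                    int ncol_grid, int nrow_grid) {
  std::vector<int> seg, col, row;
  const double eps = 1e-12;
  for (R_xlen_t i = 0; i < x0.size(); ++i) {
    double ax = x0[i], az = z0[i], bx = x1[i], bz = z1[i];
    int cx = std::min(ncol_grid - 1, std::max(0, (int)std::floor(ax)));
    int cz = std::min(nrow_grid - 1, std::max(0, (int)std::floor(az)));
    const int ex = std::min(ncol_grid - 1, std::max(0, (int)std::floor(bx)));
    const int ez = std::min(nrow_grid - 1, std::max(0, (int)std::floor(bz)));
    const double dx = bx - ax, dz = bz - az;
    const int sx = dx > 0 ? 1 : -1, sz = dz > 0 ? 1 : -1;
    double tMaxX, tMaxZ, tDeltaX, tDeltaZ;
    if (std::fabs(dx) < eps) { tMaxX = R_PosInf; tDeltaX = R_PosInf; }
    else {
      const double nxb = sx > 0 ? (cx + 1 - ax) : (ax - cx);
      tMaxX = nxb / std::fabs(dx);
      tDeltaX = 1.0 / std::fabs(dx);
    }
    if (std::fabs(dz) < eps) { tMaxZ = R_PosInf; tDeltaZ = R_PosInf; }
    else {
      const double nzb = sz > 0 ? (cz + 1 - az) : (az - cz);
      tMaxZ = nzb / std::fabs(dz);
      tDeltaZ = 1.0 / std::fabs(dz);
    }
    seg.push_back(i + 1); col.push_back(cx); row.push_back(cz);
    int guard = 4 * (ncol_grid + nrow_grid);
    while ((cx != ex || cz != ez) && guard-- > 0) {
      if (tMaxX < tMaxZ) { cx += sx; tMaxX += tDeltaX; }
      else { cz += sz; tMaxZ += tDeltaZ; }
      if (cx < 0 || cx >= ncol_grid || cz < 0 || cz >= nrow_grid) break;
      seg.push_back(i + 1); col.push_back(cx); row.push_back(cz);
    }
  }
  return List::create(_["segment"] = wrap(seg), _["col"] = wrap(col),
                      _["row"] = wrap(row));
}

// Optimal rectangular assignment (shortest augmenting path with potentials,
// O(n^2 m)); requires nrow <= ncol. Returns, for each row, the 1-based
// assigned column.
// [[Rcpp::export]]
IntegerVector cpp_assignment(NumericMatrix a) {
  const int n = a.nrow(), m = a.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// Separable zero-normalized cross-correlation of every frame of a block
// with a Gaussian template outer(gz, gx), followed by 8-neighbourhood
// local-maxima detection with a correlation threshold and an amplitude
// gate. Returns peak positions (1-based), correlation, amplitude and the
// 3x3 correlation neighbourhood (dx fast within dy) for subpixel fitting.
// [[Rcpp::export]]
List cpp_zncc_peaks(NumericVector block, NumericVector gz, NumericVector gx,
                    double threshold, int border, double min_amp) {
  IntegerVector dims = block.attr("dim");
  const int nr = dims[0], nc = dims[1], nf = dims[2];
  const int lz = gz.size(), lx = gx.size();
  const int hz = lz / 2, hx = lx / 2;
  const double n_t = (double)lz * lx;
  double sz = 0, sx = 0, szz = 0, sxx = 0;
  for (int i = 0; i < lz; ++i) { sz += gz[i]; szz += gz[i] * gz[i]; }
  for (int i = 0; i < lx; ++i) { sx += gx[i]; sxx += gx[i] * gx[i]; }
  const double m_t = sz * sx / n_t;
  const double ss_t = szz * sxx - n_t * m_t * m_t;
  std::vector<double> tmp(nr * nc), ct(nr * nc), s1(nr * nc), s2(nr * nc),
      corr(nr * nc), colsum(nr * nc), colsum2(nr * nc);
  std::vector<int> pk_f, pk_r, pk_c;
  std::vector<double> pk_corr, pk_amp, pk_neigh;
  for (int f = 0; f < nf; ++f) {
    const double *fr = &block[(R_xlen_t)f * nr * nc];
    // vertical Gaussian pass
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double acc = 0;
        const int k0 = std::max(0, r - hz), k1 = std::min(nr - 1, r + hz);
        for (int k = k0; k <= k1; ++k) acc += gz[k - r + hz] * fr[c * nr + k];
        tmp[c * nr + r] = acc;
      }
    // horizontal Gaussian pass
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        double acc = 0;
        const int k0 = std::max(0, c - hx), k1 = std::min(nc - 1, c + hx);
        for (int k = k0; k <= k1; ++k) acc += gx[k - c + hx] * tmp[k * nr + r];
        ct[c * nr + r] = acc;
      }
    // box sums of f and f^2 (same support as the template)
    for (int c = 0; c < nc; ++c) {
      double run = 0, run2 = 0;
      for (int r = 0; r < nr; ++r) {
        run += fr[c * nr + r]; run2 += fr[c * nr + r] * fr[c * nr + r];
        if (r - lz >= 0) {
          run -= fr[c * nr + r - lz];
          run2 -= fr[c * nr + r - lz] * fr[c * nr + r - lz];
        }
        const int rc = r - hz;  // window centred at rc
        if (rc >= 0) { colsum[c * nr + rc] = run; colsum2[c * nr + rc] = run2; }
      }
      for (int rc = nr - hz; rc < nr; ++rc) {
        double run3 = 0, run4 = 0;
        const int k0 = std::max(0, rc - hz);
        for (int k = k0; k < nr; ++k) {
          run3 += fr[c * nr + k]; run4 += fr[c * nr + k] * fr[c * nr + k];
        }
        colsum[c * nr + rc] = run3; colsum2[c * nr + rc] = run4;
      }
    }
    for (int r = 0; r < nr; ++r) {
      double run = 0, run2 = 0;
      for (int c = 0; c < nc; ++c) {
        run += colsum[c * nr + r]; run2 += colsum2[c * nr + r];
        if (c - lx >= 0) {
          run -= colsum[(c - lx) * nr + r];
          run2 -= colsum2[(c - lx) * nr + r];
        }
        const int cc = c - hx;
        if (cc >= 0) { s1[cc * nr + r] = run; s2[cc * nr + r] = run2; }
      }
      for (int cc = nc - hx; cc < nc; ++cc) {
        double run3 = 0, run4 = 0;
        const int k0 = std::max(0, cc - hx);
        for (int k = k0; k < nc; ++k) {
          run3 += colsum[k * nr + r]; run4 += colsum2[k * nr + r];
        }
        s1[cc * nr + r] = run3; s2[cc * nr + r] = run4;
      }
    }
    double cmax = 0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        const double varf = std::max(s2[i] - s1[i] * s1[i] / n_t, 0.0);
        const double den = std::sqrt(varf * ss_t);
        double v = den > 0 ? (ct[i] - m_t * s1[i]) / den : 0.0;
        if (!std::isfinite(v)) v = 0.0;
        corr[i] = std::min(std::max(v, -1.0), 1.0);
        if (corr[i] > cmax) cmax = corr[i];
      }
    // threshold tiny denominators relative to the frame's scale
    // (den comparison above already zeroes exact-zero variance)
    const int b = std::max(border, 1);
    for (int c = b; c < nc - b; ++c)
      for (int r = b; r < nr - b; ++r) {
        const int i = c * nr + r;
        const double v = corr[i];
        if (v <= threshold) continue;
        if (fr[i] < min_amp) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dx = -1; dx <= 1 && ismax; ++dx) {
            if (dz == 0 && dx == 0) continue;
            const double nb = corr[(c + dx) * nr + r + dz];
            if (dz > 0 || (dz == 0 && dx > 0)) { if (!(v > nb)) ismax = false; }
            else { if (!(v >= nb)) ismax = false; }
          }
        if (!ismax) continue;
        pk_f.push_back(f + 1); pk_r.push_back(r + 1); pk_c.push_back(c + 1);
        pk_corr.push_back(v); pk_amp.push_back(fr[i]);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            pk_neigh.push_back(corr[(c + dx) * nr + r + dz]);
      }
  }
  const int np = pk_f.size();
  NumericMatrix neigh(np, 9);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 9; ++j) neigh(i, j) = pk_neigh[(R_xlen_t)i * 9 + j];
  return List::create(_["frame"] = wrap(pk_f), _["row"] = wrap(pk_r),
                      _["col"] = wrap(pk_c), _["corr"] = wrap(pk_corr),
                      _["amp"] = wrap(pk_amp), _["neigh"] = neigh);
}
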