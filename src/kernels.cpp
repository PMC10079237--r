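#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise linear-spring interaction forces between cell centres, with a
// cell-list neighbour search. The force between cells i and j at separation
// d < r_int has magnitude k * (rest - d) with rest = radius_i + radius_j
// (repulsive below rest length with stiffness k_rep, attractive between
// rest and the cutoff with the weaker stiffness k_att -- volume exclusion
// must dominate adhesion or tissue collapses inward), directed along the
// centre line and scaled by scale_i * scale_j (necrotic cells shrink, so
// their interactions weaken). Returns per-cell force components and each
// cell's nearest-neighbour distance.
// [[Rcpp::export]]
List pair_spring_forces(NumericVector x, NumericVector y,
                        NumericVector radius, NumericVector scale,
                        double k_rep, double k_att, double r_int,
                        double xmin, double xmax, double ymin, double ymax,
                        bool periodic) {
  const int n = x.size();
  NumericVector fx(n), fy(n), dmin(n, R_PosInf);
  if (n == 0) return List::create(_["fx"] = fx, _["fy"] = fy, _["dmin"] = dmin);

  const double w = xmax - xmin, h = ymax - ymin;
  const double cell = r_int;
  int ncx = std::max(1, (int)std::floor(w / cell));
  int ncy = std::max(1, (int)std::floor(h / cell));
  std::vector<std::vector<int> > buckets((size_t)ncx * ncy);
  std::vector<int> bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - xmin) / w * ncx);
    int cy = (int)std::floor((y[i] - ymin) / h * ncy);
    if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
    if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
    bx[i] = cx; by[i] = cy;
    buckets[(size_t)cx * ncy + cy].push_back(i);
  }
  const double r2max = r_int * r_int;
  for (int i = 0; i < n; ++i) {
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        int cx = bx[i] + ox, cy = by[i] + oy;
        if (periodic) {
          cx = (cx + ncx) % ncx;
          cy = (cy + ncy) % ncy;
        } else {
          if (cx < 0 || cx >= ncx || cy < 0 || cy >= ncy) continue;
        }
        const std::vector<int> &bkt = buckets[(size_t)cx * ncy + cy];
        for (size_t m = 0; m < bkt.size(); ++m) {
          int j = bkt[m];
          if (j <= i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (periodic) {
            dx -= w * std::round(dx / w);
            dy -= h * std::round(dy / h);
          }
          double d2 = dx * dx + dy * dy;
          if (d2 >= r2max) continue;
          double d = std::sqrt(d2);
          if (d < dmin[i]) dmin[i] = d;
          if (d < dmin[j]) dmin[j] = d;
          if (d < 1e-9) continue;  // coincident centres: no defined direction
          double rest = radius[i] + radius[j];
          double k = (d < rest) ? k_rep : k_att;
          double mag = k * (rest - d) * scale[i] * scale[j];
          double ux = dx / d, uy = dy / d;
          fx[i] += mag * ux; fy[i] += mag * uy;
          fx[j] -= mag * ux; fy[j] -= mag * uy;
        }
      }
    }
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["dmin"] = dmin);
}

static inline int reflect(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Reaction-diffusion substeps for one field on a regular grid:
// df/dt = D lap(f) - lambda f - sink f + src, with zero-flux (clipped) or
// wraparound (periodic) boundaries. Diffusion, sources and sinks use an
// explicit (FTCS) step; the natural-decay term is integrated exactly with
// an exponential factor, so a source-free uniform field decays as
// exp(-lambda t) to machine precision. src and sink are per-node rate
// maps. The caller chooses nsub so each substep respects the stability
// bound dt/nsub <= ~0.5 / (4 D / h^2 + lambda + max sink).
// [[Rcpp::export]]
NumericMatrix field_substeps(NumericMatrix f, NumericMatrix src,
                             NumericMatrix sink, double D, double lambda,
                             double h, double dt_total, int nsub,
                             bool periodic) {
  const int nx = f.nrow(), ny = f.ncol();
  NumericMatrix cur(clone(f));
  NumericMatrix nxt(nx, ny);
  const double dt = dt_total / nsub;
  const double ih2 = 1.0 / (h * h);
  const double decay = std::exp(-lambda * dt);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < ny; ++j) {
      int jm = periodic ? (j - 1 + ny) % ny : reflect(j - 1, ny);
      int jp = periodic ? (j + 1) % ny : reflect(j + 1, ny);
      for (int i = 0; i < nx; ++i) {
        int im = periodic ? (i - 1 + nx) % nx : reflect(i - 1, nx);
        int ip = periodic ? (i + 1) % nx : reflect(i + 1, nx);
        double lap = (cur(im, j) + cur(ip, j) + cur(i, jm) + cur(i, jp)
                      - 4.0 * cur(i, j)) * ih2;
        double v = (cur(i, j)
          + dt * (D * lap - sink(i, j) * cur(i, j) + src(i, j))) * decay;
        nxt(i, j) = (v > 0.0) ? v : 0.0;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// For each query point, the indices (1-based) of reference points within
// distance r, via a cell list. Used for macrophage-tumour contact tests.
// [[Rcpp::export]]
List points_within(NumericVector qx, NumericVector qy,
                   NumericVector rx, NumericVector ry, double r) {
  const int nq = qx.size(), nr = rx.size();
  List out(nq);
  if (nr == 0) {
    for (int i = 0; i < nq; ++i) out[i] = IntegerVector(0);
    return out;
  }
  double xlo = R_PosInf, ylo = R_PosInf;
  for (int j = 0; j < nr; ++j) {
    if (rx[j] < xlo) xlo = rx[j];
    if (ry[j] < ylo) ylo = ry[j];
  }
  const double cell = r;
  std::vector<std::vector<int> > grid;
  int ncx = 1, ncy = 1;
  double xhi = xlo, yhi = ylo;
  for (int j = 0; j < nr; ++j) {
    if (rx[j] > xhi) xhi = rx[j];
    if (ry[j] > yhi) yhi = ry[j];
  }
  ncx = std::max(1, (int)std::floor((xhi - xlo) / cell) + 1);
  ncy = std::max(1, (int)std::floor((yhi - ylo) / cell) + 1);
  grid.resize((size_t)ncx * ncy);
  for (int j = 0; j < nr; ++j) {
    int cx = std::min(ncx - 1, (int)std::floor((rx[j] - xlo) / cell));
    int cy = std::min(ncy - 1, (int)std::floor((ry[j] - ylo) / cell));
    grid[(size_t)cx * ncy + cy].push_back(j);
  }
  const double r2 = r * r;
  for (int i = 0; i < nq; ++i) {
    std::vector<int> hits;
    int cx = (int)std::floor((qx[i] - xlo) / cell);
    int cy = (int)std::floor((qy[i] - ylo) / cell);
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        int gx = cx + ox, gy = cy + oy;
        if (gx < 0 || gx >= ncx || gy < 0 || gy >= ncy) continue;
        const std::vector<int> &bkt = grid[(size_t)gx * ncy + gy];
        for (size_t m = 0; m < bkt.size(); ++m) {
          int j = bkt[m];
          double dx = qx[i] - rx[j], dy = qy[i] - ry[j];
          if (dx * dx + dy * dy <= r2) hits.push_back(j + 1);
        }
      }
    }
    out[i] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

// Fused overdamped position integrator: nsub sub-steps of
//   x += (F_spring(x) + F_active) * (dt / nsub) / nu
// with the spring forces recomputed each sub-step via a cell list and the
// active (chemotactic + random) forces held fixed over the step. Positions
// are clamped to the domain. Returns the final positions, the
// nearest-neighbour distance per cell (from the last sub-step) and the
// largest single sub-step displacement (for the stability check).
// [[Rcpp::export]]
List integrate_positions(NumericVector x0, NumericVector y0,
                         NumericVector radius, NumericVector scale,
                         NumericVector fax, NumericVector fay,
                         double k_rep, double k_att, double r_int,
                         double xmin, double xmax, double ymin, double ymax,
                         double nu, double dt, int nsub) {
  const int n = x0.size();
  NumericVector x(clone(x0)), y(clone(y0)), dmin(n, R_PosInf);
  double max_disp = 0.0;
  if (n == 0) {
    return List::create(_["x"] = x, _["y"] = y, _["dmin"] = dmin,
                        _["max_disp"] = max_disp);
  }
  const double w = xmax - xmin, h = ymax - ymin;
  const double cell = r_int;
  const int ncx = std::max(1, (int)std::floor(w / cell));
  const int ncy = std::max(1, (int)std::floor(h / cell));
  std::vector<int> head((size_t)ncx * ncy), nxt(n), cxv(n), cyv(n);
  std::vector<double> fx(n), fy(n);
  const double r2max = r_int * r_int;
  const double dts = dt / nsub;
  const double eps = 1e-6;
  for (int s = 0; s < nsub; ++s) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - xmin) / w * ncx);
      int cy = (int)std::floor((y[i] - ymin) / h * ncy);
      if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
      if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
      cxv[i] = cx; cyv[i] = cy;
      size_t b = (size_t)cx * ncy + cy;
      nxt[i] = head[b];
      head[b] = i;
    }
    const bool last = (s == nsub - 1);
    for (int i = 0; i < n; ++i) { fx[i] = fax[i]; fy[i] = fay[i]; }
    for (int i = 0; i < n; ++i) {
      for (int ox = -1; ox <= 1; ++ox) {
        int cx = cxv[i] + ox;
        if (cx < 0 || cx >= ncx) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int cy = cyv[i] + oy;
          if (cy < 0 || cy >= ncy) continue;
          for (int j = head[(size_t)cx * ncy + cy]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d2 = dx * dx + dy * dy;
            if (d2 >= r2max) continue;
            double d = std::sqrt(d2);
            if (last) {
              if (d < dmin[i]) dmin[i] = d;
              if (d < dmin[j]) dmin[j] = d;
            }
            if (d < 1e-9) continue;
            double rest = radius[i] + radius[j];
            double k = (d < rest) ? k_rep : k_att;
            double mag = k * (rest - d) * scale[i] * scale[j];
            double ux = dx / d, uy = dy / d;
            fx[i] += mag * ux; fy[i] += mag * uy;
            fx[j] -= mag * ux; fy[j] -= mag * uy;
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double ddx = fx[i] * dts / nu, ddy = fy[i] * dts / nu;
      double dnorm = std::sqrt(ddx * ddx + ddy * ddy);
      if (dnorm > max_disp) max_disp = dnorm;
      double nx = x[i] + ddx, ny = y[i] + ddy;
      if (nx < xmin + eps) nx = xmin + eps;
      if (nx > xmax - eps) nx = xmax - eps;
      if (ny < ymin + eps) ny = ymin + eps;
      if (ny > ymax - eps) ny = ymax - eps;
      x[i] = nx; y[i] = ny;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["dmin"] = dmin,
                      _["max_disp"] = max_disp);
}
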