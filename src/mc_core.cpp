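#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image squared distance in a periodic square box of side L.
// Assumes |dx|, |dy| < L (coordinates live in [0, L)).
static inline double min_image_d2(double dx, double dy, double L) {
  dx = std::fabs(dx);
  if (dx > 0.5 * L) dx = L - dx;
  dy = std::fabs(dy);
  if (dy > 0.5 * L) dy = L - dy;
  return dx * dx + dy * dy;
}

// --- cell-list support for hard-disk packing -------------------------------
// Cell width >= 2R so that any center within 2R of a point lies in the 3x3
// cell neighborhood.
struct CellGrid {
  int nc;
  double L, w;
  std::vector<std::vector<int>> cells;
  CellGrid(double L_, double R) : L(L_) {
    nc = std::max(1, (int)std::floor(L_ / (2.0 * R)));
    w = L_ / nc;
    cells.assign((size_t)nc * nc, {});
  }
  inline int cell_of(double x, double y) const {
    int ix = (int)(x / w);
    if (ix >= nc) ix = nc - 1;
    int iy = (int)(y / w);
    if (iy >= nc) iy = nc - 1;
    return iy * nc + ix;
  }
  inline void insert(int id, double x, double y) {
    cells[cell_of(x, y)].push_back(id);
  }
  inline void remove(int id, double x, double y) {
    auto& v = cells[cell_of(x, y)];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == id) {
        v[k] = v.back();
        v.pop_back();
        return;
      }
  }
  template <typename F>
  bool any_neighbor(double x, double y, F&& pred) const {
    int ix = (int)(x / w);
    if (ix >= nc) ix = nc - 1;
    int iy = (int)(y / w);
    if (iy >= nc) iy = nc - 1;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int jx = (ix + dx + nc) % nc, jy = (iy + dy + nc) % nc;
        for (int id : cells[(size_t)jy * nc + jx])
          if (pred(id)) return true;
        if (nc == 1) break;  // single cell: no distinct neighbors
      }
    return false;
  }
};

// Random sequential adsorption of hard disks (center separation >= 2 R) with
// Metropolis relaxation sweeps when insertion stalls; packs up to area
// fractions around 0.6 where plain RSA jams (~0.547).
// [[Rcpp::export]]
NumericMatrix cpp_place_domains(double L, double R, int n, int max_fail,
                                int relax_sweeps, int max_rounds) {
  std::vector<double> cx, cy;
  cx.reserve(n);
  cy.reserve(n);
  const double dmin2 = 4.0 * R * R;
  CellGrid grid(L, R);
  auto overlaps = [&](double x, double y, int skip) {
    return grid.any_neighbor(x, y, [&](int id) {
      if (id == skip) return false;
      return min_image_d2(x - cx[id], y - cy[id], L) < dmin2;
    });
  };
  int rounds = 0;

  while ((int)cx.size() < n) {
    int fails = 0;
    while ((int)cx.size() < n && fails < max_fail) {
      double x = unif_rand() * L, y = unif_rand() * L;
      if (!overlaps(x, y, -1)) {
        int id = cx.size();
        cx.push_back(x);
        cy.push_back(y);
        grid.insert(id, x, y);
        fails = 0;
      } else {
        ++fails;
      }
    }
    if ((int)cx.size() >= n) break;
    if (++rounds > max_rounds)
      stop("packing unreachable: could not place %d domains (R = %g nm, box = %g nm)",
           n, R, L);
    // small-displacement relaxation to open insertion gaps
    const double step = 0.5 * R;
    for (int s = 0; s < relax_sweeps; ++s) {
      for (int k = 0; k < (int)cx.size(); ++k) {
        double nx = cx[k] + (unif_rand() - 0.5) * 2.0 * step;
        double ny = cy[k] + (unif_rand() - 0.5) * 2.0 * step;
        nx -= L * std::floor(nx / L);
        ny -= L * std::floor(ny / L);
        if (!overlaps(nx, ny, k)) {
          grid.remove(k, cx[k], cy[k]);
          cx[k] = nx;
          cy[k] = ny;
          grid.insert(k, nx, ny);
        }
      }
    }
  }

  NumericMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    out(k, 0) = cx[k];
    out(k, 1) = cy[k];
  }
  return out;
}

static inline bool point_in_domains(double x, double y,
                                    const NumericMatrix& centers, double L,
                                    double R2) {
  for (int k = 0; k < centers.nrow(); ++k) {
    if (min_image_d2(x - centers(k, 0), y - centers(k, 1), L) <= R2)
      return true;
  }
  return false;
}

// Place n probes: each is inside the domain union with probability p_in.
// Inside placement draws a domain uniformly and a point uniformly within the
// disk (exact for non-overlapping domains); outside placement is rejection
// sampling from the box complement.
// [[Rcpp::export]]
NumericMatrix cpp_place_probes(NumericMatrix centers, double L, double R,
                               int n, double p_in, int max_attempts) {
  NumericMatrix out(n, 3);  // x, y, inside
  const double R2 = R * R;
  const int ndom = centers.nrow();
  for (int i = 0; i < n; ++i) {
    bool inside = unif_rand() < p_in;
    if (inside && ndom == 0)
      stop("inside placement requested but the layout has no domains");
    double x = 0.0, y = 0.0;
    if (inside) {
      int k = (int)std::floor(unif_rand() * ndom);
      if (k >= ndom) k = ndom - 1;
      // uniform point in a disk of radius R
      double rr = R * std::sqrt(unif_rand());
      double th = 2.0 * M_PI * unif_rand();
      x = centers(k, 0) + rr * std::cos(th);
      y = centers(k, 1) + rr * std::sin(th);
      x -= L * std::floor(x / L);
      y -= L * std::floor(y / L);
    } else {
      int att = 0;
      for (;;) {
        x = unif_rand() * L;
        y = unif_rand() * L;
        if (ndom == 0 || !point_in_domains(x, y, centers, L, R2)) break;
        if (++att >= max_attempts)
          stop("rejection sampling stalled while placing a probe outside the domains");
      }
    }
    out(i, 0) = x;
    out(i, 1) = y;
    out(i, 2) = inside ? 1.0 : 0.0;
  }
  return out;
}

// Total Foerster transfer rate per donor: Omega_i = sum_j (1/tau) (R0/r_ij)^6
// with minimum-image in-plane distance, cross-leaflet offset h, and a contact
// clamp on r.
// [[Rcpp::export]]
NumericVector cpp_donor_rates(NumericVector dx, NumericVector dy,
                              IntegerVector dleaf, NumericVector ax,
                              NumericVector ay, IntegerVector aleaf, double L,
                              double h, double R0, double inv_tau,
                              double clamp) {
  const int nd = dx.size(), na = ax.size();
  const double h2 = h * h, clamp2 = clamp * clamp;
  const double R02 = R0 * R0, halfL = 0.5 * L;
  NumericVector omega(nd);
  const double* axp = ax.begin();
  const double* ayp = ay.begin();
  const int* alp = aleaf.begin();
  for (int i = 0; i < nd; ++i) {
    const double xi = dx[i], yi = dy[i];
    const int li = dleaf[i];
    double s = 0.0;
    for (int j = 0; j < na; ++j) {
      double ddx = std::fabs(xi - axp[j]);
      if (ddx > halfL) ddx = L - ddx;
      double ddy = std::fabs(yi - ayp[j]);
      if (ddy > halfL) ddy = L - ddy;
      double r2 = ddx * ddx + ddy * ddy;
      if (li != alp[j]) r2 += h2;
      if (r2 < clamp2) r2 = clamp2;
      double q = R02 / r2;
      s += q * q * q;
    }
    omega[i] = s * inv_tau;
  }
  return omega;
}

// Flag probes as inside/outside the domain union (minimum image).
// [[Rcpp::export]]
LogicalVector cpp_in_domains(NumericVector x, NumericVector y,
                             NumericMatrix centers, double L, double R) {
  const double R2 = R * R;
  const int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = point_in_domains(x[i], y[i], centers, L, R2);
  return out;
}

// Mean survival <exp(-omega_i t_k)> over donors on a uniform time grid
// t_k = k * dt, k = 0..nt-1, via the recurrence
// exp(-w t_k) = exp(-w t_{k-1}) * exp(-w dt).
// [[Rcpp::export]]
NumericVector cpp_survival_expectation(NumericVector omega, int nt,
                                       double dt) {
  const int n = omega.size();
  NumericVector g(nt);
  for (int i = 0; i < n; ++i) {
    const double f = std::exp(-omega[i] * dt);
    double v = 1.0;
    for (int k = 0; k < nt; ++k) {
      g[k] += v;
      v *= f;
    }
  }
  for (int k = 0; k < nt; ++k) g[k] /= n;
  return g;
}
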