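// Finite-difference Poisson kernels and the Metropolis titration loop.
// Grid arrays are column-major (R layout), node (i,j,k) -> i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <random>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Fraction of the segment a -> b (parameter t in [0,1]) lying inside the
// union of atom spheres. Intervals per sphere are merged exactly.
static double segment_inside_fraction(const double a[3], const double b[3],
                                      const std::vector<int> &atoms,
                                      const NumericMatrix &pos,
                                      const NumericVector &rad) {
  std::vector<std::pair<double, double> > iv;
  double d[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double dd = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (dd <= 0.0) return 0.0;
  for (size_t s = 0; s < atoms.size(); ++s) {
    int ia = atoms[s];
    double m[3] = { a[0] - pos(ia, 0), a[1] - pos(ia, 1), a[2] - pos(ia, 2) };
    double bq = m[0] * d[0] + m[1] * d[1] + m[2] * d[2];
    double cq = m[0] * m[0] + m[1] * m[1] + m[2] * m[2] - rad[ia] * rad[ia];
    double disc = bq * bq - dd * cq;
    if (disc <= 0.0) continue;
    double sq = std::sqrt(disc);
    double t0 = (-bq - sq) / dd, t1 = (-bq + sq) / dd;
    t0 = std::max(0.0, t0); t1 = std::min(1.0, t1);
    if (t1 > t0) iv.push_back(std::make_pair(t0, t1));
  }
  if (iv.empty()) return 0.0;
  std::sort(iv.begin(), iv.end());
  double tot = 0.0, lo = iv[0].first, hi = iv[0].second;
  for (size_t s = 1; s < iv.size(); ++s) {
    if (iv[s].first > hi) { tot += hi - lo; lo = iv[s].first; hi = iv[s].second; }
    else hi = std::max(hi, iv[s].second);
  }
  tot += hi - lo;
  return tot;
}

// Simple cell list over atoms for locality when painting face dielectrics.
struct CellList {
  double org[3], cell;
  int nc[3];
  std::vector<std::vector<int> > cells;
  CellList(const NumericMatrix &pos, const NumericVector &rad,
           const double gorg[3], const double gmax[3]) {
    double rmax = 0.0;
    for (int i = 0; i < rad.size(); ++i) rmax = std::max(rmax, (double)rad[i]);
    cell = std::max(2.0 * rmax, 2.0);
    for (int d = 0; d < 3; ++d) {
      org[d] = gorg[d] - cell;
      nc[d] = std::max(1, (int)std::ceil((gmax[d] - org[d] + cell) / cell));
    }
    cells.resize((size_t)nc[0] * nc[1] * nc[2]);
    for (int ia = 0; ia < pos.nrow(); ++ia) {
      int c[3];
      bool ok = true;
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)std::floor((pos(ia, d) - org[d]) / cell);
        if (c[d] < 0) c[d] = 0;
        if (c[d] >= nc[d]) c[d] = nc[d] - 1;
        (void)ok;
      }
      cells[(size_t)c[0] + (size_t)nc[0] * (c[1] + (size_t)nc[1] * c[2])].push_back(ia);
    }
  }
  void gather(const double p[3], std::vector<int> &out) const {
    out.clear();
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((p[d] - org[d]) / cell);
    }
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int x = c[0] + di, y = c[1] + dj, z = c[2] + dk;
          if (x < 0 || y < 0 || z < 0 || x >= nc[0] || y >= nc[1] || z >= nc[2]) continue;
          const std::vector<int> &v = cells[(size_t)x + (size_t)nc[0] * (y + (size_t)nc[1] * z)];
          out.insert(out.end(), v.begin(), v.end());
        }
  }
};

// Face-centred dielectric maps for the 7-point stencil. For every grid link
// the fraction of the link inside the solute (atom-sphere union, radii
// optionally probe-inflated upstream) weights a harmonic average of
// eps_in/eps_out, which keeps the Born energy smooth in the grid spacing.
// [[Rcpp::export]]
List cpp_face_eps(NumericVector origin, double h, IntegerVector dims,
                  NumericMatrix pos, NumericVector rad,
                  double eps_in, double eps_out) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double gorg[3] = { origin[0], origin[1], origin[2] };
  double gmax[3] = { origin[0] + h * (nx - 1), origin[1] + h * (ny - 1),
                     origin[2] + h * (nz - 1) };
  CellList cl(pos, rad, gorg, gmax);
  NumericVector ex((size_t)(nx - 1) * ny * nz), ey((size_t)nx * (ny - 1) * nz),
      ez((size_t)nx * ny * (nz - 1));
  std::vector<int> near;
  for (int dir = 0; dir < 3; ++dir) {
    int mx = (dir == 0) ? nx - 1 : nx, my = (dir == 1) ? ny - 1 : ny,
        mz = (dir == 2) ? nz - 1 : nz;
    NumericVector &out = (dir == 0) ? ex : (dir == 1) ? ey : ez;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double a[3] = { gorg[0] + h * i, gorg[1] + h * j, gorg[2] + h * k };
          double b[3] = { a[0], a[1], a[2] };
          b[dir] += h;
          double mid[3] = { 0.5 * (a[0] + b[0]), 0.5 * (a[1] + b[1]),
                            0.5 * (a[2] + b[2]) };
          cl.gather(mid, near);
          double f = near.empty() ? 0.0
                                  : segment_inside_fraction(a, b, near, pos, rad);
          out[idx3(i, j, k, mx, my)] =
              1.0 / (f / eps_in + (1.0 - f) / eps_out);
        }
  }
  return List::create(_["ex"] = ex, _["ey"] = ey, _["ez"] = ez);
}

// Screened-Coulomb potential of all charges at every grid node:
// phi = sum_i k q_i / (eps r_i), kcal/(mol e). Used as boundary condition
// and initial guess for the SOR solver.
// [[Rcpp::export]]
NumericVector cpp_coulomb_phi(NumericVector origin, double h,
                              IntegerVector dims, NumericMatrix pos,
                              NumericVector q, double eps, double ke) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int na = pos.nrow();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> px(na), py(na), pz(na), qq(na);
  int nq = 0;
  for (int a = 0; a < na; ++a) {
    if (q[a] == 0.0) continue;
    px[nq] = pos(a, 0); py[nq] = pos(a, 1); pz[nq] = pos(a, 2);
    qq[nq] = ke * q[a] / eps;
    ++nq;
  }
  size_t c = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + h * k;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + h * j;
      for (int i = 0; i < nx; ++i, ++c) {
        double x = origin[0] + h * i;
        double acc = 0.0;
        for (int a = 0; a < nq; ++a) {
          double dx = x - px[a], dy = y - py[a], dz = z - pz[a];
          double r2 = dx * dx + dy * dy + dz * dz;
          double r = std::sqrt(r2);
          if (r < 1e-6) r = 1e-6;
          acc += qq[a] / r;
        }
        out[c] = acc;
      }
    }
  }
  return out;
}

// Gauss-Seidel successive over-relaxation for div(eps grad phi) = -4 pi k rho.
// phi carries pre-set boundary values on the six faces; src is 4*pi*k*q/h per
// node. Returns iterations used and the final max per-sweep update.
// [[Rcpp::export]]
List cpp_sor(NumericVector phi_in, NumericVector src, IntegerVector dims,
             NumericVector ex, NumericVector ey, NumericVector ez,
             double omega, double tol, int max_iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_in);
  double *p = REAL(phi);
  const double *s = REAL(src), *px = REAL(ex), *py = REAL(ey), *pz = REAL(ez);
  int exx = nx - 1, eyy = ny - 1;
  double resid = R_PosInf;
  int it = 0;
  const int nxy = nx * ny;
  for (it = 1; it <= max_iter; ++it) {
    double dmax = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j) {
        double *row = p + idx3(0, j, k, nx, ny);
        const double *srow = s + idx3(0, j, k, nx, ny);
        const double *exr = px + idx3(0, j, k, exx, ny);
        const double *eymr = py + idx3(0, j - 1, k, nx, eyy);
        const double *eypr = py + idx3(0, j, k, nx, eyy);
        const double *ezmr = pz + idx3(0, j, k - 1, nx, ny);
        const double *ezpr = pz + idx3(0, j, k, nx, ny);
        for (int i = 1; i < nx - 1; ++i) {
          double exm = exr[i - 1], exp_ = exr[i];
          double eym = eymr[i], eyp = eypr[i];
          double ezm = ezmr[i], ezp = ezpr[i];
          double val = (exm * row[i - 1] + exp_ * row[i + 1] +
                        eym * row[i - nx] + eyp * row[i + nx] +
                        ezm * row[i - nxy] + ezp * row[i + nxy] + srow[i]) /
                       (exm + exp_ + eym + eyp + ezm + ezp);
          double d = omega * (val - row[i]);
          row[i] += d;
          double ad = std::fabs(d);
          if (ad > dmax) dmax = ad;
        }
      }
    resid = dmax;
    if (dmax < tol) break;
  }
  bool converged = resid < tol;
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, max_iter),
                      _["residual"] = resid, _["converged"] = converged);
}

// Metropolis single-flip titration over ionization microstates.
// nu[i]: energy (kcal/mol) of ionizing site i alone at this pH;
// W[i,j]: charged-charged pairwise energy. Sites are visited in order within
// each sweep; occupancy is averaged after burn-in. mt19937 keeps runs
// reproducible for a given seed.
// [[Rcpp::export]]
NumericVector cpp_mc_titrate(NumericVector nu, NumericMatrix W, int n_sweeps,
                             double burn_frac, int seed, double kT) {
  int n = nu.size();
  std::mt19937 gen((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> x(n, 0);
  std::vector<double> acc(n, 0.0);
  int burn = (int)(burn_frac * n_sweeps);
  long nsamp = 0;
  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int i = 0; i < n; ++i) {
      double dE = nu[i];
      for (int j = 0; j < n; ++j)
        if (j != i && x[j]) dE += W(i, j);
      if (x[i]) dE = -dE;
      if (dE <= 0.0 || unif(gen) < std::exp(-dE / kT)) x[i] = 1 - x[i];
    }
    if (sw >= burn) {
      for (int i = 0; i < n; ++i) acc[i] += x[i];
      ++nsamp;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / (double)nsamp;
  return out;
}
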