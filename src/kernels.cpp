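#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// min over atoms of node-to-atom-center Euclidean distance
// [[Rcpp::export]]
NumericVector cpp_distance_map(IntegerVector dims, NumericVector origin,
                               NumericVector spacing, NumericMatrix atoms) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = atoms.nrow();
  NumericVector out((long)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing[0];
        double best = R_PosInf;
        for (int a = 0; a < na; ++a) {
          double dx = x - atoms(a, 0), dy = y - atoms(a, 1), dz = z - atoms(a, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
        out[idx3(i, j, k, nx, ny)] = std::sqrt(best);
      }
    }
  }
  return out;
}

// per-node min over atoms of (distance - atom radius): signed surface distance
// [[Rcpp::export]]
NumericVector cpp_surface_distance(IntegerVector dims, NumericVector origin,
                                   NumericVector spacing, NumericMatrix atoms,
                                   NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = atoms.nrow();
  NumericVector out((long)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing[0];
        double best = R_PosInf;
        for (int a = 0; a < na; ++a) {
          double dx = x - atoms(a, 0), dy = y - atoms(a, 1), dz = z - atoms(a, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
          if (d < best) best = d;
        }
        out[idx3(i, j, k, nx, ny)] = best;
      }
    }
  }
  return out;
}

// distance from each point to its closest atom
// [[Rcpp::export]]
NumericVector cpp_closest_atom_distance(NumericMatrix points, NumericMatrix atoms) {
  const int np = points.nrow(), na = atoms.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int a = 0; a < na; ++a) {
      double dx = points(p, 0) - atoms(a, 0);
      double dy = points(p, 1) - atoms(a, 1);
      double dz = points(p, 2) - atoms(a, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// erode tentatively-interior nodes that lie within `probe` of an exterior node
// interior: integer 0/1 per node (1 = tentatively interior)
// [[Rcpp::export]]
IntegerVector cpp_erode_interior(IntegerVector interior, IntegerVector dims,
                                 NumericVector spacing, double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int wx = (int)std::ceil(probe / spacing[0]);
  const int wy = (int)std::ceil(probe / spacing[1]);
  const int wz = (int)std::ceil(probe / spacing[2]);
  const double p2 = probe * probe;
  IntegerVector out = clone(interior);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = idx3(i, j, k, nx, ny);
        if (!interior[id]) continue;
        bool reclass = false;
        for (int dk = -wz; dk <= wz && !reclass; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          double z2 = dk * spacing[2] * dk * spacing[2];
          for (int dj = -wy; dj <= wy && !reclass; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            double yz2 = z2 + dj * spacing[1] * dj * spacing[1];
            if (yz2 > p2) continue;
            for (int di = -wx; di <= wx; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              double d2 = yz2 + di * spacing[0] * di * spacing[0];
              if (d2 <= p2 && !interior[idx3(ii, jj, kk, nx, ny)]) {
                reclass = true;
                break;
              }
            }
          }
        }
        if (reclass) out[id] = 0;
      }
  return out;
}

// deposit radial triangular kernels, renormalised on-grid to unit weight per
// sample; returns accumulated weights plus the number of samples dropped
// (zero on-grid kernel mass)
// [[Rcpp::export]]
List cpp_kde_deposit(IntegerVector dims, NumericVector origin,
                     NumericVector spacing, NumericMatrix points, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector acc((long)nx * ny * nz);
  const int wx = (int)std::ceil(h / spacing[0]);
  const int wy = (int)std::ceil(h / spacing[1]);
  const int wz = (int)std::ceil(h / spacing[2]);
  int dropped = 0;
  std::vector<long> ids;
  std::vector<double> w;
  ids.reserve((2 * wx + 1) * (2 * wy + 1) * (2 * wz + 1));
  w.reserve(ids.capacity());
  for (int p = 0; p < points.nrow(); ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    int ci = (int)std::floor((px - origin[0]) / spacing[0]);
    int cj = (int)std::floor((py - origin[1]) / spacing[1]);
    int ck = (int)std::floor((pz - origin[2]) / spacing[2]);
    ids.clear(); w.clear();
    double tot = 0.0;
    for (int dk = -wz; dk <= wz + 1; ++dk) {
      int kk = ck + dk;
      if (kk < 0 || kk >= nz) continue;
      double dz = origin[2] + kk * spacing[2] - pz;
      for (int dj = -wy; dj <= wy + 1; ++dj) {
        int jj = cj + dj;
        if (jj < 0 || jj >= ny) continue;
        double dy = origin[1] + jj * spacing[1] - py;
        double dzy2 = dz * dz + dy * dy;
        if (dzy2 >= h * h) continue;
        for (int di = -wx; di <= wx + 1; ++di) {
          int ii = ci + di;
          if (ii < 0 || ii >= nx) continue;
          double dx = origin[0] + ii * spacing[0] - px;
          double d = std::sqrt(dzy2 + dx * dx);
          if (d < h) {
            double wt = 1.0 - d / h;
            ids.push_back(idx3(ii, jj, kk, nx, ny));
            w.push_back(wt);
            tot += wt;
          }
        }
      }
    }
    if (tot <= 0.0) {
      ++dropped;
      continue;
    }
    for (size_t q = 0; q < ids.size(); ++q) acc[ids[q]] += w[q] / tot;
  }
  return List::create(_["weights"] = acc, _["dropped"] = dropped);
}

struct Faces {
  // harmonic-mean face dielectrics built from a node interior mask
  std::vector<double> ex, ey, ez;
};

static Faces build_faces(const IntegerVector &interior, int nx, int ny, int nz,
                         double idie, double sdie) {
  Faces f;
  long n = (long)nx * ny * nz;
  f.ex.assign(n, 0.0);
  f.ey.assign(n, 0.0);
  f.ez.assign(n, 0.0);
  auto node_eps = [&](long id) { return interior[id] ? idie : sdie; };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = idx3(i, j, k, nx, ny);
        double e0 = node_eps(id);
        if (i + 1 < nx) {
          double e1 = node_eps(idx3(i + 1, j, k, nx, ny));
          f.ex[id] = 2.0 * e0 * e1 / (e0 + e1);
        }
        if (j + 1 < ny) {
          double e1 = node_eps(idx3(i, j + 1, k, nx, ny));
          f.ey[id] = 2.0 * e0 * e1 / (e0 + e1);
        }
        if (k + 1 < nz) {
          double e1 = node_eps(idx3(i, j, k + 1, nx, ny));
          f.ez[id] = 2.0 * e0 * e1 / (e0 + e1);
        }
      }
  return f;
}

// Finite-difference PB solve on a uniform cubic grid.
//   interior: 0/1 node mask (dielectric assignment)
//   access:   0/1 ion accessibility mask
//   source:   4*pi*lB_vac*q_node/h  (kT/e units, pre-multiplied by h^2/h^3)
//   kappa2h2: eps_s * kappa^2 * h^2
//   u:        initial guess with Dirichlet boundary values filled in
// nonlinear = false: SOR with relaxation omega on the LPB form
// nonlinear = true : damped nonlinear Gauss-Seidel (Newton local step) on sinh
// [[Rcpp::export]]
List cpp_pb_solve(IntegerVector dims, IntegerVector interior,
                  IntegerVector access, NumericVector source,
                  NumericVector u0, double idie, double sdie,
                  double kappa2h2, bool nonlinear, double omega,
                  double tol, int maxiter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector u = clone(u0);
  Faces f = build_faces(interior, nx, ny, nz, idie, sdie);
  double snorm = 0.0;
  for (long i = 0; i < source.size(); ++i) snorm += source[i] * source[i];
  snorm = std::sqrt(snorm);
  double resid = R_PosInf, prev_resid = R_PosInf;
  int it = 0, grow = 0;
  const int check_every = 4; // residual sweeps are as costly as updates
  bool converged = false;
  for (it = 1; it <= maxiter; ++it) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          long id = idx3(i, j, k, nx, ny);
          double exm = f.ex[idx3(i - 1, j, k, nx, ny)], exp_ = f.ex[id];
          double eym = f.ey[idx3(i, j - 1, k, nx, ny)], eyp = f.ey[id];
          double ezm = f.ez[idx3(i, j, k - 1, nx, ny)], ezp = f.ez[id];
          double nb = exm * u[id - 1] + exp_ * u[id + 1] +
                      eym * u[id - nx] + eyp * u[id + nx] +
                      ezm * u[id - (long)nx * ny] + ezp * u[id + (long)nx * ny];
          double esum = exm + exp_ + eym + eyp + ezm + ezp;
          double b = access[id] ? kappa2h2 : 0.0;
          if (!nonlinear) {
            double unew = (nb + source[id]) / (esum + b);
            u[id] = (1.0 - omega) * u[id] + omega * unew;
          } else {
            // clamp the sinh argument: keeps transients finite without
            // affecting converged states (mobile term only acts where
            // ions are accessible and |u| is moderate)
            double uc = u[id];
            double us = std::max(-50.0, std::min(50.0, uc));
            double fv = nb - esum * uc + source[id] - b * std::sinh(us);
            double dfv = esum + b * std::cosh(us);
            u[id] = uc + omega * fv / dfv;
          }
        }
    // residual sweep (every few iterations; it costs as much as an update)
    if (it % check_every != 0 && it != maxiter) continue;
    double rn = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          long id = idx3(i, j, k, nx, ny);
          double exm = f.ex[idx3(i - 1, j, k, nx, ny)], exp_ = f.ex[id];
          double eym = f.ey[idx3(i, j - 1, k, nx, ny)], eyp = f.ey[id];
          double ezm = f.ez[idx3(i, j, k - 1, nx, ny)], ezp = f.ez[id];
          double nb = exm * u[id - 1] + exp_ * u[id + 1] +
                      eym * u[id - nx] + eyp * u[id + nx] +
                      ezm * u[id - (long)nx * ny] + ezp * u[id + (long)nx * ny];
          double esum = exm + exp_ + eym + eyp + ezm + ezp;
          double b = access[id] ? kappa2h2 : 0.0;
          double um = std::max(-50.0, std::min(50.0, u[id]));
          double mob = nonlinear ? b * std::sinh(um) : b * u[id];
          double fv = nb - esum * u[id] + source[id] - mob;
          rn += fv * fv;
        }
    rn = std::sqrt(rn);
    resid = (snorm > 0.0) ? rn / snorm : rn;
    if (!std::isfinite(resid)) {
      return List::create(_["u"] = u, _["iterations"] = it,
                          _["residual"] = resid, _["converged"] = false,
                          _["diverged"] = true);
    }
    if (resid < tol) {
      converged = true;
      break;
    }
    if (nonlinear) {
      if (resid > prev_resid * 1.000001) ++grow; else grow = 0;
      if (grow >= 25)
        return List::create(_["u"] = u, _["iterations"] = it,
                            _["residual"] = resid, _["converged"] = false,
                            _["diverged"] = true);
    }
    prev_resid = resid;
  }
  return List::create(_["u"] = u, _["iterations"] = std::min(it, maxiter),
                      _["residual"] = resid, _["converged"] = converged,
                      _["diverged"] = false);
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo sampler of mobile ions in the screened field of
// fixed beads.  Energies in kT; interactions: ion-bead Debye-Hueckel sphere
// potential, ion-ion Yukawa.  mode: 0 = full, 1 = no ion-ion, 2 = ideal
// (hard cores against beads only).  Box centered at the origin; moves
// leaving the box are rejected.  Uses R's RNG.
// ---------------------------------------------------------------------------
struct McSys {
  NumericMatrix bead_pos;
  NumericVector bead_q, bead_r;
  std::vector<double> x, y, z; // ions: cations then anions
  std::vector<int> zi;
  int n_ion;
  double ion_r, lB, kappa, box2[3];
  int mode;

  double pair_bead(int i, int b) const {
    double dx = x[i] - bead_pos(b, 0), dy = y[i] - bead_pos(b, 1),
           dz = z[i] - bead_pos(b, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < bead_r[b] + ion_r) return R_PosInf;
    if (mode == 2) return 0.0;
    // Debye-Hueckel sphere potential with the ion closest-approach radius
    // as contact radius: no screening inside the ion-free shell
    double a = bead_r[b] + ion_r;
    return zi[i] * bead_q[b] * lB * std::exp(-kappa * (d - a)) /
           ((1.0 + kappa * a) * d);
  }
  double pair_ion(int i, int j) const {
    if (mode >= 1) return 0.0;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 2.0 * ion_r) return R_PosInf;
    return zi[i] * zi[j] * lB * std::exp(-kappa * d) / d;
  }
  double energy_of(int i) const {
    double e = 0.0;
    for (int b = 0; b < bead_pos.nrow(); ++b) {
      double v = pair_bead(i, b);
      if (!std::isfinite(v)) return R_PosInf;
      e += v;
    }
    for (int j = 0; j < n_ion; ++j) {
      if (j == i) continue;
      double v = pair_ion(i, j);
      if (!std::isfinite(v)) return R_PosInf;
      e += v;
    }
    return e;
  }
  double total_energy() const {
    double e = 0.0;
    for (int i = 0; i < n_ion; ++i)
      for (int b = 0; b < bead_pos.nrow(); ++b) e += pair_bead(i, b);
    for (int i = 0; i < n_ion; ++i)
      for (int j = i + 1; j < n_ion; ++j) e += pair_ion(i, j);
    return e;
  }
};

// [[Rcpp::export]]
List cpp_mc_sample(NumericMatrix bead_pos, NumericVector bead_q,
                   NumericVector bead_r, int n_cat, int n_ani, int n_water,
                   double ion_radius, double lB, double kappa,
                   NumericVector box, int sweeps, int equil_sweeps,
                   int stride, double step, int mode) {
  McSys s;
  s.bead_pos = bead_pos;
  s.bead_q = bead_q;
  s.bead_r = bead_r;
  s.n_ion = n_cat + n_ani;
  s.ion_r = ion_radius;
  s.lB = lB;
  s.kappa = kappa;
  s.mode = mode;
  for (int d = 0; d < 3; ++d) s.box2[d] = box[d] / 2.0;
  s.x.resize(s.n_ion);
  s.y.resize(s.n_ion);
  s.z.resize(s.n_ion);
  s.zi.resize(s.n_ion);
  for (int i = 0; i < s.n_ion; ++i) s.zi[i] = (i < n_cat) ? 1 : -1;

  RNGScope scope;
  auto runifc = [&](double half) { return (unif_rand() * 2.0 - 1.0) * half; };
  // initial placement: uniform, rejecting hard-core overlap
  for (int i = 0; i < s.n_ion; ++i) {
    bool ok = false;
    for (int attempt = 0; attempt < 10000 && !ok; ++attempt) {
      s.x[i] = runifc(s.box2[0]);
      s.y[i] = runifc(s.box2[1]);
      s.z[i] = runifc(s.box2[2]);
      ok = std::isfinite(s.energy_of(i));
    }
    if (!ok) stop("could not place ion %d without overlap", i + 1);
  }
  double etot = s.total_energy();
  long accepted = 0, attempted = 0;
  List frames;
  int nbead = bead_pos.nrow();
  auto draw_water = [&](double *wx, double *wy, double *wz) {
    for (int attempt = 0; attempt < 10000; ++attempt) {
      double px = runifc(s.box2[0]), py = runifc(s.box2[1]), pz = runifc(s.box2[2]);
      bool clash = false;
      for (int b = 0; b < nbead; ++b) {
        double dx = px - bead_pos(b, 0), dy = py - bead_pos(b, 1),
               dz = pz - bead_pos(b, 2);
        if (dx * dx + dy * dy + dz * dz < bead_r[b] * bead_r[b]) {
          clash = true;
          break;
        }
      }
      if (!clash) {
        *wx = px; *wy = py; *wz = pz;
        return;
      }
    }
    stop("could not place water site outside beads");
  };
  for (int sweep = 1; sweep <= sweeps; ++sweep) {
    for (int m = 0; m < s.n_ion; ++m) {
      int i = (int)std::floor(unif_rand() * s.n_ion);
      if (i >= s.n_ion) i = s.n_ion - 1;
      double ox = s.x[i], oy = s.y[i], oz = s.z[i];
      double e_old = s.energy_of(i);
      double nxp = ox + (unif_rand() * 2.0 - 1.0) * step;
      double nyp = oy + (unif_rand() * 2.0 - 1.0) * step;
      double nzp = oz + (unif_rand() * 2.0 - 1.0) * step;
      ++attempted;
      if (std::fabs(nxp) > s.box2[0] || std::fabs(nyp) > s.box2[1] ||
          std::fabs(nzp) > s.box2[2])
        continue;
      s.x[i] = nxp; s.y[i] = nyp; s.z[i] = nzp;
      double e_new = s.energy_of(i);
      double dE = e_new - e_old;
      if (std::isfinite(dE) && (dE <= 0.0 || unif_rand() < std::exp(-dE))) {
        etot += dE;
        ++accepted;
      } else {
        s.x[i] = ox; s.y[i] = oy; s.z[i] = oz;
      }
    }
    if (sweep > equil_sweeps && ((sweep - equil_sweeps) % stride == 0)) {
      NumericMatrix fr(s.n_ion + n_water, 3);
      for (int i = 0; i < s.n_ion; ++i) {
        fr(i, 0) = s.x[i];
        fr(i, 1) = s.y[i];
        fr(i, 2) = s.z[i];
      }
      for (int w = 0; w < n_water; ++w) {
        double wx, wy, wz;
        draw_water(&wx, &wy, &wz);
        fr(s.n_ion + w, 0) = wx;
        fr(s.n_ion + w, 1) = wy;
        fr(s.n_ion + w, 2) = wz;
      }
      frames.push_back(fr);
    }
  }
  return List::create(_["frames"] = frames,
                      _["energy_incremental"] = etot,
                      _["energy_recomputed"] = s.total_energy(),
                      _["acceptance"] = (double)accepted / (double)attempted);
}

// per-frame closest-atom distances for a list of frames (used by RDF and
// bound-ion counting); atoms fixed across frames
// [[Rcpp::export]]
List cpp_frame_distances(List frames, NumericMatrix atoms) {
  int nf = frames.size();
  List out(nf);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix fr = frames[f];
    out[f] = cpp_closest_atom_distance(fr, atoms);
  }
  return out;
}
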