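#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Boltzmann constant, kcal/(mol K)
static const double KB = 0.0019872041;
// Coulomb constant, kcal A / (mol e^2)
static const double COULOMB = 332.0636;

// CHARMM-convention 12-6 pair energy: Rmin_ij = rmin_half_i + rmin_half_j,
// eps_ij = sqrt(eps_i eps_j), E = eps_ij [ (Rmin/r)^12 - 2 (Rmin/r)^6 ].
static inline double lj_energy(double rminSum, double epsij, double r2) {
  double s2 = rminSum * rminSum / r2;
  double s6 = s2 * s2 * s2;
  return epsij * (s6 * s6 - 2.0 * s6);
}

static inline double min_image(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// [[Rcpp::export(name = ".ljPairEnergyCpp")]]
NumericVector ljPairEnergyCpp(double rminHalfI, double epsI,
                              double rminHalfJ, double epsJ,
                              NumericVector r) {
  double rminSum = rminHalfI + rminHalfJ;
  double epsij = std::sqrt(epsI * epsJ);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) {
    if (r[i] <= 0.0) stop("lj_pair_energy: r must be > 0");
    out[i] = lj_energy(rminSum, epsij, r[i] * r[i]);
  }
  return out;
}

// Rotation taking the local +z axis onto a unit vector `a` (Rodrigues).
static void rot_from_z(const double *a, double R[3][3]) {
  double az = a[2];
  if (az > 1.0 - 1e-12) {          // identity
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
    return;
  }
  if (az < -1.0 + 1e-12) {         // flip about x
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = 0.0;
    R[0][0] = 1.0; R[1][1] = -1.0; R[2][2] = -1.0;
    return;
  }
  // k = z x a = (-a_y, a_x, 0), sin = |k|, cos = a_z
  double kx = -a[1], ky = a[0];
  double s2 = kx * kx + ky * ky;
  double c = az;
  // R = I + [k]_x + [k]_x^2 (1-c)/s^2
  double f = (1.0 - c) / s2;
  R[0][0] = 1.0 - f * ky * ky; R[0][1] = f * kx * ky;        R[0][2] = ky;
  R[1][0] = f * kx * ky;       R[1][1] = 1.0 - f * kx * kx;  R[1][2] = -kx;
  R[2][0] = -ky;               R[2][1] = kx;                 R[2][2] = c;
}

// Interaction energy of a rigid multi-site probe centred at `pos` with
// orientation axis `axis`, against LJ sites `atomPos` under the minimum-image
// convention (orthorhombic box; box length <= 0 disables imaging on that
// axis). Truncated, unshifted at `cutoff`. Atoms are visited in index order
// so the accumulation order matches a naive loop exactly.
static double insertion_energy(const double *atomPos, const double *rminH,
                               const double *eps, int nAtoms,
                               const double *pos, const double *axis,
                               const double *siteOff, const double *siteRminH,
                               const double *siteEps, int nSites,
                               const double *box, double cutoff,
                               double breakAbove) {
  double R[3][3];
  rot_from_z(axis, R);
  double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int s = 0; s < nSites; ++s) {
    double lx = siteOff[s], ly = siteOff[nSites + s], lz = siteOff[2 * nSites + s];
    double sx = pos[0] + R[0][0] * lx + R[0][1] * ly + R[0][2] * lz;
    double sy = pos[1] + R[1][0] * lx + R[1][1] * ly + R[1][2] * lz;
    double sz = pos[2] + R[2][0] * lx + R[2][1] * ly + R[2][2] * lz;
    double rh = siteRminH[s], ep = siteEps[s];
    for (int a = 0; a < nAtoms; ++a) {
      double epa = eps[a];
      if (epa == 0.0) continue;
      double dx = min_image(atomPos[a] - sx, box[0]);
      double dy = min_image(atomPos[nAtoms + a] - sy, box[1]);
      double dz = min_image(atomPos[2 * nAtoms + a] - sz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      if (r2 == 0.0) return std::numeric_limits<double>::infinity();
      e += lj_energy(rh + rminH[a], std::sqrt(ep * epa), r2);
      if (e > breakAbove) return e;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".insertionEnergyCpp")]]
double insertionEnergyCpp(NumericMatrix atomPos, NumericVector rminHalf,
                          NumericVector eps, NumericVector pos,
                          NumericVector axis, NumericMatrix siteOffsets,
                          NumericVector siteRminHalf, NumericVector siteEps,
                          NumericVector box, double cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0");
  return insertion_energy(atomPos.begin(), rminHalf.begin(), eps.begin(),
                          atomPos.nrow(), pos.begin(), axis.begin(),
                          siteOffsets.begin(), siteRminHalf.begin(),
                          siteEps.begin(), siteOffsets.nrow(), box.begin(),
                          cutoff, std::numeric_limits<double>::infinity());
}

// Core of the 3D gas PMF: per voxel r,
//   G(r) = -kB T log( (1/(N C)) sum_{m,k} exp(-beta dE_{m,k}(r)) ),
// with dE above `energyCap` given zero Boltzmann weight. Voxels where every
// sample is capped are flagged occluded. Every retained Boltzmann factor is
// >= exp(-beta*cap), far above double underflow, so plain summation is exact.
// [[Rcpp::export(name = ".ilsMapCpp")]]
List ilsMapCpp(NumericVector coords, int nAtoms, int nFrames,
               NumericVector rminHalf, NumericVector eps, NumericMatrix box,
               NumericMatrix axes, NumericMatrix siteOffsets,
               NumericVector siteRminHalf, NumericVector siteEps,
               NumericVector origin, double spacing, IntegerVector dims,
               double temperature, double cutoff, double energyCap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nVox = (R_xlen_t)nx * ny * nz;
  int nC = axes.nrow();
  int nSites = siteOffsets.nrow();
  double beta = 1.0 / (KB * temperature);

  // early-exit threshold: remaining pair terms are bounded below by
  // -(nAtoms*nSites)*eps_max, so exceeding cap + bound proves dE > cap.
  double epsMaxA = 0.0, epsMaxS = 0.0;
  for (int a = 0; a < nAtoms; ++a) epsMaxA = std::max(epsMaxA, eps[a]);
  for (int s = 0; s < nSites; ++s) epsMaxS = std::max(epsMaxS, siteEps[s]);
  double bound = (double)nAtoms * nSites * std::sqrt(epsMaxA * epsMaxS);
  double breakAbove = energyCap + bound + 1.0;

  std::vector<double> sumW(nVox, 0.0);
  double posv[3], axv[3];
  for (int m = 0; m < nFrames; ++m) {
    const double *fr = coords.begin() + (R_xlen_t)m * nAtoms * 3;
    const double *bx = NULL;
    double bvec[3] = { box(m, 0), box(m, 1), box(m, 2) };
    bx = bvec;
    R_xlen_t v = 0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i, ++v) {
          posv[0] = origin[0] + spacing * i;
          posv[1] = origin[1] + spacing * j;
          posv[2] = origin[2] + spacing * k;
          double w = 0.0;
          for (int c = 0; c < nC; ++c) {
            axv[0] = axes(c, 0); axv[1] = axes(c, 1); axv[2] = axes(c, 2);
            double dE = insertion_energy(fr, rminHalf.begin(), eps.begin(),
                                         nAtoms, posv, axv,
                                         siteOffsets.begin(),
                                         siteRminHalf.begin(), siteEps.begin(),
                                         nSites, bx, cutoff, breakAbove);
            if (dE <= energyCap) w += std::exp(-beta * dE);
          }
          sumW[v] += w;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector G(nVox);
  LogicalVector occluded(nVox);
  double norm = (double)nFrames * nC;
  for (R_xlen_t v = 0; v < nVox; ++v) {
    if (sumW[v] <= 0.0) {
      occluded[v] = true;
      G[v] = NA_REAL;  // caller substitutes the display cap
    } else {
      occluded[v] = false;
      G[v] = -KB * temperature * std::log(sumW[v] / norm);
    }
  }
  return List::create(_["G"] = G, _["occluded"] = occluded);
}

// ---------------------------------------------------------------------------
// Rigid-water Metropolis Monte Carlo (three-site model, O-site LJ only,
// Coulomb with a molecule-based cutoff on the O-O distance and an
// infinite-dielectric reaction-field correction).
// ---------------------------------------------------------------------------

struct WaterSystem {
  int n;
  double L, rc, rc2, krf, crf;
  double rminO, epsO;
  std::vector<double> q;          // site charges (O,H,H)
  std::vector<double> x, y, z;    // 3n sites, molecule-major (O,H1,H2)
};

// pair energy between molecules i and j, whole-molecule minimum image
// anchored on the O-O separation
static double water_pair(const WaterSystem &w, int i, int j) {
  int oi = 3 * i, oj = 3 * j;
  double dx = w.x[oj] - w.x[oi], dy = w.y[oj] - w.y[oi], dz = w.z[oj] - w.z[oi];
  double sx = -w.L * std::round(dx / w.L);
  double sy = -w.L * std::round(dy / w.L);
  double sz = -w.L * std::round(dz / w.L);
  double ox = dx + sx, oy = dy + sy, oz = dz + sz;
  double r2 = ox * ox + oy * oy + oz * oz;
  if (r2 >= w.rc2) return 0.0;
  double e = lj_energy(2.0 * w.rminO, w.epsO, r2);
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      double ax = w.x[oj + b] + sx - w.x[oi + a];
      double ay = w.y[oj + b] + sy - w.y[oi + a];
      double az = w.z[oj + b] + sz - w.z[oi + a];
      double rr2 = ax * ax + ay * ay + az * az;
      double r = std::sqrt(rr2);
      e += COULOMB * w.q[a] * w.q[b] * (1.0 / r + w.krf * rr2 - w.crf);
    }
  }
  return e;
}

static double water_mol_energy(const WaterSystem &w, int i) {
  double e = 0.0;
  for (int j = 0; j < w.n; ++j) if (j != i) e += water_pair(w, i, j);
  return e;
}

// [[Rcpp::export(name = ".waterPairEnergyCpp")]]
double waterPairEnergyCpp(NumericMatrix sitesI, NumericMatrix sitesJ,
                          double boxL, double rc,
                          double rminO, double epsO, NumericVector charges) {
  WaterSystem w;
  w.n = 2; w.L = boxL; w.rc = rc; w.rc2 = rc * rc;
  w.krf = 1.0 / (2.0 * rc * rc * rc);
  w.crf = 3.0 / (2.0 * rc);
  w.rminO = rminO; w.epsO = epsO;
  w.q.assign(charges.begin(), charges.end());
  w.x.resize(6); w.y.resize(6); w.z.resize(6);
  for (int a = 0; a < 3; ++a) {
    w.x[a] = sitesI(a, 0); w.y[a] = sitesI(a, 1); w.z[a] = sitesI(a, 2);
    w.x[3 + a] = sitesJ(a, 0); w.y[3 + a] = sitesJ(a, 1); w.z[3 + a] = sitesJ(a, 2);
  }
  return water_pair(w, 0, 1);
}

static void random_rotation(double R[3][3]) {
  // uniform random rotation via random unit axis + uniform angle would not be
  // Haar-uniform, but as a *symmetric proposal* any axis/angle density works;
  // here: random axis (marsaglia), angle uniform in [-pi, pi].
  double u1, u2, s;
  do {
    u1 = 2.0 * R::runif(0.0, 1.0) - 1.0;
    u2 = 2.0 * R::runif(0.0, 1.0) - 1.0;
    s = u1 * u1 + u2 * u2;
  } while (s >= 1.0 || s == 0.0);
  double ax = 2.0 * u1 * std::sqrt(1.0 - s);
  double ay = 2.0 * u2 * std::sqrt(1.0 - s);
  double az = 1.0 - 2.0 * s;
  double th = R::runif(-M_PI, M_PI);
  double c = std::cos(th), si = std::sin(th), mc = 1.0 - c;
  R[0][0] = c + ax * ax * mc;      R[0][1] = ax * ay * mc - az * si; R[0][2] = ax * az * mc + ay * si;
  R[1][0] = ay * ax * mc + az * si; R[1][1] = c + ay * ay * mc;      R[1][2] = ay * az * mc - ax * si;
  R[2][0] = az * ax * mc - ay * si; R[2][1] = az * ay * mc + ax * si; R[2][2] = c + az * az * mc;
}

static void rotate_about(double R[3][3], double px, double py, double pz,
                         double &x, double &y, double &z) {
  double dx = x - px, dy = y - py, dz = z - pz;
  x = px + R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
  y = py + R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
  z = pz + R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
}

// [[Rcpp::export(name = ".waterBoxMCCpp")]]
List waterBoxMCCpp(int nMol, double boxL, double temperature,
                   int equilSweeps, int nFrames, int sampleInterval,
                   double maxTrans, double maxRotDeg, double rc,
                   double rminO, double epsO, NumericVector charges,
                   double rOH, double angHOHdeg) {
  WaterSystem w;
  w.n = nMol; w.L = boxL; w.rc = rc; w.rc2 = rc * rc;
  w.krf = 1.0 / (2.0 * rc * rc * rc);
  w.crf = 3.0 / (2.0 * rc);
  w.rminO = rminO; w.epsO = epsO;
  w.q.assign(charges.begin(), charges.end());
  w.x.resize(3 * nMol); w.y.resize(3 * nMol); w.z.resize(3 * nMol);

  // local water geometry: O at origin, H's in the xz plane
  double half = 0.5 * angHOHdeg * M_PI / 180.0;
  double hx = rOH * std::sin(half), hz = rOH * std::cos(half);
  double local[3][3] = { {0, 0, 0}, {hx, 0, hz}, {-hx, 0, hz} };

  int ng = (int)std::ceil(std::cbrt((double)nMol));
  double a = boxL / ng;
  int m = 0;
  for (int i = 0; i < ng && m < nMol; ++i)
    for (int j = 0; j < ng && m < nMol; ++j)
      for (int k = 0; k < ng && m < nMol; ++k, ++m) {
        double R[3][3];
        random_rotation(R);
        double ox = (i + 0.5) * a, oy = (j + 0.5) * a, oz = (k + 0.5) * a;
        for (int s = 0; s < 3; ++s) {
          double lx = local[s][0], ly = local[s][1], lz = local[s][2];
          w.x[3 * m + s] = ox + R[0][0] * lx + R[0][1] * ly + R[0][2] * lz;
          w.y[3 * m + s] = oy + R[1][0] * lx + R[1][1] * ly + R[1][2] * lz;
          w.z[3 * m + s] = oz + R[2][0] * lx + R[2][1] * ly + R[2][2] * lz;
        }
      }

  double beta = 1.0 / (KB * temperature);
  double maxRot = maxRotDeg * M_PI / 180.0;
  long nAcc = 0, nTry = 0;
  int totalSweeps = equilSweeps + nFrames * sampleInterval;
  NumericVector frames((R_xlen_t)nFrames * 3 * nMol * 3);
  int frameOut = 0;

  std::vector<double> oldx(3), oldy(3), oldz(3);
  for (int sweep = 0; sweep < totalSweeps; ++sweep) {
    for (int mv = 0; mv < nMol; ++mv) {
      int i = (int)std::floor(R::runif(0.0, 1.0) * nMol);
      if (i >= nMol) i = nMol - 1;
      double e0 = water_mol_energy(w, i);
      for (int s = 0; s < 3; ++s) {
        oldx[s] = w.x[3 * i + s]; oldy[s] = w.y[3 * i + s]; oldz[s] = w.z[3 * i + s];
      }
      double tx = R::runif(-maxTrans, maxTrans);
      double ty = R::runif(-maxTrans, maxTrans);
      double tz = R::runif(-maxTrans, maxTrans);
      double R3[3][3];
      // rotation with angle scaled to maxRot
      {
        double u1, u2, s;
        do {
          u1 = 2.0 * R::runif(0.0, 1.0) - 1.0;
          u2 = 2.0 * R::runif(0.0, 1.0) - 1.0;
          s = u1 * u1 + u2 * u2;
        } while (s >= 1.0 || s == 0.0);
        double ax = 2.0 * u1 * std::sqrt(1.0 - s);
        double ay = 2.0 * u2 * std::sqrt(1.0 - s);
        double az = 1.0 - 2.0 * s;
        double th = R::runif(-maxRot, maxRot);
        double c = std::cos(th), si = std::sin(th), mc = 1.0 - c;
        R3[0][0] = c + ax * ax * mc;      R3[0][1] = ax * ay * mc - az * si; R3[0][2] = ax * az * mc + ay * si;
        R3[1][0] = ay * ax * mc + az * si; R3[1][1] = c + ay * ay * mc;      R3[1][2] = ay * az * mc - ax * si;
        R3[2][0] = az * ax * mc - ay * si; R3[2][1] = az * ay * mc + ax * si; R3[2][2] = c + az * az * mc;
      }
      double px = w.x[3 * i], py = w.y[3 * i], pz = w.z[3 * i];
      for (int s = 0; s < 3; ++s) {
        rotate_about(R3, px, py, pz, w.x[3 * i + s], w.y[3 * i + s], w.z[3 * i + s]);
        w.x[3 * i + s] += tx; w.y[3 * i + s] += ty; w.z[3 * i + s] += tz;
      }
      double e1 = water_mol_energy(w, i);
      double dE = e1 - e0;
      ++nTry;
      if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-beta * dE)) {
        ++nAcc;
      } else {
        for (int s = 0; s < 3; ++s) {
          w.x[3 * i + s] = oldx[s]; w.y[3 * i + s] = oldy[s]; w.z[3 * i + s] = oldz[s];
        }
      }
    }
    if (sweep >= equilSweeps &&
        (sweep - equilSweeps + 1) % sampleInterval == 0 && frameOut < nFrames) {
      R_xlen_t off = (R_xlen_t)frameOut * 3 * nMol * 3;
      int nAtoms = 3 * nMol;
      for (int s = 0; s < nAtoms; ++s) {
        // wrap O into the box, keep molecule intact
        int mol = s / 3, o = 3 * mol;
        double wx = w.L * std::floor(w.x[o] / w.L);
        double wy = w.L * std::floor(w.y[o] / w.L);
        double wz = w.L * std::floor(w.z[o] / w.L);
        frames[off + s] = w.x[s] - wx;
        frames[off + nAtoms + s] = w.y[s] - wy;
        frames[off + 2 * nAtoms + s] = w.z[s] - wz;
      }
      ++frameOut;
    }
    if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["frames"] = frames,
                      _["acceptance"] = (double)nAcc / (double)nTry);
}

// ---------------------------------------------------------------------------
// Single-site Lennard-Jones fluid Metropolis MC
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".ljFluidMCCpp")]]
List ljFluidMCCpp(int n, double boxL, double rminHalf, double eps,
                  double temperature, int equilSweeps, int nFrames,
                  int sampleInterval, double maxTrans, double rc) {
  std::vector<double> x(n), y(n), z(n);
  int ng = (int)std::ceil(std::cbrt((double)n));
  double a = boxL / ng;
  int m = 0;
  for (int i = 0; i < ng && m < n; ++i)
    for (int j = 0; j < ng && m < n; ++j)
      for (int k = 0; k < ng && m < n; ++k, ++m) {
        x[m] = (i + 0.5) * a; y[m] = (j + 0.5) * a; z[m] = (k + 0.5) * a;
      }
  double beta = 1.0 / (KB * temperature);
  double rc2 = rc * rc, rminSum = 2.0 * rminHalf;
  long nAcc = 0, nTry = 0;
  int totalSweeps = equilSweeps + nFrames * sampleInterval;
  NumericVector frames((R_xlen_t)nFrames * n * 3);
  int frameOut = 0;

  auto part_energy = [&](int i, double xi, double yi, double zi) {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = min_image(x[j] - xi, boxL);
      double dy = min_image(y[j] - yi, boxL);
      double dz = min_image(z[j] - zi, boxL);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2) e += lj_energy(rminSum, eps, r2);
    }
    return e;
  };

  for (int sweep = 0; sweep < totalSweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int i = (int)std::floor(R::runif(0.0, 1.0) * n);
      if (i >= n) i = n - 1;
      double nx = x[i] + R::runif(-maxTrans, maxTrans);
      double ny = y[i] + R::runif(-maxTrans, maxTrans);
      double nz = z[i] + R::runif(-maxTrans, maxTrans);
      double dE = (eps == 0.0) ? 0.0
        : part_energy(i, nx, ny, nz) - part_energy(i, x[i], y[i], z[i]);
      ++nTry;
      if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-beta * dE)) {
        ++nAcc;
        x[i] = nx - boxL * std::floor(nx / boxL);
        y[i] = ny - boxL * std::floor(ny / boxL);
        z[i] = nz - boxL * std::floor(nz / boxL);
      }
    }
    if (sweep >= equilSweeps &&
        (sweep - equilSweeps + 1) % sampleInterval == 0 && frameOut < nFrames) {
      R_xlen_t off = (R_xlen_t)frameOut * n * 3;
      for (int s = 0; s < n; ++s) {
        frames[off + s] = x[s];
        frames[off + n + s] = y[s];
        frames[off + 2 * n + s] = z[s];
      }
      ++frameOut;
    }
    if (sweep % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["frames"] = frames,
                      _["acceptance"] = (double)nAcc / (double)nTry);
}

// ---------------------------------------------------------------------------
// Exact bottleneck-shortest-path (widest-path variant of best-first search)
// on the voxel lattice with 26-connectivity. The path cost is the maximum G
// along it (start included); ties are broken by fewer steps, then by
// lexicographically smallest voxel index.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".minimaxPathCpp")]]
List minimaxPathCpp(NumericVector G, IntegerVector dims, LogicalVector occluded,
                    int start, IntegerVector goal) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nVox = (R_xlen_t)nx * ny * nz;
  std::vector<bool> isGoal(nVox, false);
  for (R_xlen_t g = 0; g < goal.size(); ++g) isGoal[goal[g]] = true;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> best(nVox, INF);
  std::vector<long> steps(nVox, -1);
  std::vector<int> pred(nVox, -1);
  std::vector<bool> done(nVox, false);

  if (occluded[start])
    return List::create(_["connected"] = false);

  typedef std::tuple<double, long, int> Key;  // (bottleneck, steps, voxel)
  std::set<Key> pq;
  best[start] = G[start];
  steps[start] = 0;
  pq.insert(Key(best[start], 0, start));

  int found = -1;
  while (!pq.empty()) {
    Key top = *pq.begin();
    pq.erase(pq.begin());
    int v = std::get<2>(top);
    if (done[v]) continue;
    done[v] = true;
    if (isGoal[v]) { found = v; break; }
    int vi = v % nx, vj = (v / nx) % ny, vk = v / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ni = vi + di, nj = vj + dj, nk = vk + dk;
          if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
            continue;
          int u = ni + nx * (nj + ny * nk);
          if (done[u] || occluded[u]) continue;
          double nb = std::max(best[v], G[u]);
          long ns = steps[v] + 1;
          bool better = nb < best[u] ||
            (nb == best[u] && (ns < steps[u] ||
             (ns == steps[u] && pred[u] >= 0 && v < pred[u])));
          if (better) {
            if (steps[u] >= 0) pq.erase(Key(best[u], steps[u], u));
            best[u] = nb; steps[u] = ns; pred[u] = v;
            pq.insert(Key(nb, ns, u));
          }
        }
  }
  if (found < 0) return List::create(_["connected"] = false);
  std::vector<int> path;
  for (int v = found; v >= 0; v = pred[v]) {
    path.push_back(v);
    if (v == start) break;
  }
  std::reverse(path.begin(), path.end());
  IntegerVector p(path.begin(), path.end());
  return List::create(_["connected"] = true,
                      _["path"] = p + 1,        // 1-based for R
                      _["bottleneck"] = best[found]);
}
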