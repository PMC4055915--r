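// Metropolis Monte-Carlo engine for the C-alpha bead chain under the
// Gaussian inter-residue distance potential.
//
// A chain of N beads with fixed virtual bonds is perturbed joint by joint:
// for the bond between beads i and i+1 the downstream segment is rotated
// rigidly, first about an axis perpendicular to the bond (bend, changing
// the bond angle at bead i) and then about the bond axis itself (torsion),
// each by an independent uniform angle in [-amax, +amax]. Rigid rotation
// of the downstream segment leaves all internal downstream distances
// unchanged, so the energy difference involves only pairs that cross the
// joint. Energies are the dimensionless Gaussian quadratic
// (r - rbar)^2 / (2 sigma^2); the Metropolis ratio uses exp(-dU / kT).
// The per-pair constant -log(Z / (sqrt(2 pi) sigma)) is conformation
// independent and cancels in dU, so it is never evaluated here.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pair_u(double dx, double dy, double dz,
                            double rbar, double sig) {
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  double z = (r - rbar) / sig;
  return 0.5 * z * z;
}

// energy over pairs (a <= j, b > j) with b - a >= 2, coordinates taken
// from X for a <= j and from Y (proposed downstream buffer, offset j+1)
// for b > j
static double cross_energy(const NumericMatrix& X, const NumericMatrix& Y,
                           int j, int n,
                           const NumericMatrix& rbar,
                           const NumericMatrix& sig) {
  double u = 0.0;
  for (int a = 0; a <= j; ++a) {
    double ax = X(a, 0), ay = X(a, 1), az = X(a, 2);
    int b0 = std::max(j + 1, a + 2);
    for (int b = b0; b < n; ++b) {
      u += pair_u(ax - Y(b, 0), ay - Y(b, 1), az - Y(b, 2),
                  rbar(a, b), sig(a, b));
    }
  }
  return u;
}

static void rotate_about(NumericMatrix& Y, int from, int n,
                         const double* c, const double* axis, double ang) {
  double ca = std::cos(ang), sa = std::sin(ang);
  double ux = axis[0], uy = axis[1], uz = axis[2];
  for (int k = from; k < n; ++k) {
    double px = Y(k, 0) - c[0], py = Y(k, 1) - c[1], pz = Y(k, 2) - c[2];
    double dot = ux * px + uy * py + uz * pz;
    double cx = uy * pz - uz * py;
    double cy = uz * px - ux * pz;
    double cz = ux * py - uy * px;
    Y(k, 0) = c[0] + px * ca + cx * sa + ux * dot * (1 - ca);
    Y(k, 1) = c[1] + py * ca + cy * sa + uy * dot * (1 - ca);
    Y(k, 2) = c[2] + pz * ca + cz * sa + uz * dot * (1 - ca);
  }
}

static void unit_perp(const double* v, double* out) {
  // deterministic unit vector perpendicular to v
  double ax = std::fabs(v[0]), ay = std::fabs(v[1]), az = std::fabs(v[2]);
  double e[3] = {0, 0, 0};
  if (ax <= ay && ax <= az) e[0] = 1;
  else if (ay <= az) e[1] = 1;
  else e[2] = 1;
  out[0] = v[1] * e[2] - v[2] * e[1];
  out[1] = v[2] * e[0] - v[0] * e[2];
  out[2] = v[0] * e[1] - v[1] * e[0];
  double nrm = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
  out[0] /= nrm; out[1] /= nrm; out[2] /= nrm;
}

// [[Rcpp::export]]
double chain_energy_cpp(NumericMatrix coords, NumericMatrix rbar,
                        NumericMatrix sigma) {
  int n = coords.nrow();
  double u = 0.0;
  for (int a = 0; a < n - 2; ++a)
    for (int b = a + 2; b < n; ++b)
      u += pair_u(coords(a, 0) - coords(b, 0), coords(a, 1) - coords(b, 1),
                  coords(a, 2) - coords(b, 2), rbar(a, b), sigma(a, b));
  return u;
}

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix coords, NumericMatrix rbar, NumericMatrix sigma,
                double kT, int n_sweeps, int burn_in_sweeps,
                double contact_cutoff, double max_angle_deg, bool collect) {
  int n = coords.nrow();
  NumericMatrix X = clone(coords);
  NumericMatrix Y(n, 3);  // proposal buffer for the downstream segment
  NumericMatrix g(n, n);
  IntegerVector acc_sweep(n_sweeps);
  double amax = max_angle_deg * M_PI / 180.0;
  long accepted = 0, trials = 0;
  long accepted_post = 0, trials_post = 0;
  int n_samples = 0;
  double cut2 = contact_cutoff * contact_cutoff;

  for (int sw = 0; sw < n_sweeps; ++sw) {
    int acc_this = 0;
    for (int j = 0; j < n - 1; ++j) {
      // copy downstream into buffer
      for (int k = j + 1; k < n; ++k) {
        Y(k, 0) = X(k, 0); Y(k, 1) = X(k, 1); Y(k, 2) = X(k, 2);
      }
      double c[3] = {X(j, 0), X(j, 1), X(j, 2)};
      double bond[3] = {X(j + 1, 0) - c[0], X(j + 1, 1) - c[1],
                        X(j + 1, 2) - c[2]};
      double bl = std::sqrt(bond[0] * bond[0] + bond[1] * bond[1] +
                            bond[2] * bond[2]);
      double bu[3] = {bond[0] / bl, bond[1] / bl, bond[2] / bl};
      // bend axis: perpendicular to the previous bond and this bond;
      // falls back to a fixed perpendicular for the first joint or
      // collinear bonds
      double axis[3];
      bool have_axis = false;
      if (j > 0) {
        double p[3] = {c[0] - X(j - 1, 0), c[1] - X(j - 1, 1),
                       c[2] - X(j - 1, 2)};
        axis[0] = p[1] * bu[2] - p[2] * bu[1];
        axis[1] = p[2] * bu[0] - p[0] * bu[2];
        axis[2] = p[0] * bu[1] - p[1] * bu[0];
        double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                               axis[2] * axis[2]);
        if (nrm > 1e-9) {
          axis[0] /= nrm; axis[1] /= nrm; axis[2] /= nrm;
          have_axis = true;
        }
      }
      if (!have_axis) unit_perp(bu, axis);

      double dbend = R::runif(-amax, amax);
      double dtors = R::runif(-amax, amax);
      rotate_about(Y, j + 1, n, c, axis, dbend);
      // torsion about the (rotated) bond direction through bead j
      double nb[3] = {Y(j + 1, 0) - c[0], Y(j + 1, 1) - c[1],
                      Y(j + 1, 2) - c[2]};
      double nbl = std::sqrt(nb[0] * nb[0] + nb[1] * nb[1] + nb[2] * nb[2]);
      nb[0] /= nbl; nb[1] /= nbl; nb[2] /= nbl;
      rotate_about(Y, j + 1, n, c, nb, dtors);

      double u_old = cross_energy(X, X, j, n, rbar, sigma);
      double u_new = cross_energy(X, Y, j, n, rbar, sigma);
      double du = u_new - u_old;
      ++trials;
      bool take = du <= 0.0 || R::runif(0.0, 1.0) < std::exp(-du / kT);
      if (take) {
        for (int k = j + 1; k < n; ++k) {
          X(k, 0) = Y(k, 0); X(k, 1) = Y(k, 1); X(k, 2) = Y(k, 2);
        }
        ++accepted;
        ++acc_this;
      }
    }
    acc_sweep[sw] = acc_this;
    if (sw >= burn_in_sweeps) {
      trials_post += n - 1;
      accepted_post += acc_this;
      if (collect) {
        ++n_samples;
        for (int a = 0; a < n - 2; ++a)
          for (int b = a + 2; b < n; ++b) {
            double dx = X(a, 0) - X(b, 0), dy = X(a, 1) - X(b, 1),
                   dz = X(a, 2) - X(b, 2);
            if (dx * dx + dy * dy + dz * dz <= cut2) {
              g(a, b) += 1.0;
              g(b, a) += 1.0;
            }
          }
      }
    }
  }
  return List::create(
    _["coords"] = X, _["g_counts"] = g, _["n_samples"] = n_samples,
    _["accepted"] = (double)accepted, _["trials"] = (double)trials,
    _["accepted_post"] = (double)accepted_post,
    _["trials_post"] = (double)trials_post,
    _["acceptance"] = trials ? (double)accepted / trials : NA_REAL,
    _["acceptance_post"] =
        trials_post ? (double)accepted_post / trials_post : NA_REAL,
    _["acc_per_sweep"] = acc_sweep);
}
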