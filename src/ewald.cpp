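#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KE_COUL = 1389.35458; // e^2/(4 pi eps0), kJ Å / mol

// Reciprocal-space energy and forces of spherical Gaussian charges in an
// orthorhombic periodic box.  Site i carries charge q[i] (e) and Gaussian
// exponent beta[i] (1/Å): rho_i(r) = q_i (beta_i^2/pi)^(3/2) exp(-beta_i^2 r^2).
// The k-space form factor is exp(-k^2/(4 beta_i^2)); wide Gaussians make the
// sum converge with few wave vectors, so no real-space Ewald split is needed.
// The k = 0 term is omitted (tinfoil / neutralising-background convention)
// and the Gaussian self-energy q_i^2 beta_i / sqrt(2 pi) is subtracted.
// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector q, NumericVector beta,
               NumericVector L, double kmax) {
  int n = pos.nrow();
  double V = L[0] * L[1] * L[2];
  int nmax[3];
  for (int a = 0; a < 3; a++)
    nmax[a] = (int)std::ceil(kmax * L[a] / (2.0 * M_PI));
  double E = 0.0;
  NumericMatrix F(n, 3);
  std::vector<double> kr(n), cf(n), sf(n);
  long nk = 0;
  for (int ix = -nmax[0]; ix <= nmax[0]; ix++)
    for (int iy = -nmax[1]; iy <= nmax[1]; iy++)
      for (int iz = -nmax[2]; iz <= nmax[2]; iz++) {
        if (ix == 0 && iy == 0 && iz == 0) continue;
        double kx = 2.0 * M_PI * ix / L[0];
        double ky = 2.0 * M_PI * iy / L[1];
        double kz = 2.0 * M_PI * iz / L[2];
        double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 > kmax * kmax) continue;
        nk++;
        double sre = 0.0, sim = 0.0;
        for (int i = 0; i < n; i++) {
          kr[i] = kx * pos(i, 0) + ky * pos(i, 1) + kz * pos(i, 2);
          double a = q[i] * std::exp(-k2 / (4.0 * beta[i] * beta[i]));
          cf[i] = a * std::cos(kr[i]);
          sf[i] = a * std::sin(kr[i]);
          sre += cf[i];
          sim += sf[i];
        }
        double pref = 2.0 * M_PI * KE_COUL / (V * k2);
        E += pref * (sre * sre + sim * sim);
        for (int i = 0; i < n; i++) {
          double fmag = 2.0 * pref * (sre * sf[i] - sim * cf[i]);
          F(i, 0) += fmag * kx;
          F(i, 1) += fmag * ky;
          F(i, 2) += fmag * kz;
        }
      }
  // Gaussian self-energy
  double Eself = 0.0;
  for (int i = 0; i < n; i++)
    Eself += KE_COUL * q[i] * q[i] * beta[i] / std::sqrt(2.0 * M_PI);
  // charged-cell background correction (zero for neutral sets)
  double Q = 0.0, S = 0.0;
  for (int i = 0; i < n; i++) {
    Q += q[i];
    S += q[i] / (beta[i] * beta[i]);
  }
  double Ebg = -M_PI * KE_COUL * Q * S / (2.0 * V);
  return List::create(_["energy"] = E - Eself + Ebg,
                      _["forces"] = F, _["n_kvec"] = nk,
                      _["net_charge"] = Q);
}

// Real-space partial sums of the same Gaussian-charge lattice energy over
// cubic image shells (Chebyshev norm of the image vector).  Element s+1 of
// the result is the energy including all images with max-norm <= s.
// Pair energy: q_i q_j erf(b_ij r)/r with b_ij = b_i b_j / sqrt(b_i^2+b_j^2);
// self-image terms (i == j, image != 0) enter with weight 1/2 like all
// ordered pairs.  O(N^2 shells^3); verification use only.
// [[Rcpp::export]]
NumericVector cpp_direct_shells(NumericMatrix pos, NumericVector q,
                                NumericVector beta, NumericVector L,
                                int max_shell) {
  int n = pos.nrow();
  NumericVector out(max_shell + 1);
  double E = 0.0;
  for (int s = 0; s <= max_shell; s++) {
    for (int ix = -s; ix <= s; ix++)
      for (int iy = -s; iy <= s; iy++)
        for (int iz = -s; iz <= s; iz++) {
          int cheb = std::max(std::abs(ix), std::max(std::abs(iy), std::abs(iz)));
          if (cheb != s) continue; // only the new shell
          bool home = (s == 0);
          double vx = ix * L[0], vy = iy * L[1], vz = iz * L[2];
          for (int i = 0; i < n; i++) {
            int j0 = home ? i + 1 : 0;
            for (int j = j0; j < n; j++) {
              double dx = pos(i, 0) - pos(j, 0) + vx;
              double dy = pos(i, 1) - pos(j, 1) + vy;
              double dz = pos(i, 2) - pos(j, 2) + vz;
              double r = std::sqrt(dx * dx + dy * dy + dz * dz);
              double bij = beta[i] * beta[j] /
                           std::sqrt(beta[i] * beta[i] + beta[j] * beta[j]);
              double e = KE_COUL * q[i] * q[j] * std::erf(bij * r) / r;
              E += home ? e : 0.5 * e;
            }
          }
        }
    out[s] = E;
  }
  return out;
}
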