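#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Package-wide unit system: Å, ps, K, kJ/mol.
static const double KB_KJMOL = 0.008314463; // kJ/mol/K

// cubic switch: 1 below lo, 0 above hi, (y-1)^2(1+2y) in between
static inline double cswitch(double r, double lo, double hi) {
  if (r <= lo) return 1.0;
  if (r >= hi) return 0.0;
  double y = (r - lo) / (hi - lo);
  return (y - 1.0) * (y - 1.0) * (1.0 + 2.0 * y);
}
static inline double cswitch_deriv(double r, double lo, double hi) {
  if (r <= lo || r >= hi) return 0.0;
  double y = (r - lo) / (hi - lo);
  return 6.0 * y * (y - 1.0) / (hi - lo);
}

// Model potentials.  `code` selects the family, `par` its parameters:
//   1 harmonic           : par = (k, center), any dimension
//   2 barrier double well: par = (h, w, a, kconf)  [1D: Gaussian barrier at 0,
//                          harmonic confinement beyond |x| = a]
//   3 radial pair model  : par = (nb, {center, amp, width} x nb, qq, eps,
//                          r0, krep, trunc, t_lo, t_hi, ton, on_lo, on_hi);
//                          3D, U depends on r; the screened tail ramps on
//                          over [on_lo, on_hi] (bulk screening only beyond
//                          the solvation shells) and, if trunc, off over
//                          [t_lo, t_hi]
//   4 flat in reflecting sphere: par = (R); 3D, U = 0
static const double KE_COUL = 1389.35458; // e^2 Coulomb constant, kJ Å / mol

static double radial_U(const double* p, double r) {
  int nb = (int)p[0];
  double u = 0.0;
  for (int i = 0; i < nb; i++) {
    double c = p[1 + 3 * i], a = p[2 + 3 * i], w = p[3 + 3 * i];
    double z = (r - c) / w;
    u += a * std::exp(-0.5 * z * z);
  }
  const double* q = p + 1 + 3 * nb;
  double qq = q[0], eps = q[1], r0 = q[2], krep = q[3];
  int trunc = (int)q[4];
  double tlo = q[5], thi = q[6];
  int ton = (int)q[7];
  double olo = q[8], ohi = q[9];
  double tail = qq * KE_COUL / (eps * r);
  if (ton) tail *= 1.0 - cswitch(r, olo, ohi);
  if (trunc) tail *= cswitch(r, tlo, thi);
  u += tail;
  if (r < r0) u += krep * (r - r0) * (r - r0);
  return u;
}
static double radial_dU(const double* p, double r) {
  int nb = (int)p[0];
  double du = 0.0;
  for (int i = 0; i < nb; i++) {
    double c = p[1 + 3 * i], a = p[2 + 3 * i], w = p[3 + 3 * i];
    double z = (r - c) / w;
    du += -a * z / w * std::exp(-0.5 * z * z);
  }
  const double* q = p + 1 + 3 * nb;
  double qq = q[0], eps = q[1], r0 = q[2], krep = q[3];
  int trunc = (int)q[4];
  double tlo = q[5], thi = q[6];
  int ton = (int)q[7];
  double olo = q[8], ohi = q[9];
  // product rule over tail * ramp_on * ramp_off
  double f1 = qq * KE_COUL / (eps * r);
  double d1 = -qq * KE_COUL / (eps * r * r);
  double f2 = ton ? 1.0 - cswitch(r, olo, ohi) : 1.0;
  double d2 = ton ? -cswitch_deriv(r, olo, ohi) : 0.0;
  double f3 = trunc ? cswitch(r, tlo, thi) : 1.0;
  double d3 = trunc ? cswitch_deriv(r, tlo, thi) : 0.0;
  du += d1 * f2 * f3 + f1 * d2 * f3 + f1 * f2 * d3;
  if (r < r0) du += 2.0 * krep * (r - r0);
  return du;
}

// [[Rcpp::export]]
List cpp_pot_eval(int code, NumericVector par, NumericVector x) {
  int dim = x.size();
  double U = 0.0;
  NumericVector g(dim);
  if (code == 1) {
    double k = par[0], c = par[1];
    for (int i = 0; i < dim; i++) {
      U += 0.5 * k * (x[i] - c) * (x[i] - c);
      g[i] = k * (x[i] - c);
    }
  } else if (code == 2) {
    double h = par[0], w = par[1], a = par[2], kc = par[3];
    double z = x[0] / w;
    U = h * std::exp(-0.5 * z * z);
    g[0] = -h * z / w * std::exp(-0.5 * z * z);
    double ax = std::fabs(x[0]);
    if (ax > a) {
      U += kc * (ax - a) * (ax - a);
      g[0] += 2.0 * kc * (ax - a) * (x[0] > 0 ? 1.0 : -1.0);
    }
  } else if (code == 3) {
    double r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
    U = radial_U(par.begin(), r);
    double du = radial_dU(par.begin(), r);
    for (int i = 0; i < 3; i++) g[i] = du * x[i] / r;
  } else if (code == 4) {
    U = 0.0;
  } else {
    stop("unknown potential code");
  }
  return List::create(_["energy"] = U, _["gradient"] = g);
}

struct OpesGrid {
  int n;
  double smin, smax, ds;
  std::vector<double> prob, V, F;
  double sumw, probmax, pref, eps;
  OpesGrid(int n_, double smin_, double smax_, double pref_, double eps_)
      : n(n_), smin(smin_), smax(smax_), ds((smax_ - smin_) / n_),
        prob(n_, 0.0), V(n_, 0.0), F(n_, 0.0), sumw(0.0), probmax(0.0),
        pref(pref_), eps(eps_) {}
  double center(int i) const { return smin + (i + 0.5) * ds; }
  void deposit(double s, double w, double bw) {
    int i0 = (int)std::floor((s - 5.0 * bw - smin) / ds);
    int i1 = (int)std::ceil((s + 5.0 * bw - smin) / ds);
    if (i0 < 0) i0 = 0;
    if (i1 > n - 1) i1 = n - 1;
    for (int i = i0; i <= i1; i++) {
      double z = (center(i) - s) / bw;
      prob[i] += w * std::exp(-0.5 * z * z);
    }
    sumw += w;
  }
  // returns L-inf change of the bias over explored bins
  double update_bias() {
    probmax = 0.0;
    for (int i = 0; i < n; i++)
      if (prob[i] > probmax) probmax = prob[i];
    double dmax = 0.0;
    std::vector<double> Vnew(n);
    for (int i = 0; i < n; i++) {
      double p = probmax > 0 ? prob[i] / probmax : 0.0;
      Vnew[i] = pref * std::log(p + eps);
      if (p > 0.01) { // convergence metric on explored bins only
        double d = std::fabs(Vnew[i] - V[i]);
        if (d > dmax) dmax = d;
      }
    }
    V = Vnew;
    for (int i = 0; i < n; i++) {
      int im = i > 0 ? i - 1 : i, ip = i < n - 1 ? i + 1 : i;
      F[i] = -(V[ip] - V[im]) / ((ip - im) * ds);
    }
    return dmax;
  }
  double value(double s) const {
    if (sumw == 0.0) return 0.0;
    double u = (s - smin) / ds - 0.5;
    if (u <= 0) return V[0];
    if (u >= n - 1) return V[n - 1];
    int i = (int)u;
    double f = u - i;
    return V[i] * (1 - f) + V[i + 1] * f;
  }
  double force(double s) const {
    if (sumw == 0.0) return 0.0;
    double u = (s - smin) / ds - 0.5;
    if (u <= 0 || u >= n - 1) return 0.0;
    int i = (int)u;
    double f = u - i;
    return F[i] * (1 - f) + F[i + 1] * f;
  }
};

// Overdamped Langevin dynamics with optional OPES bias and harmonic walls
// on the collective variable (x for 1D, r = |x| for 3D radial systems).
// Update: x <- x - (dt/friction) dU/dx + sqrt(2 D dt) eta,  D = kB T / friction.
// [[Rcpp::export]]
List cpp_langevin(int code, NumericVector par, int dim, double temperature,
                  double friction, double dt, double nsteps_d, int stride,
                  NumericVector x0, bool record_pos,
                  bool use_opes, double de, double gamma, double kernel_bw,
                  int pace, double smin, double smax, int nbins,
                  NumericMatrix walls) {
  long nsteps = (long)nsteps_d;
  double kT = KB_KJMOL * temperature;
  double D = kT / friction;
  double mob = dt / friction;            // mobility x dt
  double noise = std::sqrt(2.0 * D * dt);
  double beta = kT > 0 ? 1.0 / kT : 0.0;

  double pref = use_opes ? (1.0 - 1.0 / gamma) * kT : 0.0;
  double eps = use_opes ? std::exp(-de * beta / (1.0 - 1.0 / gamma)) : 0.0;
  OpesGrid grid(use_opes ? nbins : 1, smin, smax, pref, eps);

  std::vector<double> x(x0.begin(), x0.end());
  long nrec = nsteps / stride;
  NumericVector rt(nrec), rs(nrec), rb(nrec), rw(nrec);
  NumericMatrix rp(record_pos ? nrec : 1, record_pos ? dim : 1);
  std::vector<double> kc, kw;         // kernel centers and weights
  std::vector<double> dhist;          // bias L-inf change per update
  // snapshot of the bias at 90% of the scheduled updates, for the
  // quasi-static drift diagnostic
  long nupd_total = use_opes ? nsteps / pace : 0;
  long snap_at = (long)std::ceil(0.9 * nupd_total);
  std::vector<double> vsnap;
  long nupd = 0;
  int nwall = walls.nrow();
  long irec = 0;

  for (long step = 1; step <= nsteps; step++) {
    // potential force
    double s = 0.0, fcv = 0.0; // force along the CV from bias + walls
    double gx[3] = {0, 0, 0};
    double r = 0.0;
    if (code == 1) {
      double k = par[0], c = par[1];
      for (int i = 0; i < dim; i++) gx[i] = k * (x[i] - c);
      s = x[0];
    } else if (code == 2) {
      double h = par[0], w = par[1], a = par[2], kc2 = par[3];
      double z = x[0] / w;
      gx[0] = -h * z / w * std::exp(-0.5 * z * z);
      double ax = std::fabs(x[0]);
      if (ax > a) gx[0] += 2.0 * kc2 * (ax - a) * (x[0] > 0 ? 1.0 : -1.0);
      s = x[0];
    } else if (code == 3) {
      r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
      double du = radial_dU(par.begin(), r);
      for (int i = 0; i < 3; i++) gx[i] = du * x[i] / r;
      s = r;
    } else if (code == 4) {
      r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
      s = r;
    } else stop("unknown potential code");

    double biasV = use_opes ? grid.value(s) : 0.0;
    if (use_opes) fcv += grid.force(s);
    double wallE = 0.0;
    for (int iw = 0; iw < nwall; iw++) {
      double loc = walls(iw, 0), kap = walls(iw, 1), side = walls(iw, 2);
      double ex = side > 0 ? s - loc : loc - s;
      if (ex > 0) {
        wallE += kap * ex * ex;
        fcv += -2.0 * kap * ex * (side > 0 ? 1.0 : -1.0);
      }
    }

    // move
    if (dim == 1) {
      x[0] += mob * (-gx[0] + fcv) + noise * norm_rand();
    } else {
      for (int i = 0; i < dim; i++) {
        double f = -gx[i];
        if (fcv != 0.0 && r > 0) f += fcv * x[i] / r;
        x[i] += mob * f + noise * norm_rand();
      }
    }
    if (code == 4) { // reflecting sphere of radius R
      double R = par[0];
      double rr = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
      if (rr > R) {
        double rnew = 2.0 * R - rr;
        if (rnew < 1e-12) rnew = 1e-12;
        for (int i = 0; i < 3; i++) x[i] *= rnew / rr;
      }
    }
    double norm2 = 0.0;
    for (int i = 0; i < dim; i++) norm2 += x[i] * x[i];
    if (!std::isfinite(norm2) || norm2 > 1e16)
      stop("Langevin dynamics diverged at step %ld (|x| not finite); "
           "reduce the timestep", step);

    // record (state after the move, bias as of this step)
    if (step % stride == 0 && irec < nrec) {
      double snew;
      if (dim == 1) snew = x[0];
      else snew = std::sqrt(norm2);
      rt[irec] = step * dt;
      rs[irec] = snew;
      rb[irec] = use_opes ? grid.value(snew) : 0.0;
      double we = 0.0;
      for (int iw = 0; iw < nwall; iw++) {
        double loc = walls(iw, 0), kap = walls(iw, 1), side = walls(iw, 2);
        double ex = side > 0 ? snew - loc : loc - snew;
        if (ex > 0) we += kap * ex * ex;
      }
      rw[irec] = we;
      if (record_pos)
        for (int i = 0; i < dim; i++) rp(irec, i) = x[i];
      irec++;
    }

    // OPES kernel deposition
    if (use_opes && step % pace == 0) {
      double snew = dim == 1 ? x[0] : std::sqrt(norm2);
      double w = std::exp(beta * grid.value(snew));
      grid.deposit(snew, w, kernel_bw);
      kc.push_back(snew);
      kw.push_back(w);
      dhist.push_back(grid.update_bias());
      nupd++;
      if (nupd == snap_at) vsnap = grid.V;
    }
    (void)biasV;
  }

  List bias_state = List::create(
      _["grid_centers"] = use_opes
          ? NumericVector(grid.n, 0.0) : NumericVector(0),
      _["bias"] = NumericVector(grid.V.begin(), grid.V.end()),
      _["prob"] = NumericVector(grid.prob.begin(), grid.prob.end()),
      _["kernel_centers"] = NumericVector(kc.begin(), kc.end()),
      _["kernel_weights"] = NumericVector(kw.begin(), kw.end()),
      _["sum_weights"] = grid.sumw,
      _["update_linf"] = NumericVector(dhist.begin(), dhist.end()),
      _["bias_snapshot"] = NumericVector(vsnap.begin(), vsnap.end()),
      _["snapshot_update"] = (double)snap_at,
      _["n_updates"] = (double)nupd);
  if (use_opes) {
    NumericVector gc(grid.n);
    for (int i = 0; i < grid.n; i++) gc[i] = grid.center(i);
    bias_state["grid_centers"] = gc;
  }
  return List::create(_["time"] = rt, _["cv"] = rs, _["bias"] = rb,
                      _["wall"] = rw, _["positions"] = rp,
                      _["bias_state"] = bias_state);
}

// minimum-image pair distance histogram between index sets ia and ib
// (1-based); when same = true, each unordered pair is counted once.
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, IntegerVector ia,
                            IntegerVector ib, bool same, NumericVector L,
                            double rmax, double dr) {
  int nbins = (int)std::ceil(rmax / dr - 1e-9);
  NumericVector h(nbins);
  int na = ia.size(), nb = ib.size();
  for (int u = 0; u < na; u++) {
    int i = ia[u] - 1;
    int vstart = same ? u + 1 : 0;
    for (int v = vstart; v < nb; v++) {
      int j = ib[v] - 1;
      if (i == j) continue;
      double r2 = 0.0;
      for (int k = 0; k < 3; k++) {
        double d = pos(i, k) - pos(j, k);
        d -= L[k] * std::round(d / L[k]);
        r2 += d * d;
      }
      double r = std::sqrt(r2);
      if (r < rmax) {
        int b = (int)(r / dr);
        if (b >= 0 && b < nbins) h[b] += 1.0;
      }
    }
  }
  return h;
}
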