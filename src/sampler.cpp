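#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Periodic dihedral sampling engine.
//
// All angles are in degrees, canonical range [-180, 180).  Energies in
// kJ/mol.  The target density is exp(-[U_surface + U_bias]/kB T) where
// U_surface is a sum of nearest-image wrapped 2D Gaussian wells over
// angle pairs plus cosine torsion terms, and U_bias a set of grid-based
// local-elevation potentials (wrapped Gaussian basis functions of width
// sigma centred at bin centres).

static const double KB = 0.0083144621; // kJ/(mol K)

static inline double wrapd(double x) {
  x = std::fmod(x + 180.0, 360.0);
  if (x < 0) x += 360.0;
  return x - 180.0;
}

// Gaussian well surface: terms matrix columns
//   0: pair index (0-based), 1: center_phi, 2: center_psi, 3: depth, 4: width
// Torsion terms matrix columns
//   0: angle index (0-based), 1: k, 2: theta0 (deg), 3: multiplicity
static double surface_energy_cpp(const NumericVector& state,
                                 const IntegerMatrix& pairs,
                                 const NumericMatrix& terms,
                                 const NumericMatrix& tors,
                                 double offset) {
  double e = offset;
  for (int t = 0; t < terms.nrow(); ++t) {
    int p = (int) terms(t, 0);
    double dphi = wrapd(state[pairs(p, 0)] - terms(t, 1));
    double dpsi = wrapd(state[pairs(p, 1)] - terms(t, 2));
    double w = terms(t, 4);
    e += terms(t, 3) * std::exp(-(dphi * dphi + dpsi * dpsi) / (2.0 * w * w));
  }
  for (int t = 0; t < tors.nrow(); ++t) {
    double th = state[(int) tors(t, 0)] * M_PI / 180.0;
    double th0 = tors(t, 2) * M_PI / 180.0;
    e += tors(t, 1) * (1.0 + std::cos(tors(t, 3) * th - th0));
  }
  return e;
}

// one grid bias evaluated at (phi, psi); weights is n x n, bin j covers
// [-180 + j*delta, -180 + (j+1)*delta), basis centred at bin centres
static double bias_eval(const NumericMatrix& w, double sigma,
                        double phi, double psi) {
  int n = w.nrow();
  double delta = 360.0 / n;
  double s2 = 2.0 * sigma * sigma;
  std::vector<double> gphi(n), gpsi(n);
  for (int j = 0; j < n; ++j) {
    double c = -180.0 + (j + 0.5) * delta;
    double d1 = wrapd(phi - c);
    double d2 = wrapd(psi - c);
    gphi[j] = std::exp(-d1 * d1 / s2);
    gpsi[j] = std::exp(-d2 * d2 / s2);
  }
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (gphi[j] < 1e-300) continue;
    double row = 0.0;
    for (int k = 0; k < n; ++k) row += w(j, k) * gpsi[k];
    e += gphi[j] * row;
  }
  return e;
}

static inline int bin_index(double x, int n) {
  double delta = 360.0 / n;
  int j = (int) std::floor((wrapd(x) + 180.0) / delta);
  if (j < 0) j = 0;
  if (j >= n) j = n - 1;
  return j;
}

// [[Rcpp::export]]
NumericVector cpp_bias_energy(NumericMatrix weights, double sigma,
                              NumericVector phi, NumericVector psi) {
  int m = phi.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = bias_eval(weights, sigma, phi[i], psi[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_surface_energy(NumericMatrix state,
                                 IntegerMatrix pairs,
                                 NumericMatrix terms,
                                 NumericMatrix tors,
                                 double offset) {
  int m = state.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    NumericVector s = state(i, _);
    out[i] = surface_energy_cpp(s, pairs, terms, tors, offset);
  }
  return out;
}

// Metropolis chain over n_angles dihedrals.
//
// bias_pair (rows = biases, columns = 0-based angle indices), bias_w a
// list of square weight matrices, bias_sigma per bias.  le_index >= 0
// selects the bias receiving local-elevation depositions of increment_c
// every deposit_every steps; -1 runs with all biases frozen.
// [[Rcpp::export]]
List cpp_run_chain(NumericVector init,
                   IntegerMatrix pairs,
                   NumericMatrix terms,
                   NumericMatrix tors,
                   double offset,
                   int n_steps,
                   double step_size,
                   double temperature,
                   int record_every,
                   IntegerMatrix bias_pair,
                   List bias_w,
                   NumericVector bias_sigma,
                   int le_index,
                   double increment_c,
                   int deposit_every) {
  int n_ang = init.size();
  int n_bias = bias_w.size();
  double kT = KB * temperature;

  std::vector<NumericMatrix> W;
  for (int b = 0; b < n_bias; ++b)
    W.push_back(clone(as<NumericMatrix>(bias_w[b])));  // never alias caller state

  NumericVector state = clone(init);
  for (int a = 0; a < n_ang; ++a) state[a] = wrapd(state[a]);

  double e_surf = surface_energy_cpp(state, pairs, terms, tors, offset);
  std::vector<double> e_bias(n_bias, 0.0);
  double e_bias_tot = 0.0;
  for (int b = 0; b < n_bias; ++b) {
    e_bias[b] = bias_eval(W[b], bias_sigma[b],
                          state[bias_pair(b, 0)], state[bias_pair(b, 1)]);
    e_bias_tot += e_bias[b];
  }

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix frames(n_rec, n_ang);
  NumericVector rec_bias(n_rec);
  IntegerMatrix visits;
  long n_dep = 0;
  if (le_index >= 0) {
    int n = W[le_index].nrow();
    visits = IntegerMatrix(n, n);
  }

  RNGScope scope;
  NumericVector prop(n_ang);
  int irec = 0;
  long accepted = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int a = 0; a < n_ang; ++a)
      prop[a] = wrapd(state[a] + R::runif(-step_size, step_size));

    double e_surf_p = surface_energy_cpp(prop, pairs, terms, tors, offset);
    double e_bias_p_tot = 0.0;
    std::vector<double> e_bias_p(n_bias, 0.0);
    for (int b = 0; b < n_bias; ++b) {
      e_bias_p[b] = bias_eval(W[b], bias_sigma[b],
                              prop[bias_pair(b, 0)], prop[bias_pair(b, 1)]);
      e_bias_p_tot += e_bias_p[b];
    }
    double de = (e_surf_p + e_bias_p_tot) - (e_surf + e_bias_tot);
    if (!std::isfinite(de))
      stop("non-finite energy encountered at step %d", step);
    if (de <= 0.0 || R::runif(0.0, 1.0) < std::exp(-de / kT)) {
      state = clone(prop);
      e_surf = e_surf_p;
      e_bias = e_bias_p;
      e_bias_tot = e_bias_p_tot;
      ++accepted;
    }

    if (le_index >= 0 && deposit_every > 0 && step % deposit_every == 0) {
      int n = W[le_index].nrow();
      int j = bin_index(state[bias_pair(le_index, 0)], n);
      int k = bin_index(state[bias_pair(le_index, 1)], n);
      W[le_index](j, k) += increment_c;
      visits(j, k) += 1;
      ++n_dep;
      // the bias under the current state changed; refresh cached energy
      e_bias[le_index] = bias_eval(W[le_index], bias_sigma[le_index],
                                   state[bias_pair(le_index, 0)],
                                   state[bias_pair(le_index, 1)]);
      e_bias_tot = 0.0;
      for (int b = 0; b < n_bias; ++b) e_bias_tot += e_bias[b];
    }

    if (record_every > 0 && step % record_every == 0) {
      for (int a = 0; a < n_ang; ++a) frames(irec, a) = state[a];
      rec_bias[irec] = e_bias_tot;
      ++irec;
    }
  }

  List out = List::create(
    _["frames"] = frames,
    _["bias_energy"] = rec_bias,
    _["acceptance"] = (double) accepted / (double) n_steps,
    _["n_depositions"] = (double) n_dep);
  if (le_index >= 0) {
    out["weights"] = W[le_index];
    out["visits"] = visits;
  }
  return out;
}
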