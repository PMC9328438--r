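#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Brownian-dynamics photon-trace simulator.
//
// Particles of each species are placed uniformly in a periodic box (2D species
// confined to the focal plane z = 0), propagated with Gaussian steps of
// standard deviation sqrt(2 D dt) per axis, and carry a two-state (bright/dark)
// telegraph process with stationary dark occupancy T and relaxation time
// tau_dark.  The per-bin expected count is
//   background * bin_time + sum_steps dt * sum_bright eps * MDF(x, y, z)
// with MDF = exp(-2 (x^2 + y^2) / omega^2 - 2 z^2 / (S omega)^2), and the
// observed count is a Poisson draw from it.
//
// Species arrays are parallel vectors (one entry per species).  n_particles
// is drawn upstream (Poisson with mean density * box measure) so the box is
// grand-canonical.  Uses R's RNG: set.seed() upstream gives identical traces.

// MDF values below this threshold are treated as zero (saves the exp() for
// the large fraction of the box that cannot contribute a detectable rate).
static const double MDF_EXPONENT_CUTOFF = 18.42;  // exp(-18.42) ~ 1e-8

// [[Rcpp::export]]
List sim_trace_cpp(int n_bins, int steps_per_bin, double dt,
                   IntegerVector dim, NumericVector D, IntegerVector n_particles,
                   NumericVector epsilon, NumericVector T_dark, NumericVector tau_dark,
                   double omega, double S, double Lxy, double Lz,
                   double background, bool return_rates) {
  const int n_species = dim.size();
  const double inv_w2 = 2.0 / (omega * omega);
  const double wz = S * omega;
  const double inv_wz2 = 2.0 / (wz * wz);
  const double bin_time = steps_per_bin * dt;

  // flatten particles across species
  std::vector<double> px, py, pz, sig, eps_p, p_bd, p_db;
  std::vector<char> is3d, dark;
  for (int s = 0; s < n_species; ++s) {
    const int np = n_particles[s];
    const double sigma = std::sqrt(2.0 * D[s] * dt);
    const double T = T_dark[s];
    // exact discrete-time sampling of the two-state process: relaxation
    // rate 1/tau_dark, stationary dark occupancy T is preserved for any dt
    const double relax = -std::expm1(-dt / tau_dark[s]);
    const double pbd = (T > 0.0) ? T * relax : 0.0;
    const double pdb = (T > 0.0) ? (1.0 - T) * relax : 1.0;
    for (int i = 0; i < np; ++i) {
      px.push_back(R::runif(-Lxy, Lxy));
      py.push_back(R::runif(-Lxy, Lxy));
      pz.push_back(dim[s] == 3 ? R::runif(-Lz, Lz) : 0.0);
      is3d.push_back(dim[s] == 3);
      dark.push_back(T > 0.0 && R::unif_rand() < T);
      sig.push_back(sigma);
      eps_p.push_back(epsilon[s]);
      p_bd.push_back(pbd);
      p_db.push_back(pdb);
    }
  }
  const int np_all = (int)px.size();

  NumericVector counts(n_bins);
  NumericVector rates;  // expected counts per bin
  if (return_rates) rates = NumericVector(n_bins);

  const double bg_counts = background * bin_time;
  for (int b = 0; b < n_bins; ++b) {
    double lambda = 0.0;
    for (int st = 0; st < steps_per_bin; ++st) {
      double rate = 0.0;
      for (int i = 0; i < np_all; ++i) {
        const double sigma = sig[i];
        if (sigma > 0.0) {
          double x = px[i] + sigma * norm_rand();
          double y = py[i] + sigma * norm_rand();
          if (x > Lxy) x -= 2.0 * Lxy; else if (x < -Lxy) x += 2.0 * Lxy;
          if (y > Lxy) y -= 2.0 * Lxy; else if (y < -Lxy) y += 2.0 * Lxy;
          px[i] = x; py[i] = y;
          if (is3d[i]) {
            double z = pz[i] + sigma * norm_rand();
            if (z > Lz) z -= 2.0 * Lz; else if (z < -Lz) z += 2.0 * Lz;
            pz[i] = z;
          }
        }
        if (p_bd[i] > 0.0) {  // species with a dark state
          if (dark[i]) {
            if (unif_rand() < p_db[i]) dark[i] = 0;
          } else {
            if (unif_rand() < p_bd[i]) dark[i] = 1;
          }
          if (dark[i]) continue;
        }
        double q = (px[i] * px[i] + py[i] * py[i]) * inv_w2;
        if (is3d[i]) q += pz[i] * pz[i] * inv_wz2;
        if (q < MDF_EXPONENT_CUTOFF) rate += eps_p[i] * std::exp(-q);
      }
      lambda += rate * dt;
    }
    lambda += bg_counts;
    counts[b] = R::rpois(lambda);
    if (return_rates) rates[b] = lambda;
  }

  if (return_rates)
    return List::create(_["counts"] = counts, _["rates"] = rates);
  return List::create(_["counts"] = counts);
}

// Free-space trajectories (no periodic wrap), for mean-squared-displacement
// checks of the propagator.  Returns final squared displacement per particle
// after n_steps steps.
// [[Rcpp::export]]
NumericVector sim_displacement2_cpp(int n_particles, int n_steps, double dt,
                                    double D, int dim) {
  const double sigma = std::sqrt(2.0 * D * dt);
  NumericVector out(n_particles);
  for (int i = 0; i < n_particles; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    for (int st = 0; st < n_steps; ++st) {
      x += sigma * norm_rand();
      y += sigma * norm_rand();
      if (dim == 3) z += sigma * norm_rand();
    }
    out[i] = x * x + y * y + z * z;
  }
  return out;
}

// Dark-state telegraph process on its own: fraction of steps spent dark.
// [[Rcpp::export]]
double sim_dark_fraction_cpp(int n_steps, double dt, double T, double tau_dark) {
  const double relax = -std::expm1(-dt / tau_dark);
  const double pbd = T * relax;
  const double pdb = (1.0 - T) * relax;
  bool dark = unif_rand() < T;
  long n_dark = 0;
  for (int st = 0; st < n_steps; ++st) {
    if (dark) {
      if (unif_rand() < pdb) dark = false;
    } else {
      if (unif_rand() < pbd) dark = true;
    }
    if (dark) ++n_dark;
  }
  return (double)n_dark / (double)n_steps;
}
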