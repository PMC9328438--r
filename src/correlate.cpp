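#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Normalized autocorrelation of one level series at the given integer lags.
// normalization: 0 = symmetric (separate means over the leading and lagging
// segments), 1 = global (single mean over the whole series).
static void acf_at_lags(const std::vector<double>& y,
                        const std::vector<long>& lags_bins,
                        int normalization,
                        std::vector<double>& G_out,
                        std::vector<double>& npts_out) {
  const long n = (long)y.size();
  double total = 0.0;
  for (long i = 0; i < n; ++i) total += y[i];
  const double mu = total / (double)n;
  // prefix sums for the symmetric segment means
  std::vector<double> cum(n + 1, 0.0);
  for (long i = 0; i < n; ++i) cum[i + 1] = cum[i] + y[i];
  for (size_t k = 0; k < lags_bins.size(); ++k) {
    const long L = lags_bins[k];
    const long M = n - L;
    if (M < 8) { G_out.push_back(NA_REAL); npts_out.push_back((double)M); continue; }
    double sxy = 0.0;
    for (long i = 0; i < M; ++i) sxy += y[i] * y[i + L];
    double G;
    if (normalization == 0) {
      const double m_lead = cum[M] / (double)M;
      const double m_lag = (cum[n] - cum[L]) / (double)M;
      G = sxy / ((double)M * m_lead * m_lag) - 1.0;
    } else {
      double s = 0.0;
      for (long i = 0; i < M; ++i) s += (y[i] - mu) * (y[i + L] - mu);
      G = (s / (double)M) / (mu * mu);
    }
    G_out.push_back(G);
    npts_out.push_back((double)M);
  }
}

// Multi-tau correlator: m linear lags per octave, counts rebinned x2 per
// octave.  Level 0 covers lags 1..2m at native resolution; each further level
// rebins by 2 and covers lags m+1..2m of the rebinned series.  Lags are
// returned in native-bin units.
// [[Rcpp::export]]
List multitau_cpp(NumericVector counts, int m, int normalization) {
  std::vector<double> y(counts.begin(), counts.end());
  std::vector<double> lag_native, G, npts;
  long scale = 1;
  int level = 0;
  while (true) {
    std::vector<long> lags;
    const long lo = (level == 0) ? 1 : m + 1;
    for (long L = lo; L <= 2L * m; ++L)
      if ((long)y.size() - L >= 8) lags.push_back(L);
    if (lags.empty()) break;
    std::vector<double> Gl, nl;
    acf_at_lags(y, lags, normalization, Gl, nl);
    for (size_t k = 0; k < lags.size(); ++k) {
      if (!ISNA(Gl[k])) {
        lag_native.push_back((double)lags[k] * (double)scale);
        G.push_back(Gl[k]);
        npts.push_back(nl[k]);
      }
    }
    // rebin x2 for the next octave
    const long nh = (long)y.size() / 2;
    if (nh < 2L * m + 8) break;
    std::vector<double> y2(nh);
    for (long i = 0; i < nh; ++i) y2[i] = y[2 * i] + y[2 * i + 1];
    y.swap(y2);
    scale *= 2;
    ++level;
  }
  return List::create(_["lag_bins"] = wrap(lag_native),
                      _["G"] = wrap(G),
                      _["npts"] = wrap(npts));
}

// Brute-force correlator: the normalized covariance definition evaluated at
// every integer lag 1..max_lag, no rebinning.
// [[Rcpp::export]]
List direct_acf_cpp(NumericVector counts, int max_lag, int normalization) {
  std::vector<double> y(counts.begin(), counts.end());
  std::vector<long> lags;
  for (long L = 1; L <= (long)max_lag; ++L) lags.push_back(L);
  std::vector<double> lag_out, G, npts;
  // the direct oracle keeps every lag, however poorly averaged, except the
  // degenerate ones where a segment mean vanishes (undefined normalization)
  const long n = (long)y.size();
  double total = 0.0;
  for (long i = 0; i < n; ++i) total += y[i];
  const double mu = total / (double)n;
  std::vector<double> cum(n + 1, 0.0);
  for (long i = 0; i < n; ++i) cum[i + 1] = cum[i] + y[i];
  for (size_t k = 0; k < lags.size(); ++k) {
    const long L = lags[k];
    const long M = n - L;
    double sxy = 0.0;
    for (long i = 0; i < M; ++i) sxy += y[i] * y[i + L];
    double Gv;
    if (normalization == 0) {
      const double m_lead = cum[M] / (double)M;
      const double m_lag = (cum[n] - cum[L]) / (double)M;
      Gv = sxy / ((double)M * m_lead * m_lag) - 1.0;
    } else {
      double s = 0.0;
      for (long i = 0; i < M; ++i) s += (y[i] - mu) * (y[i + L] - mu);
      Gv = (s / (double)M) / (mu * mu);
    }
    if (!std::isfinite(Gv)) continue;
    lag_out.push_back((double)L);
    G.push_back(Gv);
    npts.push_back((double)M);
  }
  return List::create(_["lag_bins"] = wrap(lag_out),
                      _["G"] = wrap(G),
                      _["npts"] = wrap(npts));
}
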