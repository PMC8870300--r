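#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Non-paralyzable dead-time filter: an event is recorded iff it occurs at
// least `dead_ns` after the previously *recorded* event. `times_ns` must be
// sorted ascending.
// [[Rcpp::export]]
LogicalVector dead_time_filter(NumericVector times_ns, double dead_ns) {
  int n = times_ns.size();
  LogicalVector keep(n);
  double last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (times_ns[i] - last >= dead_ns) {
      keep[i] = true;
      last = times_ns[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}

struct PixelResult {
  std::vector<double> micro;  // recorded micro-times (ns)
  int n_emitted;
};

// Core pulse-by-pulse TCSPC simulation for one pixel. Uses R's RNG so that
// set.seed() in R governs reproducibility. Emission is Bernoulli(p) per
// pulse; delay after the pulse is Exp(tau) plus Gaussian IRF jitter; the
// detector records an event only if it is not within `dead_ns` of the
// previous recorded event (absolute time); recorded micro-time is the
// absolute time modulo the pulse period.
static PixelResult sim_pixel_core(int n_pulses, double p, double tau_ns,
                                  double period_ns, double dead_ns,
                                  double irf_sigma_ns, bool poisson) {
  PixelResult res;
  res.n_emitted = 0;
  std::vector<double> tabs;
  for (int k = 0; k < n_pulses; ++k) {
    int nph;
    if (poisson) {
      nph = (int)R::rpois(p);
    } else {
      nph = (p >= 1.0 || unif_rand() < p) ? 1 : 0;
    }
    for (int q = 0; q < nph; ++q) {
      double delay = exp_rand() * tau_ns;
      if (irf_sigma_ns > 0) delay += norm_rand() * irf_sigma_ns;
      tabs.push_back(k * period_ns + delay);
      ++res.n_emitted;
    }
  }
  // exponential tails (and jitter) can reorder events across pulses
  std::sort(tabs.begin(), tabs.end());
  double last = R_NegInf;
  for (size_t i = 0; i < tabs.size(); ++i) {
    if (tabs[i] - last >= dead_ns) {
      last = tabs[i];
      double m = tabs[i] - period_ns * std::floor(tabs[i] / period_ns);
      if (m < 0) m += period_ns;
      if (m >= period_ns) m -= period_ns;
      res.micro.push_back(m);
    }
  }
  return res;
}

// [[Rcpp::export]]
List sim_pixel(int n_pulses, double p, double tau_ns, double period_ns,
               double dead_ns, double irf_sigma_ns, int nbins, bool poisson) {
  PixelResult r = sim_pixel_core(n_pulses, p, tau_ns, period_ns, dead_ns,
                                 irf_sigma_ns, poisson);
  IntegerVector counts(nbins);
  double bw = period_ns / nbins;
  for (size_t i = 0; i < r.micro.size(); ++i) {
    int b = (int)(r.micro[i] / bw);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    counts[b]++;
  }
  return List::create(_["counts"] = counts,
                      _["n_emitted"] = r.n_emitted,
                      _["n_detected"] = (int)r.micro.size());
}

// Simulate a whole frame of pixel decays. p_mat and tau_mat are per-pixel
// emission probability per pulse and (mixture-mean) lifetime in ns. Returns
// an integer array (rows x cols x nbins).
// [[Rcpp::export]]
IntegerVector sim_frame(NumericMatrix p_mat, NumericMatrix tau_mat,
                        int n_pulses, double period_ns, double dead_ns,
                        double irf_sigma_ns, int nbins) {
  int nr = p_mat.nrow(), nc = p_mat.ncol();
  IntegerVector out(nr * nc * nbins);
  double bw = period_ns / nbins;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double p = p_mat(i, j);
      if (p <= 0) continue;
      PixelResult r = sim_pixel_core(n_pulses, p, tau_mat(i, j), period_ns,
                                     dead_ns, irf_sigma_ns, false);
      for (size_t k = 0; k < r.micro.size(); ++k) {
        int b = (int)(r.micro[k] / bw);
        if (b >= nbins) b = nbins - 1;
        if (b < 0) b = 0;
        out[i + nr * j + nr * nc * b]++;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, nbins);
  return out;
}
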