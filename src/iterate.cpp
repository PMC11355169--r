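#include <Rcpp.h>
using namespace Rcpp;

// Logistic-map orbit: P_{t+1} = r * P_t * (1 - P_t), constant r.
// Returns the full series including P0 (length n + 1).
// [[Rcpp::export]]
NumericVector orbit_cpp(double P0, double r, int n) {
  NumericVector out(n + 1);
  double P = P0;
  out[0] = P;
  for (int t = 0; t < n; ++t) {
    P = r * P * (1.0 - P);
    out[t + 1] = P;
  }
  return out;
}

// Final orbit value only (memory-free variant for long runs).
// [[Rcpp::export]]
double orbit_final_cpp(double P0, double r, double n) {
  double P = P0;
  for (double t = 0; t < n; ++t) P = r * P * (1.0 - P);
  return P;
}

// Largest Lyapunov exponent estimate: mean of log|r (1 - 2 P_t)| along the
// post-burn-in orbit. Terms where the derivative is exactly 0 are skipped.
// [[Rcpp::export]]
double lyapunov_cpp(double r, double P0, double burn_in, double n_iter) {
  double P = P0;
  for (double t = 0; t < burn_in; ++t) P = r * P * (1.0 - P);
  double s = 0.0;
  double k = 0.0;
  for (double t = 0; t < n_iter; ++t) {
    double d = r * (1.0 - 2.0 * P);
    if (d != 0.0) {
      s += std::log(std::fabs(d));
      k += 1.0;
    }
    P = r * P * (1.0 - P);
  }
  if (k == 0.0) return R_NegInf;
  return s / k;
}

// Post-burn-in orbit window used for attractor-period detection.
// [[Rcpp::export]]
NumericVector attractor_cpp(double r, double P0, double burn_in, int n_check) {
  double P = P0;
  for (double t = 0; t < burn_in; ++t) P = r * P * (1.0 - P);
  NumericVector out(n_check);
  for (int t = 0; t < n_check; ++t) {
    out[t] = P;
    P = r * P * (1.0 - P);
  }
  return out;
}

// Two-state chain simulation; states coded 0 = Stable, 1 = Unstable.
// Uses R's RNG so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
IntegerVector simulate_chain_cpp(double p_su, double p_us, int n_steps,
                                 int initial) {
  IntegerVector out(n_steps);
  int s = initial;
  for (int t = 0; t < n_steps; ++t) {
    double u = R::unif_rand();
    if (s == 0) {
      if (u < p_su) s = 1;
    } else {
      if (u < p_us) s = 0;
    }
    out[t] = s;
  }
  return out;
}

// Systematic-scan single-site Gibbs sampler for a two-state Markov random
// field. V is n x 2 (site potentials, columns S/U), U2 is 2 x 2 (pair
// potential, rows = state of the focal site). nbrs is a list of 0-based
// neighbor index vectors. One retained sample per sweep after burn-in.
// [[Rcpp::export]]
IntegerMatrix gibbs_cpp(NumericMatrix V, NumericMatrix U2, List nbrs,
                        IntegerVector init, int n_sweeps, int burn_in,
                        double beta) {
  int n = V.nrow();
  std::vector<int> s(init.begin(), init.end());
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) nb[i] = as< std::vector<int> >(nbrs[i]);
  IntegerMatrix out(n_sweeps, n);
  int total = burn_in + n_sweeps;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double e0 = V(i, 0);
      double e1 = V(i, 1);
      for (size_t k = 0; k < nb[i].size(); ++k) {
        int j = nb[i][k];
        e0 += U2(0, s[j]);
        e1 += U2(1, s[j]);
      }
      // conditional P(s_i = U | rest) under P(config) propto exp(-beta E)
      double pU = 1.0 / (1.0 + std::exp(beta * (e1 - e0)));
      s[i] = (R::unif_rand() < pU) ? 1 : 0;
    }
    if (sweep >= burn_in) {
      for (int i = 0; i < n; ++i) out(sweep - burn_in, i) = s[i];
    }
  }
  return out;
}
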