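#include <Rcpp.h>
using namespace Rcpp;

// Euler–Maruyama integration of C coupled noisy phase oscillators:
//   dphi_i = omega_i dt + sum_j K_ij sin(phi_j - phi_i) dt + sigma dW_i.
// Uses R's RNG (set.seed() on the R side governs reproducibility).
// Returns unwrapped phases, C x (n_steps + 1) including the initial state.
// [[Rcpp::export]]
NumericMatrix kuramoto_integrate(NumericVector phi0, NumericVector omega,
                                 NumericMatrix K, double sigma, double dt,
                                 int n_steps) {
  const int C = phi0.size();
  if (omega.size() != C || K.nrow() != C || K.ncol() != C)
    stop("dimension mismatch between phi0, omega and K");
  if (n_steps < 0) stop("n_steps must be nonnegative");
  NumericMatrix phi(C, n_steps + 1);
  std::vector<double> cur(C), nxt(C);
  for (int i = 0; i < C; ++i) {
    cur[i] = phi0[i];
    phi(i, 0) = cur[i];
  }
  const double sq = sigma * std::sqrt(dt);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < C; ++i) {
      double coup = 0.0;
      for (int j = 0; j < C; ++j) {
        const double k = K(i, j);
        if (k != 0.0) coup += k * std::sin(cur[j] - cur[i]);
      }
      nxt[i] = cur[i] + (omega[i] + coup) * dt + sq * norm_rand();
    }
    for (int i = 0; i < C; ++i) {
      cur[i] = nxt[i];
      phi(i, t + 1) = cur[i];
    }
  }
  return phi;
}

// Independent phase random walk (no drift): phi_t = phi_{t-1} + sigma dW.
// Used as the unlocked-jitter component of cross-band linkages.
// [[Rcpp::export]]
NumericVector phase_random_walk(double phi0, double sigma, double dt,
                                int n_steps) {
  NumericVector out(n_steps + 1);
  out[0] = phi0;
  const double sq = sigma * std::sqrt(dt);
  for (int t = 0; t < n_steps; ++t) out[t + 1] = out[t] + sq * norm_rand();
  return out;
}
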