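#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward-Euler integration of the two-variable Aliev-Panfilov model on a
// graph Laplacian:
//   du/dt = d * L u - c u (u - theta) (u - 1) - u v + I_stim
//   dv/dt = eps(u, v) * (-v - c u (u - theta - 1)),
//   eps(u, v) = e0 + mu1 v / (u + mu2)
// States are stored every keep_every steps (step 0 included).
// [[Rcpp::export(name = ".ap_integrate_cpp")]]
List ap_integrate_cpp(const arma::mat& L, const arma::vec& theta,
                      double c, double e0, double mu1, double mu2,
                      double d, double dt, int n_steps,
                      const arma::uvec& stim_nodes, double stim_amplitude,
                      double stim_duration,
                      const arma::vec& u0, const arma::vec& v0,
                      int keep_every) {
  const arma::uword n = L.n_rows;
  arma::vec u = u0, v = v0;
  const int n_kept = n_steps / keep_every + 1;
  arma::mat U(n, n_kept), V(n, n_kept);
  arma::vec times(n_kept);
  U.col(0) = u; V.col(0) = v; times(0) = 0.0;
  int kept = 1;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    arma::vec diff = (d != 0.0) ? arma::vec(d * (L * u)) : arma::vec(n, arma::fill::zeros);
    arma::vec eps = e0 + mu1 * v / (u + mu2);
    arma::vec du = diff - c * (u % (u - theta) % (u - 1.0)) - u % v;
    arma::vec dv = eps % (-v - c * (u % (u - theta - 1.0)));
    if (t < stim_duration && stim_nodes.n_elem > 0) {
      for (arma::uword j = 0; j < stim_nodes.n_elem; ++j)
        du(stim_nodes(j)) += stim_amplitude;
    }
    u += dt * du;
    v += dt * dv;
    // additive stimulus is capped at the action-potential plateau (u = 1)
    if (t < stim_duration && stim_nodes.n_elem > 0) {
      for (arma::uword j = 0; j < stim_nodes.n_elem; ++j)
        if (u(stim_nodes(j)) > 1.0) u(stim_nodes(j)) = 1.0;
    }
    if (!u.is_finite() || !v.is_finite()) {
      stop("non-finite state at step %d (t = %.3f): integration unstable, reduce dt",
           s + 1, t + dt);
    }
    if ((s + 1) % keep_every == 0) {
      U.col(kept) = u; V.col(kept) = v; times(kept) = (s + 1) * dt;
      ++kept;
    }
  }
  return List::create(_["u"] = U.cols(0, kept - 1),
                      _["v"] = V.cols(0, kept - 1),
                      _["times"] = times.subvec(0, kept - 1));
}
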