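#' Bayesian active learning of the latent posterior
#'
#' The latent log-posterior (up to its normalizing constant)
#'
#'   log pi(z | Y) = -1/2 ( ||Y - M(E[p(theta|z)])||^2 / sigma_e^2 + ||z||^2 )
#'
#' is learned by a GP surrogate: each iteration selects the next latent
#' point by maximizing an acquisition function of the log-normal process
#' exp(GP), pays one forward simulation to label it, refits the GP, and
#' stops when the normalized posterior estimate stabilizes in KL.
#'
#' @name active_posterior
#' @keywords internal
NULL

#' Acquisition specification
#'
#' @param kind one of `"lognormal_variance"`, `"lognormal_entropy"`,
#'   `"ucb"`. The log-normal acquisitions target the accuracy of the
#'   posterior pdf exp(GP); UCB (mu + kappa sigma) is the regular
#'   Bayesian-active-learning baseline.
#' @param ucb_kappa exploration weight for UCB (default 2)
#' @param domain latent search box, applied per dimension
#' @param grid_n coarse acquisition grid resolution per dimension
#' @param refine_top number of best grid cells refined by L-BFGS-B
#' @return an `acquisition_spec`
#' @export
acquisition_spec <- function(kind = c("lognormal_variance",
                                      "lognormal_entropy", "ucb"),
                             ucb_kappa = 2, domain = c(-3.5, 3.5),
                             grid_n = 60L, refine_top = 3L) {
  kind <- match.arg(kind)
  stopifnot(is.finite(domain), domain[1] < domain[2])
  structure(list(kind = kind, ucb_kappa = ucb_kappa, domain = domain,
                 grid_n = as.integer(grid_n),
                 refine_top = as.integer(refine_top)),
            class = "acquisition_spec")
}

#' Regular latent grid with trapezoidal quadrature weights
#'
#' @param domain interval applied to both latent dimensions
#' @param n points per dimension
#' @return list: `z1`, `z2` axes, `points` (n^2 x 2, row-major over z2 then
#'   z1), `w` quadrature weight per point, `n`
#' @export
latent_grid <- function(domain = c(-3.5, 3.5), n = 60L) {
  z1 <- seq(domain[1], domain[2], length.out = n)
  h <- z1[2] - z1[1]
  w1 <- rep(h, n); w1[c(1, n)] <- h / 2     # 1-D trapezoid weights
  pts <- as.matrix(expand.grid(z1 = z1, z2 = z1))
  # expand.grid varies z1 fastest, matching column-major outer(w1, w1)
  w <- as.numeric(outer(w1, w1))
  list(z1 = z1, z2 = z1, points = pts, w = w, n = n)
}

#' Latent log-posterior evaluation (one forward simulation)
#'
#' Decodes `z` through the VAE expectation network, runs the AP model and
#' the lead field, subsamples to the observation's frame count, and
#' returns -1/2 (||Y_obs - Y(z)||^2 / sigma_e^2 + ||z||^2).
#'
#' @param z latent point (length-2)
#' @param vae trained `vae_params`
#' @param geom a `cardiac_geometry`
#' @param ap an `ap_params`
#' @param lf a `lead_field`
#' @param Y_obs observed `ecg_measurement` with `sigma_e_sq` set
#' @param sigma_lik_sq likelihood noise scale dividing the squared residual
#'   norm; defaults to the measurement's aggregated noise power
#'   `sigma_lik_sq` (per-entry injected variance times entry count), which
#'   gives the log-posterior an O(10) dynamic range over the latent domain
#' @return scalar log-posterior value (unnormalized)
#' @export
eval_log_posterior <- function(z, vae, geom, ap, lf, Y_obs,
                               sigma_lik_sq = NULL) {
  if (is.null(sigma_lik_sq)) sigma_lik_sq <- Y_obs$sigma_lik_sq
  if (is.null(sigma_lik_sq) || is.na(sigma_lik_sq))
    stop("Y_obs must carry a likelihood noise scale (sigma_lik_sq)")
  theta <- pmin(pmax(vae_decode(vae, z), 0), 0.5)
  tr <- simulate_ap(geom, ap, theta)
  Yz <- subsample_frames(apply_lead_field(lf, tr)$Y, ncol(Y_obs$Y))
  -0.5 * (sum((Y_obs$Y - Yz)^2) / sigma_lik_sq + sum(z^2))
}

#' Synthesize an observed ECG from a ground-truth field
#'
#' Runs the forward model on `theta_true`, subsamples to `n_frames`, and
#' adds noise at `snr_db`. The injected noise variance is recorded as the
#' likelihood's `sigma_e_sq`.
#'
#' @param geom,ap,lf forward-model context
#' @param theta_true ground-truth excitability field
#' @param snr_db observation SNR in dB (Inf for noise-free; then
#'   `sigma_e_sq` must be supplied for inference)
#' @param seed noise seed
#' @param n_frames temporal frames kept for the likelihood (default 100)
#' @return an `ecg_measurement`
#' @export
make_observation <- function(geom, ap, lf, theta_true, snr_db = 20,
                             seed = 1L, n_frames = 100L) {
  tr <- simulate_ap(geom, ap, theta_true)
  m <- apply_lead_field(lf, tr)
  idx <- unique(round(seq(1, ncol(m$Y), length.out = min(n_frames, ncol(m$Y)))))
  m$Y <- m$Y[, idx, drop = FALSE]
  m$times <- m$times[idx]
  add_noise_snr(m, snr_db, seed = seed)
}

# Acquisition objective on GP summaries, with an affine label shift for
# numerical stability. All three objectives are monotone transforms of the
# literal acquisition values, so the shift never changes the argmax.
acquisition_objective <- function(mu, var, kind, ucb_kappa = 2, shift = 0) {
  sd <- sqrt(pmax(var, 1e-300))
  switch(kind,
    lognormal_variance = log(expm1(pmin(var, 700))) + 2 * (mu - shift) + var,
    lognormal_entropy = mu - shift + 0.5 + log(sqrt(2 * pi) * sd),
    ucb = mu - shift + ucb_kappa * sd,
    stop("unknown acquisition kind"))
}

#' Acquisition function value
#'
#' Literal acquisition values at `z`:
#' `lognormal_variance` = (exp(sigma^2) - 1) exp(2 mu + sigma^2) (the
#' pointwise variance of exp(GP)); `lognormal_entropy` =
#' mu + 1/2 + ln(sqrt(2 pi) sigma) (the differential entropy of the
#' pointwise log-normal); `ucb` = mu + kappa sigma.
#'
#' @param state a `gp_state`
#' @param z latent point(s): vector or row matrix
#' @param spec an `acquisition_spec`
#' @return numeric vector of acquisition values
#' @export
acquisition_value <- function(state, z, spec) {
  pr <- gp_predict(state, z)
  switch(spec$kind,
    lognormal_variance = expm1(pmin(pr$var, 700)) *
      exp(pmin(2 * pr$mean + pr$var, 700)),
    lognormal_entropy = pr$mean + 0.5 + log(sqrt(2 * pi * pmax(pr$var, 1e-300))),
    ucb = pr$mean + spec$ucb_kappa * sqrt(pr$var))
}

#' Select the next training point
#'
#' Dense coarse-grid argmax of the acquisition objective followed by
#' bounded local refinement (L-BFGS-B) from the best `refine_top` grid
#' cells. Deterministic given the GP state and spec; a flat acquisition
#' resolves to the lowest-index grid point.
#'
#' @param state a `gp_state`
#' @param spec an `acquisition_spec`
#' @return length-2 latent point
#' @export
select_next_point <- function(state, spec) {
  grid <- latent_grid(spec$domain, spec$grid_n)
  shift <- if (length(state$labels)) max(state$labels) else 0
  obj <- function(Z) {
    pr <- gp_predict(state, Z)
    acquisition_objective(pr$mean, pr$var, spec$kind, spec$ucb_kappa, shift)
  }
  vals <- obj(grid$points)
  best_i <- which.max(vals)                 # first index wins ties
  top <- utils::head(order(vals, decreasing = TRUE), spec$refine_top)
  best_z <- grid$points[best_i, ]
  best_v <- vals[best_i]
  for (i in top) {
    fit <- tryCatch(
      stats::optim(grid$points[i, ], function(z) -obj(matrix(z, 1)),
                   method = "L-BFGS-B",
                   lower = rep(spec$domain[1], 2),
                   upper = rep(spec$domain[2], 2),
                   control = list(maxit = 50)),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > best_v + 1e-12) {
      best_v <- -fit$value
      best_z <- fit$par
    }
  }
  as.numeric(best_z)
}

#' Normalized posterior density on the latent grid
#'
#' Evaluates the GP predictive mean on a regular grid and normalizes
#' exp(mean) by trapezoidal quadrature. The maximum mean value is
#' subtracted before exponentiation (pure numerics; the density is
#' invariant to affine label offsets).
#'
#' @param state a `gp_state`
#' @param grid a `latent_grid()` (default 60 x 60 over [-3.5, 3.5]^2)
#' @return a `posterior_grid`: `density` (vector over grid points),
#'   `log_density` (GP mean), `grid`
#' @export
posterior_grid <- function(state, grid = latent_grid()) {
  mu <- gp_predict(state, grid$points)$mean
  un <- exp(mu - max(mu))
  dens <- un / sum(grid$w * un)
  structure(list(density = dens, log_density = mu, grid = grid),
            class = "posterior_grid")
}

# KL(p || q) between two normalized grid densities with shared weights.
grid_kl <- function(p, q, w) {
  stopifnot(length(p) == length(q), length(p) == length(w))
  pos <- p > 0
  sum(w[pos] * p[pos] * (log(p[pos]) - log(pmax(q[pos], 1e-300))))
}

#' Convergence check on the trailing posterior history
#'
#' KL divergence of the current normalized posterior from the average of
#' the previous five, on the shared grid. Undefined (and not converged)
#' until six iterations have produced posterior estimates.
#'
#' @param history list of `posterior_grid`s, most recent last
#' @param threshold convergence threshold on the KL value
#' @return list: `converged` (flag), `kl` (NA while undefined)
#' @export
check_convergence <- function(history, threshold = 1e-3) {
  if (length(history) < 6L)
    return(list(converged = FALSE, kl = NA_real_))
  cur <- history[[length(history)]]
  prev <- history[(length(history) - 5L):(length(history) - 1L)]
  qbar <- Reduce(`+`, lapply(prev, function(g) g$density)) / 5
  kl <- grid_kl(cur$density, qbar, cur$grid$w)
  list(converged = kl <= threshold, kl = kl)
}

#' Run the Bayesian active learning loop
#'
#' Evaluates an initial design (a small grid over the latent prior's bulk),
#' then iterates: select the acquisition argmax, pay one forward simulation
#' for its log-posterior label, refit the GP, re-optimize hyperparameters,
#' and test the KL convergence criterion on the normalized posterior grid.
#'
#' @param Y_obs observed `ecg_measurement` (with `sigma_e_sq`)
#' @param vae trained `vae_params`
#' @param geom,ap,lf forward-model context
#' @param spec an `acquisition_spec`
#' @param kl_threshold convergence threshold (default 1e-3)
#' @param max_iter acquisition cap (default 500); reaching it returns
#'   `converged = FALSE` with a warning
#' @param init_grid_n initial design is an `init_grid_n`^2 grid over
#'   `init_domain` (defaults: 3 x 3 over [-2, 2]^2)
#' @param init_domain see `init_grid_n`
#' @param bounds `gp_bounds()` for hyperparameter optimization
#' @param grid posterior-normalization grid (default `latent_grid()`)
#' @param seed master seed (hyperparameter-optimization restarts)
#' @param verbose log per-iteration progress
#' @return an `active_run`: `state` (final `gp_state`), `posterior` (final
#'   `posterior_grid`), `record` (per-iteration data frame), `n_forward`
#'   (total forward simulations), `converged`
#' @export
run_active_learning <- function(Y_obs, vae, geom, ap, lf,
                                spec = acquisition_spec(),
                                kl_threshold = 1e-3, max_iter = 500L,
                                init_grid_n = 3L, init_domain = c(-2, 2),
                                bounds = gp_bounds(),
                                grid = latent_grid(spec$domain),
                                seed = 1L, verbose = FALSE) {
  ax <- seq(init_domain[1], init_domain[2], length.out = init_grid_n)
  Z <- as.matrix(expand.grid(z1 = ax, z2 = ax))
  labels <- apply(Z, 1, eval_log_posterior, vae = vae, geom = geom,
                  ap = ap, lf = lf, Y_obs = Y_obs)
  n_forward <- nrow(Z)
  hyper <- gp_hyper(length_scales = c(1, 1),
                    amplitude_sq = max(stats::var(labels), 1),
                    noise_var = 1e-6)
  state <- gp_state(Z, labels, hyper)
  hyper <- gp_optimize_hyperparams(state, bounds, seed = seed)
  state <- gp_state(Z, labels, hyper)
  history <- list()
  rec <- data.frame()
  converged <- FALSE
  kl <- NA_real_
  for (i in seq_len(max_iter)) {
    z_next <- select_next_point(state, spec)
    lab <- eval_log_posterior(z_next, vae, geom, ap, lf, Y_obs)
    n_forward <- n_forward + 1L
    Z <- rbind(Z, z_next)
    labels <- c(labels, lab)
    state <- gp_state(Z, labels, state$hyper)
    hyper <- gp_optimize_hyperparams(state, bounds, seed = seed + i)
    state <- gp_state(Z, labels, hyper)
    pg <- posterior_grid(state, grid)
    history[[length(history) + 1L]] <- pg
    conv <- check_convergence(history, kl_threshold)
    kl <- conv$kl
    rec <- rbind(rec, data.frame(
      iter = i, z1 = z_next[1], z2 = z_next[2], label = lab, kl = kl,
      ls1 = hyper$length_scales[1], ls2 = hyper$length_scales[2],
      amplitude_sq = hyper$amplitude_sq, noise_var = hyper$noise_var))
    if (verbose)
      message(sprintf("iter %3d  z = (%+.3f, %+.3f)  label = %.4g  KL = %s",
                      i, z_next[1], z_next[2], lab,
                      ifelse(is.na(kl), "NA", signif(kl, 3))))
    if (conv$converged) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("active learning hit max_iter = %d without converging (KL = %g)",
                    max_iter, kl))
  structure(list(state = state,
                 posterior = history[[length(history)]],
                 record = rec, n_forward = n_forward,
                 n_init = init_grid_n^2, converged = converged),
            class = "active_run")
}

#' @export
print.active_run <- function(x, ...) {
  cat(sprintf(
    "active_run: %d forward simulations (%d initial + %d acquired), converged: %s\n",
    x$n_forward, x$n_init, nrow(x$record), x$converged))
  invisible(x)
}

#' Draw latent samples from a posterior grid
#'
#' Multinomial sampling over grid cells (probability = density x weight)
#' with uniform jitter inside each cell, giving cheap samples from the
#' surrogate posterior without extra forward simulations.
#'
#' @param pg a `posterior_grid`
#' @param n number of samples
#' @param seed RNG seed
#' @return n x 2 matrix of latent samples
#' @export
sample_posterior_grid <- function(pg, n, seed = 1L) {
  rng <- local_rng(seed)
  w <- pg$density * pg$grid$w
  h <- pg$grid$z1[2] - pg$grid$z1[1]
  # multinomial cell choice by cumulative inversion
  u <- rng$runif(n)
  cw <- cumsum(w) / sum(w)
  idx <- findInterval(u, cw) + 1L
  jit <- matrix(rng$runif(2 * n, -h / 2, h / 2), n, 2)
  pg$grid$points[idx, , drop = FALSE] + jit
}
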