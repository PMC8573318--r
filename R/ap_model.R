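#' Aliev-Panfilov model parameters
#'
#' Parameter container for the two-variable Aliev-Panfilov (AP) model
#'
#'   du/dt = div(D grad u) - c u (u - theta)(u - 1) - u v
#'   dv/dt = eps(u, v) (-v - c u (u - theta - 1)),  eps = e0 + mu1 v/(u + mu2)
#'
#' with u the (dimensionless) transmembrane potential, v the recovery
#' current, and theta the per-node tissue excitability being inferred.
#' The diffusion tensor is reduced to a scalar isotropic coefficient
#' `d_iso` acting through the graph Laplacian; fibre anisotropy is out of
#' scope. Time is in model units (the AP model is phenomenological; no
#' millisecond calibration is attempted).
#'
#' Defaults `c = 8`, `e0 = 0.002`, `mu1 = 0.2`, `mu2 = 0.3` are the standard
#' literature values. The stimulus is an additive current on the pacing
#' nodes for `stim_duration` time units starting at t = 0.
#'
#' @param c repolarization coefficient
#' @param e0 recovery rate constant
#' @param mu1,mu2 recovery coupling constants
#' @param d_iso scalar isotropic diffusion coefficient
#' @param dt forward-Euler step (model time units)
#' @param t_end simulation horizon (model time units)
#' @param stim_amplitude additive stimulus current (du/dt units)
#' @param stim_duration stimulus duration from t = 0
#' @return an `ap_params` list
#' @export
ap_params <- function(c = 8, e0 = 0.002, mu1 = 0.2, mu2 = 0.3,
                      d_iso = 2.0, dt = 0.04, t_end = 120,
                      stim_amplitude = 8, stim_duration = 3) {
  p <- list(c = c, e0 = e0, mu1 = mu1, mu2 = mu2, d_iso = d_iso,
            dt = dt, t_end = t_end, stim_amplitude = stim_amplitude,
            stim_duration = stim_duration)
  with(p, stopifnot(c > 0, e0 > 0, mu1 > 0, mu2 > 0, d_iso >= 0,
                    dt > 0, t_end > 0, stim_duration >= 0))
  class(p) <- "ap_params"
  p
}

#' Simulate transmembrane potential propagation
#'
#' Integrates the AP model on the geometry's graph Laplacian with explicit
#' forward Euler. The diffusion stability bound
#' `dt < 2 / (d_iso * lambda_max)` is checked against a power-iteration
#' estimate of the largest Laplacian eigenvalue; violating it is an error
#' (the reaction terms only tighten the true bound).
#'
#' @param geom a `cardiac_geometry`
#' @param params an `ap_params`
#' @param theta per-node excitability field in [0, 0.5]
#' @param u0,v0 optional initial states (default zero)
#' @param keep_every store every `keep_every`-th step (thins the output in
#'   time; dynamics are always integrated at `dt`)
#' @param stimulate apply the pacing stimulus (default TRUE)
#' @return a `simulation_trace`: matrices `u`, `v` (node x kept step) and
#'   the `times` grid
#' @export
simulate_ap <- function(geom, params, theta, u0 = NULL, v0 = NULL,
                        keep_every = 1L, stimulate = TRUE) {
  n <- n_nodes(geom)
  theta <- as.numeric(theta)
  if (length(theta) != n)
    stop(sprintf("theta has %d values but geometry has %d nodes",
                 length(theta), n))
  if (any(theta < 0 | theta > 0.502))   # tolerate the additive field noise
    stop("theta must lie within [0, 0.5] (plus field-noise overshoot)")
  if (params$d_iso > 0) {
    lam <- laplacian_lambda_max(geom$laplacian)
    if (lam > 0 && params$dt >= 2 / (params$d_iso * lam))
      stop(sprintf(
        "dt = %g violates the diffusion stability bound 2/(d_iso*lambda_max) = %g",
        params$dt, 2 / (params$d_iso * lam)))
  }
  if (is.null(u0)) u0 <- rep(0, n)
  if (is.null(v0)) v0 <- rep(0, n)
  n_steps <- as.integer(round(params$t_end / params$dt))
  stim <- if (stimulate) as.integer(geom$pacing_nodes) - 1L else integer(0)
  out <- .ap_integrate_cpp(geom$laplacian, theta,
                           params$c, params$e0, params$mu1, params$mu2,
                           params$d_iso, params$dt, n_steps,
                           stim, params$stim_amplitude, params$stim_duration,
                           u0, v0, as.integer(keep_every))
  trace <- list(u = out$u, v = out$v, times = as.numeric(out$times))
  class(trace) <- "simulation_trace"
  trace
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("simulation_trace: %d nodes x %d steps, t in [%g, %g]\n",
              nrow(x$u), ncol(x$u), min(x$times), max(x$times)))
  invisible(x)
}

#' Last-activation time of a trace
#'
#' Time at which the last node first crosses `level` (NA if any node never
#' activates). Used to characterize propagation delay as excitability rises.
#'
#' @param trace a `simulation_trace`
#' @param level activation threshold on u
#' @return scalar time, or NA
#' @export
last_activation_time <- function(trace, level = 0.5) {
  first_cross <- apply(trace$u > level, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  if (anyNA(first_cross)) return(NA_real_)
  trace$times[max(first_cross)]
}

#' Single-cell AP dynamics by classic RK4
#'
#' Reference integrator for an isolated node (no diffusion), used as an
#' independent oracle for the forward-Euler integrator at fine steps.
#'
#' @param params an `ap_params` (d_iso ignored)
#' @param theta scalar excitability
#' @param u0,v0 initial state
#' @param dt,t_end integration grid
#' @return list with vectors `u`, `v`, `times`
#' @export
ap_single_cell_rk4 <- function(params, theta, u0, v0 = 0,
                               dt = 0.005, t_end = 80) {
  f <- function(s) {
    u <- s[1]; v <- s[2]
    eps <- params$e0 + params$mu1 * v / (u + params$mu2)
    c(-params$c * u * (u - theta) * (u - 1) - u * v,
      eps * (-v - params$c * u * (u - theta - 1)))
  }
  n <- as.integer(round(t_end / dt))
  out <- matrix(0, n + 1, 2)
  out[1, ] <- c(u0, v0)
  s <- c(u0, v0)
  for (i in seq_len(n)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- s
  }
  list(u = out[, 1], v = out[, 2], times = seq(0, by = dt, length.out = n + 1))
}

#' Write a trace to CSV files (u.csv, v.csv, times.csv)
#' @param trace a `simulation_trace`
#' @param path directory
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trace$u, file.path(path, "u.csv"), row.names = FALSE)
  utils::write.csv(trace$v, file.path(path, "v.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trace$times), file.path(path, "times.csv"),
                   row.names = FALSE)
  invisible(path)
}
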