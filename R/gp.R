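#' Gaussian-process surrogate of the latent log-posterior
#'
#' Exact GP regression with a zero prior mean and an anisotropic Matern 5/2
#' kernel. Labels are the (unstandardized) latent log-posterior values; the
#' zero mean and raw scale matter because downstream acquisition functions
#' exponentiate the GP, treating exp(GP) as a log-normal process.
#'
#' @name gp_surrogate
#' @keywords internal
NULL

#' GP hyperparameters
#'
#' @param length_scales per-latent-dimension characteristic length scales
#'   (the kernel metric uses their inverse squares on its diagonal)
#' @param amplitude_sq kernel amplitude (signal variance)
#' @param noise_var observation noise variance added to the kernel diagonal
#' @return a `gp_hyper` list
#' @export
gp_hyper <- function(length_scales = c(1, 1), amplitude_sq = 1,
                     noise_var = 1e-6) {
  stopifnot(all(length_scales > 0), amplitude_sq > 0, noise_var > 0)
  structure(list(length_scales = length_scales, amplitude_sq = amplitude_sq,
                 noise_var = noise_var), class = "gp_hyper")
}

#' Anisotropic Matern 5/2 kernel
#'
#' k(zi, zj) = amplitude_sq * exp(-sqrt(5) d) (1 + sqrt(5) d + 5/3 d^2),
#' d^2 = sum_k (zi_k - zj_k)^2 / length_scales_k^2.
#'
#' @param Z1,Z2 latent points: vectors (single point) or row matrices
#' @param hyper a `gp_hyper`
#' @return kernel matrix (nrow(Z1) x nrow(Z2)), or scalar for two vectors
#' @export
matern52 <- function(Z1, Z2, hyper) {
  v1 <- !is.matrix(Z1); v2 <- !is.matrix(Z2)
  if (v1) Z1 <- matrix(Z1, 1)
  if (v2) Z2 <- matrix(Z2, 1)
  S1 <- sweep(Z1, 2, hyper$length_scales, `/`)
  S2 <- sweep(Z2, 2, hyper$length_scales, `/`)
  d2 <- pmax(outer(rowSums(S1^2), rowSums(S2^2), `+`) - 2 * tcrossprod(S1, S2), 0)
  d <- sqrt(d2)
  K <- hyper$amplitude_sq * exp(-sqrt(5) * d) * (1 + sqrt(5) * d + 5 / 3 * d2)
  if (v1 && v2) K[1, 1] else K
}

#' Fit (factorize) a GP state
#'
#' Builds the Gram matrix with the noise variance on the diagonal and
#' caches its Cholesky factor, escalating a jitter from 1e-10 to 1e-6
#' (relative to the amplitude) if the factorization fails.
#'
#' @param z_train n x d matrix of latent training points (may have 0 rows)
#' @param labels length-n numeric log-posterior values
#' @param hyper a `gp_hyper`
#' @return a `gp_state` with cached factorization
#' @export
gp_state <- function(z_train, labels, hyper) {
  z_train <- if (is.null(z_train)) matrix(0, 0, length(hyper$length_scales))
             else as.matrix(z_train)
  labels <- as.numeric(labels)
  stopifnot(nrow(z_train) == length(labels))
  st <- list(z_train = z_train, labels = labels, hyper = hyper,
             chol_K = NULL, alpha = NULL, jitter = 0)
  n <- nrow(z_train)
  if (n > 0) {
    K <- matern52(z_train, z_train, hyper)
    diag(K) <- diag(K) + hyper$noise_var
    jit <- 0
    repeat {
      ch <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
      if (!is.null(ch)) break
      jit <- if (jit == 0) 1e-10 * hyper$amplitude_sq else jit * 100
      if (jit > 1e-6 * hyper$amplitude_sq * 100)
        stop("Gram matrix not positive definite even after jitter escalation")
    }
    st$chol_K <- ch
    st$alpha <- backsolve(ch, forwardsolve(t(ch), labels))
    st$jitter <- jit
  }
  class(st) <- "gp_state"
  st
}

#' @export
print.gp_state <- function(x, ...) {
  cat(sprintf(
    "gp_state: %d training points, length scales (%s), amplitude_sq %.3g, noise_var %.3g\n",
    nrow(x$z_train), paste(signif(x$hyper$length_scales, 3), collapse = ", "),
    x$hyper$amplitude_sq, x$hyper$noise_var))
  invisible(x)
}

#' GP predictive mean and variance
#'
#' mu = k' K^-1 L, var = k(z, z) - k' K^-1 k, with K carrying the noise
#' variance on its diagonal. The variance is clipped below at 1e-12 *
#' amplitude_sq (numerical floor). With no training points the prior
#' predictive (mu = 0, var = k(z, z)) is returned.
#'
#' @param state a `gp_state`
#' @param z_query query points: vector (single point) or row matrix
#' @return list with numeric vectors `mean` and `var`
#' @export
gp_predict <- function(state, z_query) {
  Zq <- if (is.matrix(z_query)) z_query else matrix(z_query, 1)
  kss <- rep(state$hyper$amplitude_sq, nrow(Zq))
  if (nrow(state$z_train) == 0)
    return(list(mean = rep(0, nrow(Zq)), var = kss))
  Ks <- matern52(Zq, state$z_train, state$hyper)   # m x n
  mean <- as.numeric(Ks %*% state$alpha)
  W <- forwardsolve(t(state$chol_K), t(Ks))        # n x m
  var <- kss - colSums(W^2)
  floor_var <- 1e-12 * state$hyper$amplitude_sq
  list(mean = mean, var = pmax(var, floor_var))
}

#' GP log marginal likelihood
#'
#' Standard evidence of the zero-mean GP:
#' -1/2 L' K^-1 L - 1/2 log|K| - n/2 log(2 pi).
#'
#' @param state a `gp_state` (>= 1 training point)
#' @return scalar log evidence
#' @export
gp_log_marginal_likelihood <- function(state) {
  n <- nrow(state$z_train)
  if (n < 1) stop("log marginal likelihood needs at least one training point")
  -0.5 * sum(state$labels * state$alpha) -
    sum(log(diag(state$chol_K))) - n / 2 * log(2 * pi)
}

#' Hyperparameter bounds for marginal-likelihood optimization
#'
#' Box bounds on (length scales, amplitude_sq, noise_var). Log-posterior
#' labels are deliberately not standardized, so the amplitude upper bound
#' must accommodate their raw variance (O(10^2) under the default
#' likelihood scaling).
#'
#' @param length_scale bounds on each length scale
#' @param amplitude_sq bounds on the kernel amplitude
#' @param noise_var bounds on the noise variance
#' @return list of bounds
#' @export
gp_bounds <- function(length_scale = c(0.05, 10),
                      amplitude_sq = c(1e-2, 1e4),
                      noise_var = c(1e-8, 1e-1)) {
  list(length_scale = length_scale, amplitude_sq = amplitude_sq,
       noise_var = noise_var)
}

#' Optimize GP hyperparameters by maximum marginal likelihood
#'
#' Multi-start bounded L-BFGS-B in log-hyperparameter space. The incumbent
#' hyperparameters seed the first start; the remaining starts are
#' log-uniform draws inside the bounds. The returned hyperparameters never
#' decrease the evidence relative to the incumbent (guarded update); if
#' every start fails the incumbent is kept with a warning.
#'
#' @param state a `gp_state` with >= 2 training points
#' @param bounds a `gp_bounds()` list
#' @param n_starts number of optimization starts (default 5)
#' @param seed RNG seed for the random starts
#' @return optimized `gp_hyper`
#' @export
gp_optimize_hyperparams <- function(state, bounds = gp_bounds(),
                                    n_starts = 5L, seed = 1L) {
  stopifnot(nrow(state$z_train) >= 2)
  d <- length(state$hyper$length_scales)
  lb <- log(c(rep(bounds$length_scale[1], d), bounds$amplitude_sq[1],
              bounds$noise_var[1]))
  ub <- log(c(rep(bounds$length_scale[2], d), bounds$amplitude_sq[2],
              bounds$noise_var[2]))
  unpack <- function(x) gp_hyper(exp(x[seq_len(d)]), exp(x[d + 1]), exp(x[d + 2]))
  nll <- function(x) {
    st <- tryCatch(gp_state(state$z_train, state$labels, unpack(x)),
                   error = function(e) NULL)
    if (is.null(st)) return(1e12)
    v <- tryCatch(-gp_log_marginal_likelihood(st), error = function(e) 1e12)
    if (!is.finite(v)) 1e12 else v
  }
  x0 <- pmin(pmax(log(c(state$hyper$length_scales, state$hyper$amplitude_sq,
                        state$hyper$noise_var)), lb), ub)
  rng <- local_rng(seed)
  starts <- list(x0)
  for (i in seq_len(max(0L, n_starts - 1L)))
    starts[[i + 1]] <- lb + rng$runif(d + 2) * (ub - lb)
  incumbent_ev <- -nll(x0)
  best <- list(ev = incumbent_ev, hyper = unpack(x0))
  any_ok <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- TRUE
    if (-fit$value > best$ev) best <- list(ev = -fit$value, hyper = unpack(fit$par))
  }
  if (!any_ok)
    warning("all hyperparameter optimization starts failed; keeping incumbent")
  best$hyper
}

#' Serialize / deserialize a GP state as JSON
#' @param state a `gp_state`
#' @param path file path (.json)
#' @return `path` invisibly; `read_gp_state` returns a refitted `gp_state`
#' @export
write_gp_state <- function(state, path) {
  jsonlite::write_json(
    list(z_train = list(dim = dim(state$z_train),
                        data = as.numeric(state$z_train)),
         labels = state$labels, hyper = unclass(state$hyper)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_gp_state
#' @export
read_gp_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  z <- matrix(raw$z_train$data, raw$z_train$dim[1], raw$z_train$dim[2])
  hy <- gp_hyper(as.numeric(raw$hyper$length_scales),
                 as.numeric(raw$hyper$amplitude_sq),
                 as.numeric(raw$hyper$noise_var))
  gp_state(z, as.numeric(raw$labels), hy)
}

#' Surrogate log-density from a GP state
#'
#' Returns a function of one latent point giving the GP predictive mean
#' inside `domain` and -Inf outside. Restricting the support makes
#' exp(GP mean) a proper (finite-mass) surrogate density: a zero-mean GP
#' reverts to mean zero far from its training points, which would
#' otherwise put unbounded mass in the far field.
#'
#' @param state a `gp_state`
#' @param domain per-dimension interval of support (default [-3.5, 3.5])
#' @return function(z) -> scalar surrogate log density
#' @export
gp_surrogate_log_density <- function(state, domain = c(-3.5, 3.5)) {
  force(state); force(domain)
  function(z) {
    if (any(z < domain[1] | z > domain[2])) return(-Inf)
    gp_predict(state, z)$mean[1]
  }
}
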