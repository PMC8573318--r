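#' Synthetic lead-field (transfer) matrix
#'
#' Places `n_leads` virtual electrodes on a sphere enclosing the node cloud
#' (Fibonacci spiral with a small seeded jitter) and fills the transfer
#' matrix with inverse squared electrode-to-node distances, each row
#' normalized to sum to one. This is a deliberately simple surrogate for a
#' patient-specific torso transfer matrix: it preserves the two properties
#' the inference pipeline relies on — linearity in u and spatial smoothing
#' that mixes node contributions per electrode — without any torso model.
#'
#' @param geom a `cardiac_geometry`
#' @param n_leads electrode count (default 120)
#' @param seed jitter seed
#' @param radius_factor sphere radius as a multiple of the cloud half-extent
#' @return a `lead_field`: list with matrix `H` (lead x node), `n_leads`,
#'   and electrode coordinates
#' @export
build_synthetic_lead_field <- function(geom, n_leads = 120L, seed = 1L,
                                       radius_factor = 1.8) {
  stopifnot(n_leads >= 1L)
  coords <- geom$node_coords
  center <- colMeans(coords)
  extent <- max(sqrt(rowSums(sweep(coords, 2, center)^2)))
  r <- radius_factor * extent
  rng <- local_rng(seed)
  i <- seq_len(n_leads)
  zs <- (2 * i - 1) / n_leads - 1
  phi <- 2 * pi * ((i * 0.6180339887498949) %% 1)
  el <- cbind(sqrt(pmax(1 - zs^2, 0)) * cos(phi),
              sqrt(pmax(1 - zs^2, 0)) * sin(phi),
              zs) * r
  el <- sweep(el + matrix(rng$rnorm(3 * n_leads, sd = 0.005 * r),
                          n_leads, 3), 2, center, `+`)
  D2 <- outer(rowSums(el^2), rowSums(coords^2), `+`) -
    2 * el %*% t(coords)
  # re-jitter any electrode that coincides with a node
  bad <- which(apply(D2, 1, min) < (1e-6 * r)^2)
  while (length(bad)) {
    el[bad, ] <- el[bad, , drop = FALSE] +
      matrix(rng$rnorm(3 * length(bad), sd = 0.01 * r), length(bad), 3)
    D2[bad, ] <- outer(rowSums(el[bad, , drop = FALSE]^2),
                       rowSums(coords^2), `+`) -
      2 * el[bad, , drop = FALSE] %*% t(coords)
    bad <- which(apply(D2, 1, min) < (1e-6 * r)^2)
  }
  H <- 1 / D2
  H <- H / rowSums(H)
  lf <- list(H = H, n_leads = as.integer(n_leads), electrodes = el)
  class(lf) <- "lead_field"
  lf
}

#' Map a simulation trace to noise-free ECG
#'
#' Y(t) = H u(t) at every stored timestep.
#'
#' @param lf a `lead_field`
#' @param trace a `simulation_trace`
#' @return an `ecg_measurement`: matrix `Y` (lead x timestep), `times`,
#'   `snr_db = NA`, `sigma_e_sq = NA`
#' @export
apply_lead_field <- function(lf, trace) {
  if (ncol(lf$H) != nrow(trace$u))
    stop(sprintf("lead field has %d columns but trace has %d nodes",
                 ncol(lf$H), nrow(trace$u)))
  m <- list(Y = lf$H %*% trace$u, times = trace$times,
            snr_db = NA_real_, sigma_e_sq = NA_real_, rng_seed = NA_integer_)
  class(m) <- "ecg_measurement"
  m
}

#' Add Gaussian noise at a target SNR
#'
#' Noise variance is set from the mean signal power so that
#' 10 log10(signal power / noise variance) = `snr_db`. The injected
#' per-entry variance is recorded as `sigma_e_sq`; its aggregate over the
#' measurement vector (`sigma_e_sq` times the entry count) is recorded as
#' `sigma_lik_sq` and is the default likelihood noise scale downstream,
#' which keeps the log-posterior's dynamic range at the scale of the
#' number of effective degrees of freedom rather than the raw sample
#' count. `snr_db = Inf` returns the input unchanged (with `sigma_e_sq`
#' left NA).
#'
#' @param Y an `ecg_measurement` (noise-free)
#' @param snr_db signal-to-noise ratio in dB
#' @param seed RNG seed; identical seeds give identical noise
#' @return a noisy `ecg_measurement` with `sigma_e_sq` recorded
#' @export
add_noise_snr <- function(Y, snr_db, seed = 1L) {
  stopifnot(inherits(Y, "ecg_measurement"))
  if (!is.na(Y$sigma_e_sq)) stop("measurement already carries noise")
  if (is.infinite(snr_db) && snr_db > 0) return(Y)
  p_signal <- mean(Y$Y^2)
  if (p_signal <= 0) stop("zero-power signal: cannot set an SNR")
  sigma2 <- p_signal / 10^(snr_db / 10)
  rng <- local_rng(seed)
  noisy <- Y
  noisy$Y <- Y$Y + matrix(rng$rnorm(length(Y$Y), sd = sqrt(sigma2)),
                          nrow(Y$Y), ncol(Y$Y))
  noisy$snr_db <- snr_db
  noisy$sigma_e_sq <- sigma2
  noisy$sigma_lik_sq <- sigma2 * length(Y$Y)
  noisy$rng_seed <- as.integer(seed)
  noisy
}

#' Subsample an ECG (or trace columns) to a fixed frame count
#'
#' The likelihood residual is computed over a fixed number of frames evenly
#' spaced over the stored time grid, so that observations and model
#' predictions are always compared on the same temporal support.
#'
#' @param Y lead x timestep matrix
#' @param n_frames frames to keep (default 100)
#' @return lead x n_frames matrix
#' @export
subsample_frames <- function(Y, n_frames = 100L) {
  nt <- ncol(Y)
  if (nt <= n_frames) return(Y)
  idx <- unique(round(seq(1, nt, length.out = n_frames)))
  Y[, idx, drop = FALSE]
}

#' Write / read an ECG measurement as plain-text files
#'
#' `Y.csv` holds the lead x timestep matrix; `meta.json` the time grid,
#' SNR and noise scales.
#'
#' @param m an `ecg_measurement`
#' @param path directory
#' @return `path` invisibly; `read_measurement` returns an
#'   `ecg_measurement`
#' @export
write_measurement <- function(m, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(m$Y, file.path(path, "Y.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(times = m$times, snr_db = m$snr_db, sigma_e_sq = m$sigma_e_sq,
         sigma_lik_sq = m$sigma_lik_sq, rng_seed = m$rng_seed),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  Y <- as.matrix(utils::read.csv(file.path(path, "Y.csv")))
  dimnames(Y) <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  as_null_na <- function(x) if (is.null(x)) NA_real_ else x
  structure(list(Y = Y, times = as.numeric(meta$times),
                 snr_db = as_null_na(meta$snr_db),
                 sigma_e_sq = as_null_na(meta$sigma_e_sq),
                 sigma_lik_sq = as_null_na(meta$sigma_lik_sq),
                 rng_seed = if (is.null(meta$rng_seed)) NA_integer_
                            else as.integer(meta$rng_seed)),
            class = "ecg_measurement")
}
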