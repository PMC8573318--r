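#' Posterior summaries and evaluation metrics
#'
#' Latent-space summaries (KDE mean/mode/std), decoded field summaries over
#' the heart, the Monte-Carlo KL estimator between sample-based posteriors,
#' and the Dice / RMSE / correlation metrics against ground-truth fields.
#'
#' @name summarize_evaluate
#' @keywords internal
NULL

# Product Gaussian KDE with Scott's-rule bandwidth; evaluates the density
# of `samples` (n x d) at `points` (m x d), chunked to bound memory.
kde_eval <- function(samples, points, bw = NULL) {
  n <- nrow(samples); d <- ncol(samples)
  if (is.null(bw)) {
    bw <- apply(samples, 2, stats::sd) * n^(-1 / (d + 4))
    bw[bw <= 0] <- 1e-8
  }
  m <- nrow(points)
  out <- numeric(m)
  chunk <- max(1L, as.integer(2e6 / n))
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(s + chunk - 1, m)
    acc <- matrix(0, length(idx), n)
    for (j in seq_len(d)) {
      D <- outer(points[idx, j], samples[, j], `-`) / bw[j]
      acc <- acc - 0.5 * D^2
    }
    out[idx] <- rowMeans(exp(acc)) / prod(bw * sqrt(2 * pi))
  }
  out
}

#' Latent posterior summary (mean, mode, std)
#'
#' For samples: mean and std are sample moments, the mode is the argmax of
#' a Gaussian KDE (Scott's rule) on a refined grid over the sample bounding
#' box. For a `posterior_grid`: grid moments and the density argmax.
#'
#' @param x n x 2 matrix of latent samples, or a `posterior_grid`
#' @param mode_grid_n refinement grid resolution for the KDE mode search
#' @param max_kde_samples cap on the samples entering the mode-search KDE
#'   (an evenly spaced subsample; bandwidth and moments always use the full
#'   set). Bounds the quadratic KDE cost for long chains.
#' @return a `latent_summary`: `mean`, `mode`, `std` (2-vectors),
#'   `kde_bandwidth` (NULL for grids)
#' @export
latent_summary <- function(x, mode_grid_n = 200L, max_kde_samples = 2000L) {
  if (inherits(x, "posterior_grid")) {
    w <- x$grid$w * x$density
    m <- colSums(x$grid$points * w)
    v <- colSums(sweep(x$grid$points, 2, m)^2 * w)
    mode <- x$grid$points[which.max(x$density), ]
    return(structure(list(mean = m, mode = as.numeric(mode), std = sqrt(v),
                          kde_bandwidth = NULL), class = "latent_summary"))
  }
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one sample")
  m <- colMeans(x)
  s <- if (nrow(x) > 1) apply(x, 2, stats::sd) else rep(0, ncol(x))
  if (all(s == 0)) {                        # degenerate: all samples equal
    return(structure(list(mean = m, mode = m, std = s, kde_bandwidth = NULL),
                     class = "latent_summary"))
  }
  xk <- if (nrow(x) > max_kde_samples)
    x[round(seq(1, nrow(x), length.out = max_kde_samples)), , drop = FALSE]
  else x
  # Scott bandwidth of the set actually entering the KDE
  bw <- apply(xk, 2, stats::sd) * nrow(xk)^(-1 / (ncol(x) + 4))
  bw[bw <= 0] <- 1e-8
  pad <- 3 * bw
  ax1 <- seq(min(x[, 1]) - pad[1], max(x[, 1]) + pad[1], length.out = mode_grid_n)
  ax2 <- seq(min(x[, 2]) - pad[2], max(x[, 2]) + pad[2], length.out = mode_grid_n)
  pts <- as.matrix(expand.grid(ax1, ax2))
  dens <- kde_eval(xk, pts, bw)
  structure(list(mean = m, mode = as.numeric(pts[which.max(dens), ]),
                 std = s, kde_bandwidth = bw), class = "latent_summary")
}

#' @export
print.latent_summary <- function(x, ...) {
  cat(sprintf("latent_summary: mean (%.3f, %.3f)  mode (%.3f, %.3f)  std (%.3f, %.3f)\n",
              x$mean[1], x$mean[2], x$mode[1], x$mode[2], x$std[1], x$std[2]))
  invisible(x)
}

#' Decoded field summary over the heart
#'
#' mean_field: average of decoded samples; std_field: per-node standard
#' deviation of decoded samples; mode_field: the decoder at the latent KDE
#' mode.
#'
#' @param samples n x 2 latent samples
#' @param vae trained `vae_params`
#' @param batch decode batch size
#' @return a `field_summary`: `mean_field`, `mode_field`, `std_field`
#' @export
field_summary <- function(samples, vae, batch = 512L) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  nn <- attr(vae, "n_input")
  sum1 <- numeric(nn); sum2 <- numeric(nn)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    dec <- vae_decode(vae, samples[idx, , drop = FALSE])
    sum1 <- sum1 + colSums(dec)
    sum2 <- sum2 + colSums(dec^2)
  }
  mean_field <- sum1 / n
  var_field <- pmax(sum2 / n - mean_field^2, 0)
  ls <- latent_summary(samples)
  structure(list(mean_field = mean_field,
                 mode_field = vae_decode(vae, ls$mode),
                 std_field = sqrt(var_field) * sqrt(n / max(n - 1, 1)),
                 latent = ls),
            class = "field_summary")
}

#' Monte-Carlo KL divergence between sample-based posteriors
#'
#' Fits Gaussian KDEs to both sample sets and estimates
#' KL(p || q) ~ mean(log p(x_i) - log q(x_i)) with x_i drawn from the
#' p-KDE (sample + kernel noise). q-densities are floored at a
#' machine-safe epsilon (with a warning) to survive support mismatch.
#'
#' @param p_samples,q_samples sample matrices (>= 100 rows each)
#' @param n_mc Monte-Carlo draws (default 1e4)
#' @param seed RNG seed
#' @return scalar KL estimate
#' @export
kl_between_estimates <- function(p_samples, q_samples, n_mc = 1e4, seed = 1L) {
  p_samples <- as.matrix(p_samples); q_samples <- as.matrix(q_samples)
  if (nrow(p_samples) < 100 || nrow(q_samples) < 100)
    stop("both sample sets need >= 100 rows")
  rng <- local_rng(seed)
  d <- ncol(p_samples)
  n <- nrow(p_samples)
  bw <- apply(p_samples, 2, stats::sd) * n^(-1 / (d + 4))
  bw[bw <= 0] <- 1e-8
  idx <- rng$sample_int(n, n_mc, replace = TRUE)
  xs <- p_samples[idx, , drop = FALSE] +
    matrix(rng$rnorm(n_mc * d), n_mc, d) %*% diag(bw, d)
  lp <- kde_eval(p_samples, xs, bw)
  lq <- kde_eval(q_samples, xs)
  if (any(lq < 1e-300)) {
    warning("q-KDE underflow at some Monte-Carlo points; flooring")
    lq <- pmax(lq, 1e-300)
  }
  mean(log(lp) - log(lq))
}

#' Field accuracy metrics: Dice, RMSE, correlation
#'
#' Dice overlap of the abnormal sets obtained by thresholding both fields
#' (default threshold 0.3, between healthy 0.15 and the lowest abnormal
#' severity 0.40), RMSE over all nodes, and the Pearson correlation.
#'
#' @param estimate estimated per-node field
#' @param truth ground-truth field
#' @param threshold abnormality threshold (default 0.3)
#' @return list: `dc`, `rmse`, `cc` (`cc` is NA for constant fields, with
#'   both-empty abnormal sets `dc` = 1)
#' @export
field_metrics <- function(estimate, truth, threshold = 0.3) {
  stopifnot(length(estimate) == length(truth))
  A <- estimate > threshold; B <- truth > threshold
  dc <- if (sum(A) + sum(B) == 0) 1 else 2 * sum(A & B) / (sum(A) + sum(B))
  rmse <- sqrt(mean((estimate - truth)^2))
  cc <- if (stats::sd(estimate) == 0 || stats::sd(truth) == 0) NA_real_
        else stats::cor(estimate, truth)
  list(dc = dc, rmse = rmse, cc = cc)
}

#' Absolute summary errors against a reference
#'
#' Per-statistic absolute error |s_method - s_reference|, using the
#' Euclidean norm for the 2-D mean and mode and per-dimension averaging
#' for the standard deviation, aggregated as mean +/- sd over cases.
#'
#' @param method_summaries list (cases) of `latent_summary`
#' @param reference_summaries list (cases) of reference `latent_summary`
#' @return data frame: statistic, per-case errors, mean, sd
#' @export
summary_error_table <- function(method_summaries, reference_summaries) {
  stopifnot(length(method_summaries) == length(reference_summaries))
  err1 <- function(m, r) c(
    mean = sqrt(sum((m$mean - r$mean)^2)),
    mode = sqrt(sum((m$mode - r$mode)^2)),
    std = sqrt(sum((m$std - r$std)^2)))
  E <- mapply(err1, method_summaries, reference_summaries)
  data.frame(statistic = rownames(E),
             mean_error = rowMeans(E),
             sd_error = apply(E, 1, stats::sd),
             t(E), row.names = NULL, check.names = FALSE)
}
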