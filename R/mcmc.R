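#' Metropolis-Hastings baselines
#'
#' Random-walk MH on the exact latent posterior (the expensive reference),
#' delayed-acceptance (two-stage) MH that screens candidates with the GP
#' surrogate before paying for an exact evaluation, and the chain protocol
#' used for comparisons: two chains, 20% burn-in, keep-alternate thinning,
#' Geweke and Gelman-Rubin diagnostics.
#'
#' @name mcmc_inference
#' @keywords internal
NULL

#' Random-walk Metropolis-Hastings
#'
#' Isotropic Gaussian proposal. The returned ledger counts one target
#' evaluation per proposal plus one for the initial state — the forward
#' simulation cost when the target is the exact posterior.
#'
#' @param log_target function(z) -> scalar log density (unnormalized)
#' @param init initial point (finite log_target required)
#' @param n_steps number of proposals
#' @param proposal_var Gaussian proposal variance (per dimension)
#' @param seed RNG seed
#' @return an `mcmc_chain`: `samples` (n_steps x d, the state after each
#'   proposal), `acceptance_rate`, `proposal_var`, `n_target_evals`, `seed`
#' @export
mh_sample <- function(log_target, init, n_steps, proposal_var, seed = 1L) {
  rng <- local_rng(seed)
  d <- length(init)
  cur <- as.numeric(init)
  cur_lp <- log_target(cur)
  if (!is.finite(cur_lp)) stop("log target not finite at the initial point")
  samples <- matrix(0, n_steps, d)
  n_acc <- 0L
  sd_p <- sqrt(proposal_var)
  for (i in seq_len(n_steps)) {
    prop <- cur + rng$rnorm(d, sd = sd_p)
    prop_lp <- log_target(prop)
    if (is.finite(prop_lp) && log(rng$runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp; n_acc <- n_acc + 1L
    }
    samples[i, ] <- cur
  }
  if (n_acc == 0L)
    warning("chain never accepted; target may be divergent or proposal too wide")
  structure(list(samples = samples, acceptance_rate = n_acc / n_steps,
                 proposal_var = proposal_var,
                 n_target_evals = n_steps + 1L, seed = as.integer(seed)),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("mcmc_chain: %d steps, acceptance %.3f, proposal_var %.4g\n",
              nrow(x$samples), x$acceptance_rate, x$proposal_var))
  invisible(x)
}

#' Tune the proposal variance to a target acceptance rate
#'
#' Bracketing plus bisection on short chains over a cheap surrogate target
#' (acceptance is monotone decreasing in the proposal variance for smooth
#' targets). Consumes no exact-model evaluations.
#'
#' @param surrogate_log_target cheap log-density function
#' @param init chain start for the tuning chains
#' @param target_rate desired acceptance (default 0.22)
#' @param tol acceptable deviation (default 0.03)
#' @param chain_len length of each tuning chain (default 600)
#' @param v0 initial variance guess
#' @param max_iter bisection iterations
#' @param seed RNG seed
#' @return tuned proposal variance (nearest achievable, with a warning, if
#'   the target rate cannot be bracketed)
#' @export
tune_proposal <- function(surrogate_log_target, init, target_rate = 0.22,
                          tol = 0.03, chain_len = 600L, v0 = 0.1,
                          max_iter = 25L, seed = 1L) {
  rate_at <- function(v, s)
    mh_sample(surrogate_log_target, init, chain_len, v, seed = s)$acceptance_rate
  lo <- v0; hi <- v0
  r0 <- rate_at(v0, seed)
  r_lo <- r_hi <- r0
  k <- 0L
  while (r_lo <= target_rate && k < 30L) {  # shrink until acceptance high
    lo <- lo / 4; r_lo <- rate_at(lo, seed + 100L + k); k <- k + 1L
  }
  k <- 0L
  while (r_hi >= target_rate && k < 30L) {  # grow until acceptance low
    hi <- hi * 4; r_hi <- rate_at(hi, seed + 200L + k); k <- k + 1L
  }
  if (r_lo <= target_rate || r_hi >= target_rate) {
    warning("target acceptance rate not bracketed; returning nearest variance")
    return(if (abs(r_lo - target_rate) < abs(r_hi - target_rate)) lo else hi)
  }
  v <- v0
  for (i in seq_len(max_iter)) {
    v <- sqrt(lo * hi)                       # geometric bisection
    r <- rate_at(v, seed + 300L + i)
    if (abs(r - target_rate) <= tol) return(v)
    if (r > target_rate) lo <- v else hi <- v
  }
  v
}

#' Two-stage (delayed-acceptance) Metropolis-Hastings
#'
#' Stage 1 accepts or rejects each candidate by the MH ratio on the cheap
#' surrogate (the GP predictive mean of the log-posterior); only stage-1
#' survivors are evaluated on the exact posterior, with the correction
#' ratio [pi(z') q*(z) / pi(z) q*(z')] that preserves the exact stationary
#' law. `n_forward_sims` counts only stage-2 (exact) evaluations.
#'
#' @param exact_log_target expensive log density
#' @param surrogate_log_target cheap log density (e.g. GP mean)
#' @param init initial point
#' @param n_steps number of proposals
#' @param proposal_var Gaussian proposal variance
#' @param seed RNG seed
#' @return an `mcmc_chain` with extra fields `n_forward_sims` (exact
#'   evaluations, excluding the initial one), `stage1_pass_rate`
#' @export
two_stage_mh <- function(exact_log_target, surrogate_log_target, init,
                         n_steps, proposal_var, seed = 1L) {
  rng <- local_rng(seed)
  d <- length(init)
  cur <- as.numeric(init)
  cur_exact <- exact_log_target(cur)
  cur_sur <- surrogate_log_target(cur)
  if (!is.finite(cur_exact)) stop("exact log target not finite at init")
  samples <- matrix(0, n_steps, d)
  n_acc <- 0L; n_stage2 <- 0L; n_pass1 <- 0L
  sd_p <- sqrt(proposal_var)
  for (i in seq_len(n_steps)) {
    prop <- cur + rng$rnorm(d, sd = sd_p)
    prop_sur <- surrogate_log_target(prop)
    # stage 1: surrogate MH filter
    if (is.finite(prop_sur) && log(rng$runif(1)) < prop_sur - cur_sur) {
      n_pass1 <- n_pass1 + 1L
      prop_exact <- exact_log_target(prop)
      n_stage2 <- n_stage2 + 1L
      # stage 2: exact correction preserving the exact stationary law
      if (is.finite(prop_exact) &&
          log(rng$runif(1)) < (prop_exact - cur_exact) - (prop_sur - cur_sur)) {
        cur <- prop; cur_exact <- prop_exact; cur_sur <- prop_sur
        n_acc <- n_acc + 1L
      }
    }
    samples[i, ] <- cur
  }
  structure(list(samples = samples, acceptance_rate = n_acc / n_steps,
                 proposal_var = proposal_var,
                 n_target_evals = n_stage2 + 1L,
                 n_forward_sims = n_stage2,
                 stage1_pass_rate = n_pass1 / n_steps,
                 seed = as.integer(seed)),
            class = "mcmc_chain")
}

#' Burn-in, thinning and diagnostics for a set of chains
#'
#' Discards the first 20% of each chain, keeps alternate (every second)
#' samples, and concatenates. Geweke and Gelman-Rubin diagnostics are
#' computed on the post-burn-in, pre-thinning chains.
#'
#' @param chains list of `mcmc_chain`s of equal length (>= 2 chains)
#' @param burn_frac burn-in fraction (default 0.2)
#' @return list: `samples` (combined matrix), `per_chain` (list of thinned
#'   matrices), `diagnostics` (`geweke_z` and `gelman_rubin` per dimension)
#' @export
postprocess_chains <- function(chains, burn_frac = 0.2) {
  stopifnot(length(chains) >= 2)
  lens <- vapply(chains, function(ch) nrow(ch$samples), 1L)
  if (length(unique(lens)) != 1)
    stop("chains must have equal length")
  n <- lens[1]
  burn <- as.integer(floor(burn_frac * n))
  post <- lapply(chains, function(ch) ch$samples[(burn + 1):n, , drop = FALSE])
  thinned <- lapply(post, function(s) s[seq(1, nrow(s), by = 2), , drop = FALSE])
  d <- ncol(post[[1]])
  geweke <- vapply(seq_len(d), function(j)
    geweke_z(post[[1]][, j]), numeric(1))
  psrf <- vapply(seq_len(d), function(j)
    gelman_rubin(lapply(post, function(s) s[, j])), numeric(1))
  list(samples = do.call(rbind, thinned), per_chain = thinned,
       diagnostics = list(geweke_z = geweke, gelman_rubin = psrf))
}

#' Geweke convergence score
#'
#' z-score comparing the means of the first `frac1` and last `frac2`
#' segments of a chain, with variances estimated by the spectral density
#' at frequency zero (AR fit), so autocorrelation inflates the standard
#' error as it should.
#'
#' @param x numeric chain (one dimension)
#' @param frac1,frac2 segment fractions (defaults 0.1 and 0.5)
#' @return z statistic
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- tryCatch(stats::ar(v, aic = TRUE, order.max = min(20, length(v) %/% 5)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  denom <- sqrt(s0(a) / length(a) + s0(b) / length(b))
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from m chains of one dimension each.
#'
#' @param chains list of numeric vectors (equal length)
#' @return scalar PSRF (>= 1 up to estimator noise)
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

#' Run the two-chain MCMC protocol on a log target
#'
#' Two chains from two distinct latent-prior draws, proposal variance
#' tuned on a supplied cheap surrogate to 0.22 acceptance, then burn-in,
#' thinning and diagnostics.
#'
#' @param log_target target log density (exact or surrogate)
#' @param surrogate_log_target cheap density for proposal tuning (defaults
#'   to `log_target` — only acceptable when the target itself is cheap)
#' @param chain_length proposals per chain
#' @param seed master seed (chain starts, proposals, tuning)
#' @param two_stage if not NULL, a surrogate log-density used as a
#'   delayed-acceptance first stage for the exact `log_target`
#' @return list: `chains`, `post` (postprocessed), `proposal_var`,
#'   `n_forward_sims` (exact-model evaluations over both chains)
#' @export
run_mcmc_protocol <- function(log_target, surrogate_log_target = log_target,
                              chain_length = 10000L, seed = 1L,
                              two_stage = NULL) {
  rng <- local_rng(seed)
  inits <- matrix(rng$rnorm(4), 2, 2)     # two distinct prior draws
  pv <- tune_proposal(surrogate_log_target, init = inits[1, ], seed = seed + 7L)
  chains <- lapply(1:2, function(c_i) {
    if (is.null(two_stage))
      mh_sample(log_target, inits[c_i, ], chain_length, pv, seed = seed + c_i)
    else
      two_stage_mh(log_target, two_stage, inits[c_i, ], chain_length, pv,
                   seed = seed + c_i)
  })
  post <- postprocess_chains(chains)
  nfs <- sum(vapply(chains, function(ch)
    if (!is.null(ch$n_forward_sims)) ch$n_forward_sims else ch$n_target_evals,
    numeric(1)))
  list(chains = chains, post = post, proposal_var = pv, n_forward_sims = nfs)
}
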