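# epactive

Fast posterior estimation of spatially varying cardiac tissue
excitability by Bayesian active learning.

## The problem

In the two-variable Aliev–Panfilov model of cardiac excitation

```
du/dt = div(D grad u) - c u (u - θ)(u - 1) - u v
dv/dt = ε(u, v) [ -v - c u (u - θ - 1) ],   ε = e0 + μ1 v / (u + μ2)
```

the per-node excitability θ separates healthy tissue (θ ≈ 0.15) from
inexcitable, infarcted tissue (θ ≈ 0.5). Body-surface ECG is a linear
image of the transmembrane potential, `Y(t) = H u(t)`. Recovering the
full posterior of the spatial θ field from a noisy ECG is doubly hard:
θ is high-dimensional, and every likelihood evaluation costs a full
reaction–diffusion simulation.

`epactive` implements the two-part remedy. A variational autoencoder
(VAE), trained on synthetic injury fields produced by random region
growing, compresses θ into a 2-D latent code `z` with generative map
`g(z)`. The latent log-posterior

```
log π(z | Y) = -1/2 [ ||Y - M(g(z))||² / σ² + ||z||² ] + const
```

(`M` = AP simulation + lead field) is then learned by a Gaussian-process
surrogate with a Matérn 5/2 kernel, trained by *active learning*: each
iteration maximizes an acquisition function of the log-normal process
`exp(GP)` — its pointwise variance `(e^{σ²(z)}-1) e^{2μ(z)+σ²(z)}` or
entropy `μ(z) + ½ + ln(√(2π) σ(z))` — pays one forward simulation for
the selected point, refits, and stops when the normalized posterior
estimate stabilizes in KL divergence. Direct Metropolis–Hastings and
surrogate-screened two-stage (delayed-acceptance) MH provide reference
posteriors, and kernel-density summaries with Dice / RMSE / correlation
metrics evaluate the decoded fields.

The package is self-contained: it generates its own LV-like fixture
geometry, lead field, training corpora and observations, so every
experiment runs from a single configuration with explicit seeds.

## A worked example

```r
library(epactive)

geom <- fixture_geometry(300)                      # LV-like node cloud
lf   <- build_synthetic_lead_field(geom, 120, seed = 3)
ap   <- ap_params()                                # c = 8, e0 = 0.002, ...

corpus <- make_corpus(geom, n_fields = 3000, master_seed = 7)
vae    <- train_vae(corpus, hidden = c(256, 256), epochs = 30, seed = 5)

truth <- pmin(make_aha_test_case(geom, 17, severity = 0.45, rng_seed = 9), 0.5)
Y_obs <- make_observation(geom, ap, lf, truth, snr_db = 20, seed = 11)

run <- run_active_learning(Y_obs, vae, geom, ap, lf,
                           spec = acquisition_spec("lognormal_variance"),
                           seed = 21)
run
#> active_run: 90 forward simulations (9 initial + 81 acquired), converged: TRUE

s  <- sample_posterior_grid(run$posterior, 4000, seed = 33)
fs <- field_summary(s, vae)
field_metrics(fs$mean_field, truth)
#> $dc
#> [1] 0.8210526
#> $rmse
#> [1] 0.06414223
#> $cc
#> [1] 0.8287934
```

Read: the apical-segment abnormality was localized (Dice 0.82 at
threshold 0.3) from a 20 dB ECG using 90 forward simulations — where the
standard two-chain MCMC protocol budgets 20,000. `run$record` holds the
per-iteration ledger (selected z, log-posterior label, hyperparameters,
trailing KL); `latent_summary(run$posterior)` gives the latent mean,
mode and spread.

The MCMC baselines follow the reference sampling protocol:

```r
exact <- function(z) eval_log_posterior(z, vae, geom, ap, lf, Y_obs)
sur   <- gp_surrogate_log_density(run$state)
ts    <- run_mcmc_protocol(exact, surrogate_log_target = sur,
                           chain_length = 2000, seed = 6, two_stage = sur)
ts$n_forward_sims      # exact simulations spent by two-stage MH
```

`run_benchmark(default_benchmark_config(1))` chains the whole experiment
(corpus → VAE → observation → all four inference routes → comparison
tables) and `write_benchmark_report()` emits CSV/JSON tables. A thin
command-line wrapper for the same steps lives in `inst/cli/epactive.R`.

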