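# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# small geometry for unit tests
small_geom <- function() memo("small_geom", function() fixture_geometry(120L, seed = 1))

# 200-node geometry for integrator properties
mid_geom <- function() memo("mid_geom", function() fixture_geometry(200L, seed = 2))

# forward-model context at unit-test scale
small_forward <- function() memo("small_forward", function() {
  geom <- small_geom()
  list(geom = geom,
       ap = ap_params(),
       lf = build_synthetic_lead_field(geom, 24L, seed = 3))
})

# a tiny trained VAE on a real (small) corpus
tiny_vae_ctx <- function() memo("tiny_vae_ctx", function() {
  geom <- small_geom()
  corpus <- make_corpus(geom, n_fields = 400L, master_seed = 7)
  vae <- train_vae(corpus, hidden = c(48L, 48L), epochs = 25L,
                   patience = 25L, kl_warmup = 8L, seed = 5)
  list(geom = geom, corpus = corpus, vae = vae)
})

# a "constant decoder" VAE: all weights zero, so decode(z) is the same
# field for every z. Lets log-posterior contracts be tested exactly
# (zero residual regardless of z).
constant_vae <- function(n_input) {
  p <- vae_init(n_input, hidden = c(4L, 4L), seed = 1)
  for (k in names(p)) p[[k]][] <- 0
  p
}

# benchmark-scale context shared by the acceptance suite: the study
# conditions at reduced training size so that the whole suite fits a
# desk-scale run (documented in the methods vignette).
bench_ctx <- function() memo("bench_ctx", function() {
  cfg <- default_benchmark_config(1L, modify = list(
    corpus = list(n_fields = 3000L),
    vae = list(hidden = c(256L, 256L), epochs = 30L)))
  build_experiment_context(cfg)
})

# one observed case on the benchmark context (apical-segment abnormality,
# severity 0.45, 20 dB)
bench_case <- function(obs_seed = 11L) {
  ctxt <- bench_ctx()
  truth <- pmin(make_aha_test_case(ctxt$geom, 17L, 0.45,
                                   rng_seed = obs_seed), 0.5)
  Y_obs <- make_observation(ctxt$geom, ctxt$ap, ctxt$lf, truth,
                            snr_db = 20, seed = obs_seed + 1L)
  list(ctxt = ctxt, truth = truth, Y_obs = Y_obs)
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
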