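#' End-to-end benchmark orchestration
#'
#' Builds the full experiment from one configuration: fixture geometry,
#' region-growing corpus, VAE, synthetic observations for a set of
#' AHA-segment cases, inference by the presented method (both log-normal
#' acquisitions), regular Bayesian active learning (UCB), two-stage MCMC
#' and direct MCMC, and the comparison tables.
#'
#' @name workbench
#' @keywords internal
NULL

#' Default benchmark configuration
#'
#' Desk-scale defaults: 300-node geometry, 100-frame ECG likelihood,
#' three single-segment cases at severity 0.45, reduced MCMC chains
#' (2 x 2000). Every stochastic stage has an explicit seed derived from
#' `master_seed`. All entries may be overridden via `modify`.
#'
#' @param master_seed integer master seed
#' @param modify named list of overrides (nested lists merged shallowly)
#' @return nested configuration list
#' @export
default_benchmark_config <- function(master_seed = 1L, modify = list()) {
  ms <- as.integer(master_seed)
  cfg <- list(
    geometry = list(n_nodes = 300L, k = 6L, n_pacing = 12L, seed = ms + 1L),
    ap = list(d_iso = 2.0, dt = 0.04, t_end = 120, stim_amplitude = 8,
              stim_duration = 3),
    lead_field = list(n_leads = 120L, seed = ms + 2L),
    corpus = list(n_fields = 10000L, size_range = c(0.02, 0.40), knn = 5L,
                  seed = ms + 3L),
    vae = list(hidden = c(512L, 512L), latent_dim = 2L, batch_size = 64L,
               epochs = 30L, lr = 1e-3, patience = 10L, kl_warmup = 10L,
               obs_var = 0.01, seed = ms + 4L),
    observation = list(snr_db = 20, n_frames = 100L, seed = ms + 5L),
    cases = list(list(segments = 17L, severity = 0.45),
                 list(segments = c(13L, 14L), severity = 0.45),
                 list(segments = c(15L, 16L), severity = 0.45)),
    inference = list(kl_threshold = 1e-3, max_iter = 500L,
                     chain_length = 2000L, n_surrogate_samples = 8000L,
                     protocol_chain_length = 10000L,
                     dc_threshold = 0.3, seed = ms + 6L),
    master_seed = ms)
  for (nm in names(modify)) {
    named <- is.list(modify[[nm]]) && !is.null(names(modify[[nm]])) &&
      all(nzchar(names(modify[[nm]])))
    if (named && is.list(cfg[[nm]]))
      cfg[[nm]][names(modify[[nm]])] <- modify[[nm]]
    else cfg[[nm]] <- modify[[nm]]
  }
  cfg
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; entries override `default_benchmark_config()`
#' @return configuration list
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ms <- if (!is.null(raw$master_seed)) raw$master_seed else 1L
  default_benchmark_config(ms, modify = raw)
}

#' Build the shared experiment context from a configuration
#'
#' Geometry, lead field, corpus and trained VAE — everything upstream of
#' the per-case inference.
#'
#' @param cfg configuration list (see [default_benchmark_config()])
#' @param verbose log stage progress
#' @return list: `geom`, `lf`, `ap`, `corpus`, `vae`, `cfg`
#' @export
build_experiment_context <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("building geometry (%d nodes)", cfg$geometry$n_nodes)
  geom <- fixture_geometry(cfg$geometry$n_nodes, k = cfg$geometry$k,
                           n_pacing = cfg$geometry$n_pacing,
                           seed = cfg$geometry$seed)
  ap <- do.call(ap_params, cfg$ap)
  lf <- build_synthetic_lead_field(geom, cfg$lead_field$n_leads,
                                   seed = cfg$lead_field$seed)
  say("growing corpus (%d fields)", cfg$corpus$n_fields)
  corpus <- make_corpus(geom, cfg$corpus$n_fields,
                        size_range = cfg$corpus$size_range,
                        knn = cfg$corpus$knn, master_seed = cfg$corpus$seed)
  say("training VAE (hidden %s, %d epochs)",
      paste(cfg$vae$hidden, collapse = "x"), cfg$vae$epochs)
  vae <- train_vae(corpus, hidden = cfg$vae$hidden,
                   latent_dim = cfg$vae$latent_dim,
                   batch_size = cfg$vae$batch_size, epochs = cfg$vae$epochs,
                   lr = cfg$vae$lr, patience = cfg$vae$patience,
                   kl_warmup = cfg$vae$kl_warmup, obs_var = cfg$vae$obs_var,
                   seed = cfg$vae$seed)
  list(geom = geom, lf = lf, ap = ap, corpus = corpus, vae = vae, cfg = cfg)
}

# Inference for one synthetic case by all four methods.
run_benchmark_case <- function(ctxt, case, case_seed, verbose = FALSE) {
  cfg <- ctxt$cfg
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- pmin(make_aha_test_case(ctxt$geom, case$segments, case$severity,
                                   rng_seed = case_seed), 0.5)
  Y_obs <- make_observation(ctxt$geom, ctxt$ap, ctxt$lf, truth,
                            snr_db = cfg$observation$snr_db,
                            seed = case_seed + 1L,
                            n_frames = cfg$observation$n_frames)
  exact <- function(z) eval_log_posterior(z, ctxt$vae, ctxt$geom, ctxt$ap,
                                          ctxt$lf, Y_obs)
  runs <- list()
  for (kind in c("lognormal_variance", "lognormal_entropy", "ucb")) {
    say("  active learning (%s)", kind)
    runs[[kind]] <- run_active_learning(
      Y_obs, ctxt$vae, ctxt$geom, ctxt$ap, ctxt$lf,
      spec = acquisition_spec(kind),
      kl_threshold = cfg$inference$kl_threshold,
      max_iter = cfg$inference$max_iter, seed = case_seed + 2L)
  }
  # surrogate-posterior samples for the three BAL variants
  nss <- cfg$inference$n_surrogate_samples
  samples <- lapply(runs, function(r)
    sample_posterior_grid(r$posterior, nss, seed = case_seed + 3L))
  # two-stage MCMC with the variance-run GP as first stage
  sur <- gp_surrogate_log_density(runs$lognormal_variance$state)
  say("  two-stage MCMC (2 x %d)", cfg$inference$chain_length)
  ts <- run_mcmc_protocol(exact, surrogate_log_target = sur,
                          chain_length = cfg$inference$chain_length,
                          seed = case_seed + 4L, two_stage = sur)
  say("  direct MCMC (2 x %d)", cfg$inference$chain_length)
  dm <- run_mcmc_protocol(exact, surrogate_log_target = sur,
                          chain_length = cfg$inference$chain_length,
                          seed = case_seed + 5L)
  sample_sets <- c(samples, list(two_stage = ts$post$samples,
                                 direct = dm$post$samples))
  summaries <- lapply(sample_sets, latent_summary)
  kl_to_direct <- vapply(
    sample_sets[setdiff(names(sample_sets), "direct")],
    function(s) kl_between_estimates(s, sample_sets$direct,
                                     seed = case_seed + 6L), numeric(1))
  fsum <- lapply(sample_sets, field_summary, vae = ctxt$vae)
  metrics <- lapply(fsum, function(fs) list(
    mean = field_metrics(fs$mean_field, truth, cfg$inference$dc_threshold),
    mode = field_metrics(fs$mode_field, truth, cfg$inference$dc_threshold)))
  sim_counts <- c(
    lognormal_variance = runs$lognormal_variance$n_forward,
    lognormal_entropy = runs$lognormal_entropy$n_forward,
    ucb = runs$ucb$n_forward,
    two_stage = ts$n_forward_sims,
    direct = dm$n_forward_sims)
  list(truth = truth, Y_obs = Y_obs, runs = runs,
       mcmc = list(two_stage = ts, direct = dm),
       summaries = summaries, kl_to_direct = kl_to_direct,
       field_summaries = fsum, metrics = metrics, sim_counts = sim_counts,
       error = NULL)
}

#' Run the full benchmark
#'
#' For every configured case, simulates the ground truth, adds noise, and
#' runs: the presented method (variance and entropy log-normal
#' acquisitions), regular BAL (UCB) with surrogate sampling, two-stage
#' MCMC, and direct MCMC as the reference; then aggregates the
#' latent-summary error table, the KL-to-reference table, the field
#' accuracy table (Dice / RMSE / correlation), and the simulation-count
#' ledger. Per-case failures are quarantined and flagged.
#'
#' @param cfg configuration from [default_benchmark_config()]
#' @param context optional prebuilt [build_experiment_context()] (reused
#'   across calls to avoid retraining the VAE)
#' @param verbose log progress
#' @return a `benchmark_report`
#' @export
run_benchmark <- function(cfg = default_benchmark_config(), context = NULL,
                          verbose = FALSE) {
  ctxt <- if (is.null(context)) build_experiment_context(cfg, verbose) else context
  cases <- ctxt$cfg$cases
  results <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    if (verbose) message(sprintf("case %d / %d", i, length(cases)))
    case_seed <- ctxt$cfg$inference$seed + 100L * i
    results[[i]] <- tryCatch(
      run_benchmark_case(ctxt, cases[[i]], case_seed, verbose),
      error = function(e) list(error = conditionMessage(e)))
  }
  ok <- vapply(results, function(r) is.null(r$error), TRUE)
  methods <- c("lognormal_variance", "lognormal_entropy", "ucb",
               "two_stage", "direct")
  report <- list(config = ctxt$cfg, results = results, complete = all(ok))
  if (any(ok)) {
    okr <- results[ok]
    report$error_table <- lapply(
      setdiff(methods, "direct"), function(m) summary_error_table(
        lapply(okr, function(r) r$summaries[[m]]),
        lapply(okr, function(r) r$summaries$direct)))
    names(report$error_table) <- setdiff(methods, "direct")
    report$kl_table <- do.call(rbind, lapply(okr, function(r) r$kl_to_direct))
    report$sim_counts <- do.call(rbind, lapply(okr, function(r) r$sim_counts))
    report$metric_table <- do.call(rbind, lapply(seq_along(okr), function(i)
      do.call(rbind, lapply(methods, function(m) data.frame(
        case = i, method = m,
        dc_mean = okr[[i]]$metrics[[m]]$mean$dc,
        dc_mode = okr[[i]]$metrics[[m]]$mode$dc,
        rmse_mean = okr[[i]]$metrics[[m]]$mean$rmse,
        rmse_mode = okr[[i]]$metrics[[m]]$mode$rmse,
        cc_mean = okr[[i]]$metrics[[m]]$mean$cc,
        cc_mode = okr[[i]]$metrics[[m]]$mode$cc)))))
    # computation-reduction ledger vs the full protocol denominator
    denom <- 2L * ctxt$cfg$inference$protocol_chain_length
    presented <- report$sim_counts[, c("lognormal_variance",
                                       "lognormal_entropy")]
    report$reduction <- list(
      protocol_denominator = denom,
      presented_pct = 100 * (1 - mean(presented) / denom),
      two_stage_pct = 100 * (1 - mean(report$sim_counts[, "two_stage"] /
                                        (2 * ctxt$cfg$inference$chain_length))))
  }
  class(report) <- "benchmark_report"
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d case(s), complete: %s\n",
              length(x$results), x$complete))
  if (!is.null(x$kl_table)) {
    cat("median KL to direct-MCMC reference:\n")
    print(apply(x$kl_table, 2, stats::median))
    cat("forward-simulation counts:\n")
    print(x$sim_counts)
  }
  invisible(x)
}

#' Write benchmark report tables to a directory
#'
#' CSV tables (KL, metrics, simulation counts, per-method summary errors)
#' plus a JSON overview.
#'
#' @param report a `benchmark_report`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$kl_table))
    utils::write.csv(report$kl_table, file.path(dir, "kl_table.csv"),
                     row.names = FALSE)
  if (!is.null(report$sim_counts))
    utils::write.csv(report$sim_counts, file.path(dir, "sim_counts.csv"),
                     row.names = FALSE)
  if (!is.null(report$metric_table))
    utils::write.csv(report$metric_table, file.path(dir, "field_metrics.csv"),
                     row.names = FALSE)
  for (m in names(report$error_table))
    utils::write.csv(report$error_table[[m]],
                     file.path(dir, sprintf("summary_errors_%s.csv", m)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(complete = report$complete, reduction = report$reduction,
         master_seed = report$config$master_seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
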