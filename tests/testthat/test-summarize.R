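test_that("latent summaries recover closed-form moments and degenerate cases", {
  # degenerate: all samples identical
  s0 <- matrix(rep(c(1, -1), each = 50), 50)
  ls0 <- latent_summary(s0)
  expect_equal(ls0$mean, c(1, -1), ignore_attr = TRUE)
  expect_equal(ls0$mode, c(1, -1), ignore_attr = TRUE)
  expect_equal(ls0$std, c(0, 0), ignore_attr = TRUE)
  # large standard-normal sample: moments within Monte-Carlo tolerance
  set.seed(31)
  s <- matrix(rnorm(2e5), ncol = 2)
  ls <- latent_summary(s)
  expect_close(ls$mean, c(0, 0), 0.02)
  expect_close(ls$std, c(1, 1), 0.02)
  expect_close(ls$mode, c(0, 0), 0.2)
})

test_that("the KDE mode lands on the heavier component of a mixture", {
  set.seed(32)
  n <- 5000
  pick <- runif(n) < 0.7
  s <- cbind(ifelse(pick, -2, 2) + rnorm(n, sd = 0.3), rnorm(n, sd = 0.3))
  ls <- latent_summary(s)
  expect_close(ls$mode, c(-2, 0), 0.2)
})

test_that("grid-based summaries use quadrature moments", {
  grid <- latent_grid(c(-3, 3), 61L)
  dens <- exp(-0.5 * rowSums(sweep(grid$points, 2, c(1, -0.5))^2) / 0.25)
  dens <- dens / sum(grid$w * dens)
  pg <- structure(list(density = dens, log_density = log(dens), grid = grid),
                  class = "posterior_grid")
  ls <- latent_summary(pg)
  expect_close(ls$mean, c(1, -0.5), 0.01)
  expect_close(ls$mode, c(1, -0.5), 0.1)
  expect_close(ls$std, c(0.5, 0.5), 0.01)
})

test_that("field summaries decode samples with bounded convex statistics", {
  ctx <- tiny_vae_ctx()
  s1 <- matrix(c(0.4, -0.2), 1)
  fs1 <- field_summary(s1, ctx$vae)
  expect_equal(fs1$mean_field, fs1$mode_field, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(fs1$std_field), 0)
  set.seed(33)
  S <- matrix(rnorm(600), ncol = 2)
  fs <- field_summary(S, ctx$vae)
  expect_true(all(fs$mean_field >= 0 & fs$mean_field <= 0.5))
  expect_true(all(fs$mode_field >= 0 & fs$mode_field <= 0.5))
  expect_true(all(fs$std_field >= 0))
  dec <- vae_decode(ctx$vae, S)
  expect_true(all(fs$mean_field <= apply(dec, 2, max) + 1e-12))
  expect_true(all(fs$mean_field >= apply(dec, 2, min) - 1e-12))
})

test_that("the Monte-Carlo KL estimator matches Gaussian closed forms", {
  set.seed(34)
  p <- matrix(rnorm(5000), ncol = 1)
  q <- matrix(rnorm(5000) + 1, ncol = 1)
  # KL(N(0,1) || N(1,1)) = 1/2
  kl <- kl_between_estimates(p, q, n_mc = 2e4, seed = 1)
  expect_close(kl, 0.5, 0.05)
  # identical sample sets: KL ~ 0
  expect_lt(abs(kl_between_estimates(p, p, n_mc = 1e4, seed = 2)), 0.02)
  # asymmetry is respected
  kl_rev <- kl_between_estimates(q, p, n_mc = 2e4, seed = 3)
  expect_false(isTRUE(all.equal(kl, kl_rev, tolerance = 1e-3)))
  expect_error(kl_between_estimates(p[1:50, , drop = FALSE], q), "100")
})

test_that("the KL estimator is non-negative in expectation", {
  set.seed(35)
  kls <- vapply(1:20, function(r) {
    a <- matrix(rnorm(600), ncol = 2)
    b <- matrix(rnorm(600), ncol = 2)
    kl_between_estimates(a, b, n_mc = 1500, seed = r)
  }, numeric(1))
  expect_gte(mean(kls), -0.01)
})

test_that("field metrics implement Dice, RMSE and correlation exactly", {
  truth <- c(rep(0.5, 2), rep(0.15, 4))
  expect_equal(field_metrics(truth, truth),
               list(dc = 1, rmse = 0, cc = 1))
  est <- c(rep(0.15, 2), rep(0.5, 2), rep(0.15, 2))  # disjoint, sizes 2 & 2
  expect_equal(field_metrics(est, truth)$dc, 0)
  est2 <- c(0.5, 0.15, 0.5, 0.15, 0.15, 0.15)        # overlap of 1
  expect_equal(field_metrics(est2, truth)$dc, 0.5)
  expect_equal(field_metrics(rep(0.15, 6), rep(0.5, 6))$rmse, 0.35)
  expect_true(is.na(field_metrics(rep(0.2, 6), truth)$cc))
  expect_equal(field_metrics(rep(0.2, 6), rep(0.21, 6))$dc, 1)  # both empty
  expect_error(field_metrics(1:3 / 10, 1:4 / 10))
})

test_that("summary error tables aggregate per-statistic Euclidean errors", {
  mk <- function(mean, mode, std)
    structure(list(mean = mean, mode = mode, std = std),
              class = "latent_summary")
  ref <- mk(c(0, 0), c(0, 0), c(1, 1))
  same <- summary_error_table(list(ref), list(ref))
  expect_equal(same$mean_error, rep(0, 3))
  m1 <- mk(c(0, 0), c(0.02, 0), c(1, 1))
  tab <- summary_error_table(list(m1), list(ref))
  expect_equal(tab$mean_error[tab$statistic == "mode"], 0.02)
  # aggregation over three cases matches a hand computation
  ms <- list(mk(c(1, 0), c(0, 0), c(1, 1)),
             mk(c(0, 2), c(0, 0), c(1, 1)),
             mk(c(0, 0), c(0, 0), c(1, 1)))
  tab3 <- summary_error_table(ms, rep(list(ref), 3))
  mean_errs <- c(1, 2, 0)
  expect_equal(tab3$mean_error[tab3$statistic == "mean"], mean(mean_errs))
  expect_equal(tab3$sd_error[tab3$statistic == "mean"], sd(mean_errs))
})
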