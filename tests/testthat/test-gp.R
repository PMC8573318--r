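test_that("Matern 5/2 kernel matches its closed form", {
  h <- gp_hyper(c(1, 1), amplitude_sq = 1, noise_var = 1e-8)
  expect_equal(matern52(c(0.3, -0.2), c(0.3, -0.2), h), 1)
  expect_equal(matern52(c(0, 0), c(1, 0), h), 0.5239941, tolerance = 1e-6)
  # symmetry on random pairs; anisotropy enters through the length scales
  ha <- gp_hyper(c(0.5, 2), amplitude_sq = 1.7, noise_var = 1e-8)
  set.seed(1)
  for (i in 1:5) {
    zi <- rnorm(2); zj <- rnorm(2)
    expect_equal(matern52(zi, zj, ha), matern52(zj, zi, ha))
  }
  expect_equal(matern52(c(0, 0), c(0, 0), ha), 1.7)
  # direct closed-form evaluation at a scaled distance
  d <- sqrt(sum((c(1, 1) / c(0.5, 2))^2))
  expect_equal(matern52(c(0, 0), c(1, 1), ha),
               1.7 * exp(-sqrt(5) * d) * (1 + sqrt(5) * d + 5 / 3 * d^2))
})

test_that("GP prediction matches a dense-solve oracle", {
  set.seed(7)
  Z <- matrix(runif(40, -2, 2), 20)
  y <- sin(Z[, 1]) + 0.5 * Z[, 2]^2
  h <- gp_hyper(c(0.8, 1.3), amplitude_sq = 2, noise_var = 1e-4)
  st <- gp_state(Z, y, h)
  Zq <- matrix(runif(20, -2, 2), 10)
  pr <- gp_predict(st, Zq)
  K <- matern52(Z, Z, h) + diag(1e-4, 20)
  Ks <- matern52(Zq, Z, h)
  mu_ref <- Ks %*% solve(K, y)
  var_ref <- 2 - rowSums((Ks %*% solve(K)) * Ks)
  expect_close(pr$mean, as.numeric(mu_ref), 1e-8 * max(abs(mu_ref)))
  expect_close(pr$var, as.numeric(var_ref), 1e-8)
  expect_true(all(pr$var >= 0))
})

test_that("prior predictive and exact interpolation limits hold", {
  h <- gp_hyper(c(1, 1), amplitude_sq = 3, noise_var = 1e-8)
  st0 <- gp_state(NULL, numeric(0), h)
  pr0 <- gp_predict(st0, matrix(c(0, 0, 1, 1), 2, byrow = TRUE))
  expect_equal(pr0$mean, c(0, 0))
  expect_equal(pr0$var, c(3, 3))
  Z <- matrix(c(0, 0, 1, -1, -1, 0.5), 3, 2, byrow = TRUE)
  y <- c(1.2, -0.7, 0.4)
  st <- gp_state(Z, y, h)
  pr <- gp_predict(st, Z)
  expect_close(pr$mean, y, 1e-5)
  expect_true(all(pr$var < 1e-5))
})

test_that("log marginal likelihood matches closed forms and is permutation invariant", {
  h <- gp_hyper(c(1, 1), amplitude_sq = 2.5, noise_var = 0.1)
  st1 <- gp_state(matrix(c(0.3, -0.8), 1), 0, h)
  expect_equal(gp_log_marginal_likelihood(st1),
               dnorm(0, 0, sqrt(2.5 + 0.1), log = TRUE))
  set.seed(11)
  Z <- matrix(runif(20, -2, 2), 10)
  y <- rnorm(10)
  l1 <- gp_log_marginal_likelihood(gp_state(Z, y, h))
  perm <- sample(10)
  l2 <- gp_log_marginal_likelihood(gp_state(Z[perm, ], y[perm], h))
  expect_equal(l1, l2, tolerance = 1e-10)
  # dense-Cholesky oracle
  K <- matern52(Z, Z, h) + diag(0.1, 10)
  ref <- -0.5 * drop(t(y) %*% solve(K, y)) - 0.5 * determinant(K)$modulus -
    5 * log(2 * pi)
  expect_equal(l1, as.numeric(ref), tolerance = 1e-9)
  expect_error(gp_log_marginal_likelihood(gp_state(NULL, numeric(0), h)),
               "training point")
})

test_that("hyperparameter optimization never decreases the evidence and is deterministic", {
  set.seed(13)
  Z <- matrix(runif(30, -2, 2), 15)
  y <- cos(Z[, 1] * 2) + rnorm(15, sd = 0.05)
  st <- gp_state(Z, y, gp_hyper(c(3, 3), 0.5, 1e-2))
  before <- gp_log_marginal_likelihood(st)
  h1 <- gp_optimize_hyperparams(st, seed = 2)
  after <- gp_log_marginal_likelihood(gp_state(Z, y, h1))
  expect_gte(after, before - 1e-9)
  h2 <- gp_optimize_hyperparams(st, seed = 2)
  expect_equal(h1, h2)
  # bounds respected
  b <- gp_bounds()
  expect_true(all(h1$length_scales >= b$length_scale[1] - 1e-12 &
                  h1$length_scales <= b$length_scale[2] + 1e-12))
})

test_that("length scales are recovered within a factor of two on GP draws", {
  true_h <- gp_hyper(c(0.6, 1.5), amplitude_sq = 4, noise_var = 1e-4)
  ok <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    Z <- matrix(runif(120, -3, 3), 60)
    K <- matern52(Z, Z, true_h) + diag(1e-6, 60)
    y <- drop(t(chol(K)) %*% rnorm(60))
    st <- gp_state(Z, y, gp_hyper(c(1, 1), 1, 1e-3))
    fit <- gp_optimize_hyperparams(st, n_starts = 3L, seed = r)
    rat <- fit$length_scales / true_h$length_scales
    if (all(rat > 0.5 & rat < 2)) ok <- ok + 1L
  }
  expect_gte(ok, 0.8 * reps)
})

test_that("added training points never increase predictive variance", {
  h <- gp_hyper(c(1, 1), amplitude_sq = 1, noise_var = 1e-8)
  set.seed(5)
  for (r in 1:5) {
    Z <- matrix(runif(16, -2, 2), 8)
    y <- rnorm(8)
    q <- matrix(runif(10, -2, 2), 5)
    v1 <- gp_predict(gp_state(Z[1:6, ], y[1:6], h), q)$var
    v2 <- gp_predict(gp_state(Z, y, h), q)$var
    expect_true(all(v2 <= v1 + 1e-9))
  }
})

test_that("GP state round-trips through JSON", {
  set.seed(3)
  Z <- matrix(runif(12, -2, 2), 6)
  y <- rnorm(6)
  st <- gp_state(Z, y, gp_hyper(c(0.7, 1.2), 2.2, 1e-5))
  path <- tempfile(fileext = ".json")
  write_gp_state(st, path)
  back <- read_gp_state(path)
  q <- matrix(c(0.1, -0.4, 1, 2), 2, byrow = TRUE)
  expect_equal(gp_predict(back, q), gp_predict(st, q), tolerance = 1e-10)
})

test_that("bounded surrogate density vanishes outside the search domain", {
  set.seed(4)
  st <- gp_state(matrix(runif(10, -1, 1), 5), rnorm(5), gp_hyper())
  f <- gp_surrogate_log_density(st, domain = c(-2, 2))
  expect_equal(f(c(0.5, 0.5)), gp_predict(st, c(0.5, 0.5))$mean)
  expect_identical(f(c(3, 0)), -Inf)
})
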