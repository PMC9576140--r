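test_that("with no observations the log posterior is the standard-normal prior", {
  m <- make_linear_cholesky_model(latent_dim = 5)
  z <- c(0.5, -1, 0, 2, 0.3)
  expect_equal(pivae_log_posterior(m, z), -0.5 * sum(z^2), tolerance = 1e-12)
})

test_that("hand-set tiny model reproduces a by-hand likelihood sum", {
  # one observation, identity decoder on a 2-point grid
  k <- kernel_spec("rbf", 1)
  m <- make_linear_cholesky_model(k, grid = c(0, 0.5), latent_dim = 2)
  z <- c(0.3, -0.2)
  # f(0) = (L z)_1; with unit variance L[1,1] = 1 so f(0) = 0.3
  f0 <- as.numeric(feature_map_apply(m$feature_map, 0) %*% z)
  expect_equal(f0, 0.3, tolerance = 1e-12)
  lp <- pivae_log_posterior(m, z, s = 0, y = 1,
                            likelihood = likelihood_gaussian(sigma = 0.5))
  byhand <- -0.5 * sum(z^2) - 0.5 * (1 - 0.3)^2 / 0.25 - 1 * log(0.5)
  expect_equal(lp, byhand, tolerance = 1e-12)
})

test_that("NUTS matches the closed-form conjugate Gaussian posterior", {
  # linear decoder + Cholesky feature map + fixed sigma: the posterior over z
  # is Gaussian with precision I + A'A/sigma^2, mean Sigma A'y/sigma^2 where
  # A = Phi rows at the 5 observation locations (the independent oracle)
  grid <- seq(0, 1, length.out = 5)
  k <- kernel_spec("rbf", 0.4)
  m <- make_linear_cholesky_model(k, grid = grid, latent_dim = 5)
  s_obs <- grid
  y <- c(0.3, -0.1, 0.4, 1.2, 0.8)
  sigma <- 0.3
  A <- feature_map_apply(m$feature_map, s_obs)
  Prec <- diag(5) + crossprod(A) / sigma^2
  Sig <- solve(Prec)
  mu <- as.numeric(Sig %*% crossprod(A, y) / sigma^2)
  fit <- fit_pivae(m, s_obs, y, likelihood_gaussian(sigma = sigma),
                   chains = 8, warmup = 400, iter = 800, seed = 7)
  zm <- apply(fit$z, 3, as.vector)
  # autocorrelation-robust MC error from the spread of per-chain means
  chain_means <- apply(fit$z, c(1, 3), mean)
  se <- apply(chain_means, 2, stats::sd) / sqrt(nrow(chain_means))
  expect_true(all(abs(colMeans(zm) - mu) < 3.5 * se + 1e-8))
  expect_equal(stats::cov(zm), Sig, tolerance = 0.1)
  # posterior predictive matches the closed form within MC error
  pr <- predict(fit, grid, ndraws = 2000)
  pred_mean <- as.numeric(A %*% mu)
  expect_equal(pr$mean, pred_mean, tolerance = 0.05)
})

test_that("sampling the prior through NUTS recovers N(0, I) moments", {
  m <- tiny_trained_model()
  fit <- fit_pivae(m, s = NULL, y = NULL, chains = 4, warmup = 300, iter = 800,
                   seed = 8)
  zm <- apply(fit$z, 3, as.vector)
  expect_true(all(abs(colMeans(zm)) < 0.1))
  expect_equal(apply(zm, 2, stats::var), rep(1, m$latent_dim), tolerance = 0.15)
  expect_true(all(fit$diagnostics$rhat < 1.01))
})

test_that("sample paths satisfy the finite-marginal consistency property", {
  # simulating on {s_1..s_n} then dropping s_n equals simulating on
  # {s_1..s_(n-1)} bitwise under shared z (Kolmogorov marginalisation)
  m <- tiny_trained_model()
  z <- pivae:::with_seed(9, rnorm(m$latent_dim))
  s_all <- seq(0, 1, length.out = 11)
  strip <- function(x) { attributes(x) <- list(dim = dim(x)); x }
  f_all <- simulate(m, z = z, locations = s_all)
  f_sub <- simulate(m, z = z, locations = s_all[-11])
  expect_identical(strip(f_all)[-11, , drop = FALSE], strip(f_sub))
  # per-location values do not depend on which other locations are evaluated
  perm <- c(3, 1, 2, 7, 5)
  f_perm <- simulate(m, z = z, locations = s_all[perm])
  expect_equal(strip(f_perm), strip(f_all)[perm, , drop = FALSE],
               tolerance = 1e-12)
  # and the same path is bitwise reproducible across calls
  expect_identical(simulate(m, z = z, locations = s_all), f_all)
})

test_that("the predictive distribution of a zero decoder is pure noise", {
  m <- make_linear_cholesky_model(latent_dim = 5,
                                  W = matrix(0, 5, 5))
  fit <- fit_pivae(m, s = seq(0, 1, length.out = 5), y = rep(0, 5),
                   likelihood = likelihood_gaussian(sigma = 2),
                   chains = 2, warmup = 200, iter = 400, seed = 10)
  pr <- predict(fit, seq(0, 1, length.out = 5), include_noise = TRUE,
                ndraws = 800, seed = 11)
  draws <- attr(pr, "draws")
  expect_equal(mean(draws), 0, tolerance = 0.1)
  expect_equal(stats::sd(as.vector(draws)), 2, tolerance = 0.1)
  # without noise, f is identically zero
  pr0 <- predict(fit, seq(0, 1, length.out = 5), ndraws = 100)
  expect_equal(pr0$mean, rep(0, 5), tolerance = 1e-12)
})

test_that("noise-sd recovery: the sigma posterior brackets the truth", {
  m <- tiny_trained_model()
  set.seed(12)
  s <- seq(0, 1, length.out = 50)
  f <- simulate(m, nsim = 1, locations = s)  # truth on the model manifold
  y <- f[, 1] + rnorm(50, 0, 0.4)
  fit <- fit_pivae(m, s, y, likelihood_gaussian(noise_scale = 1),
                   chains = 2, warmup = 400, iter = 600, seed = 13)
  qs <- stats::quantile(fit$sigma, c(0.025, 0.975))
  expect_lt(qs[1], 0.4)
  expect_gt(qs[2], 0.4)
  expect_true(all(fit$diagnostics$rhat < 1.02))
  expect_equal(length(residuals(fit)), 50)
})

test_that("fit-time validation errors are informative", {
  m <- tiny_trained_model()
  expect_error(fit_pivae(m, s = 1:3, y = 1:2), class = "pivae_validation_error")
  expect_error(fit_pivae(m, s = c(0.1, NA), y = c(1, 2)),
               class = "pivae_validation_error")
  expect_error(pivae_log_posterior(m, z = 1), class = "pivae_validation_error")
  # point-process likelihood refuses a single-channel model
  expect_error(
    fit_pivae(m, s = c(0.2, 0.4), likelihood = likelihood_poisson_process(1),
              chains = 2, warmup = 50, iter = 50),
    class = "pivae_validation_error")
})
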