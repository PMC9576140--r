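test_that("NUTS recovers the moments of known Gaussian targets", {
  # standard normal in 2-D: sampling the prior
  lp <- function(q) list(lp = -0.5 * sum(q^2), grad = -q)
  fit <- nuts_sample(lp, init = c(0, 0), chains = 4, warmup = 400, iter = 1000,
                     seed = 1)
  X <- apply(fit$draws, 3, as.vector)
  n_eff <- min(mcmc_ess(fit$draws))
  expect_true(all(abs(colMeans(X)) < 3 / sqrt(n_eff)))
  expect_equal(stats::cov(X), diag(2), tolerance = 0.1)
  # correlated Gaussian, rho = 0.8
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  P <- solve(S)
  lp2 <- function(q) list(lp = -0.5 * sum(q * (P %*% q)),
                          grad = as.numeric(-P %*% q))
  fit2 <- nuts_sample(lp2, init = c(0, 0), chains = 4, warmup = 400,
                      iter = 1500, seed = 2)
  X2 <- apply(fit2$draws, 3, as.vector)
  expect_equal(stats::cov(X2), S, tolerance = 0.1)
  expect_true(all(mcmc_rhat(fit2$draws) < 1.01))
})

test_that("NUTS is reproducible and respects the mass-matrix scale", {
  lp <- function(q) list(lp = -0.5 * sum(q^2 / c(1, 100)),
                         grad = -q / c(1, 100))
  f1 <- nuts_sample(lp, init = c(0, 0), chains = 2, warmup = 300, iter = 400,
                    seed = 3)
  f2 <- nuts_sample(lp, init = c(0, 0), chains = 2, warmup = 300, iter = 400,
                    seed = 3)
  expect_identical(f1$draws, f2$draws)
  # adapted inverse mass reflects the 1:100 scale ratio
  expect_gt(median(f1$inv_mass[, 2] / f1$inv_mass[, 1]), 10)
  v <- apply(f1$draws, 3, as.vector)
  expect_equal(stats::var(v[, 2]), 100, tolerance = 0.35)
})

test_that("divergence warnings surface on pathological targets", {
  # a funnel-like density with rapidly exploding curvature
  lp <- function(q) {
    list(lp = -0.5 * q[1]^2 - 0.5 * q[2]^2 * exp(4 * q[1]),
         grad = c(-q[1] - 2 * q[2]^2 * exp(4 * q[1]), -q[2] * exp(4 * q[1])))
  }
  expect_warning(
    fit <- nuts_sample(lp, init = c(2, 0.1), chains = 2, warmup = 150,
                       iter = 300, seed = 4, divergence_tol = 5,
                       divergence_warn_frac = 0.001),
    "divergent")
  expect_gt(length(fit$warnings), 0)
})

test_that("diagnostics match closed-form references", {
  # i.i.d. standard-normal pseudo-chains: R-hat within [0.99, 1.01]
  x <- pivae:::with_seed(5, array(rnorm(4 * 1000), c(4, 1000, 1)))
  r <- mcmc_rhat(x[, , 1])
  expect_gt(r, 0.99); expect_lt(r, 1.01)
  tab <- mcmc_diagnostics(x)
  expect_named(tab, c("parameter", "rhat", "ess", "ess_per_draw"))
  expect_gt(tab$ess, 2000)
  # AR(1) with phi = 0.9: ESS/N = (1 - phi)/(1 + phi) = 1/19
  phi <- 0.9
  ar <- pivae:::with_seed(6, {
    sims <- replicate(4, as.numeric(
      stats::arima.sim(list(ar = phi), 20000, sd = sqrt(1 - phi^2))))
    t(sims)
  })
  ess <- mcmc_ess(ar, rank_normalized = FALSE)
  expect_equal(ess / (4 * 20000), (1 - phi) / (1 + phi), tolerance = 0.15)
  # chains with disjoint means: R-hat far above 1.1
  bad <- rbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(mcmc_rhat(bad), 1.1)
  # validation
  expect_error(mcmc_diagnostics(array(0, c(1, 100, 2))),
               class = "pivae_validation_error")
  expect_error(mcmc_diagnostics(array(0, c(2, 3, 2))),
               class = "pivae_validation_error")
})
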