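test_that("GP draw sets have the documented shape and are seed-reproducible", {
  k <- kernel_spec("rbf", lengthscale = 8)
  d <- draw_gp_functions(k, n_draws = 50, k_points = 101, domain = c(0, 1),
                         seed = 1)
  expect_equal(dim(d$values), c(50, 101, 1))
  expect_equal(dim(d$locations), c(50, 101, 1))
  d2 <- draw_gp_functions(k, n_draws = 50, k_points = 101, domain = c(0, 1),
                          seed = 1)
  expect_identical(d$values, d2$values)
  expect_identical(d$locations, d2$locations)
  # fresh locations per draw
  expect_false(isTRUE(all.equal(d$locations[1, , 1], d$locations[2, , 1])))
})

test_that("grid GP draws match the kernel's first and second moments", {
  grid <- c(0, 0.3, 1)
  k <- kernel_spec("rbf", lengthscale = 0.5)
  x <- draw_grid_gp(k, grid, n_draws = 20000, seed = 2)
  expect_equal(dim(x), c(20000, 3))
  # per-location empirical mean -> 0 within MC error (3 * 1/sqrt(n))
  expect_true(all(abs(colMeans(x)) < 3 / sqrt(20000)))
  # empirical covariance matches the Gram entrywise within 3 * SE
  K <- kernel_gram(k, grid)
  emp <- stats::cov(x)
  se <- sqrt((K[1, 1] * K[1, 1] + K^2) / 20000)   # var of a Gaussian cov est.
  expect_true(all(abs(emp - K) < 3 * se + 1e-6))
  # closed-form adjacent correlation: exp(-(0.3/0.5)^2)
  expect_equal(stats::cor(x[, 1], x[, 2]), exp(-0.36), tolerance = 0.05)
})

test_that("degenerate and invalid prior configurations error cleanly", {
  expect_error(kernel_spec("rbf", lengthscale = -1), class = "pivae_validation_error")
  expect_error(kernel_spec("rbf", lengthscale_range = c(2, 1)),
               class = "pivae_validation_error")
  expect_error(draw_grid_gp(kernel_spec("rbf"), c(0, 0.2, 0.1), 5, seed = 1),
               class = "pivae_validation_error")
  expect_error(draw_gp_functions(kernel_spec("rbf"), 2, 5, domain = c(1, 0),
                                 seed = 1), class = "pivae_validation_error")
  expect_error(draw_cubic_functions(10, 5, coef = list(a_sdlog = -1)),
               class = "pivae_validation_error")
  expect_error(draw_cubic_functions(10, 5, coef = list(bogus = 1)),
               class = "pivae_validation_error")
})

test_that("variance -> 0 limit yields the zero function on the grid", {
  x <- draw_grid_gp(kernel_spec("rbf", 1, variance = 1e-30), seq(0, 1, 0.1),
                    n_draws = 5, seed = 3)
  expect_true(all(abs(x) < 1e-10))
})

test_that("per-draw lengthscale resampling is log-uniform over the range", {
  k <- kernel_spec("rbf", lengthscale = 1, lengthscale_range = c(1e-3, 10))
  ells <- pivae:::with_seed(4, pivae:::draw_lengthscales(k, 5000))
  expect_true(all(ells >= 1e-3 & ells <= 10))
  lo <- log(1e-3); hi <- log(10)
  u <- (log(ells) - lo) / (hi - lo)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("cubic draws are monotone with the forced algebraic values", {
  d <- draw_cubic_functions(200, 30, domain = c(-6, 6), seed = 5)
  # derivative 3 a s^2 + b is nonnegative, so sorted locations give sorted values
  for (i in seq_len(200)) {
    o <- order(d$locations[i, , 1])
    expect_true(all(diff(d$values[i, o, 1]) >= 0))
  }
  # a = 1, b = 0, c = 0 forces f(2) = 8
  d0 <- draw_cubic_functions(5, 10, domain = c(-3, 3), seed = 6,
                             coef = list(a_sdlog = 0, b_scale = 0, c_sd = 0))
  i <- 1
  expect_equal(d0$values[i, , 1], d0$locations[i, , 1]^3)
})

test_that("LGCP draws carry consistent intensity and integral channels", {
  k <- kernel_spec("rbf", lengthscale = 0.25)
  d <- draw_lgcp_functions(k, n_draws = 40, n_events = 30, seed = 7)
  expect_equal(dim(d$values), c(40, 30, 2))
  # Lambda is nondecreasing along (sorted) event times in every draw
  for (i in seq_len(40)) expect_true(all(diff(d$values[i, , 2]) >= 0))
  # Lambda channel equals quadrature of the intensity on an independent fine
  # grid reconstruction: check via trapezoid of the lambda channel between
  # consecutive events (coarse bound, intensity is smooth)
  i <- 1
  ev <- d$locations[i, , 1]
  lam <- d$values[i, , 1]
  Lam <- d$values[i, , 2]
  inc_quad <- diff(ev) * (lam[-1] + lam[-30]) / 2
  expect_equal(diff(Lam), inc_quad, tolerance = 0.2)
  # raw accepted event counts average to the target across draws
  expect_equal(mean(d$meta$raw_counts), 30, tolerance = 0.15)
})

test_that("unit intensity makes the cumulative integral the identity", {
  # variance -> 0 forces g = 0, lambda = 1, so Lambda(s) = s and T = n_events
  k <- kernel_spec("rbf", lengthscale = 0.25, variance = 1e-12)
  d <- draw_lgcp_functions(k, n_draws = 3, n_events = 25, seed = 8)
  expect_equal(d$meta$horizon, rep(25, 3), tolerance = 1e-4)
  for (i in 1:3) {
    expect_equal(d$values[i, , 1], rep(1, 25), tolerance = 1e-4)
    expect_equal(d$values[i, , 2], d$locations[i, , 1], tolerance = 1e-3)
  }
})

test_that("draw sets round-trip through the archive and long CSV formats", {
  d <- draw_gp_functions(kernel_spec("rbf", 1), 4, 6, c(0, 1), seed = 9)
  p1 <- tempfile(fileext = ".rds"); p2 <- tempfile(fileext = ".csv")
  write_function_draws(d, p1)
  r1 <- read_function_draws(p1)
  expect_identical(r1$values, d$values)
  expect_identical(r1$meta$seed, 9L)
  write_function_draws(d, p2, csv = TRUE)
  r2 <- read_function_draws(p2, csv = TRUE)
  expect_equal(r2$values, d$values, tolerance = 1e-12)
  df <- as.data.frame(d)
  expect_named(df, c("draw_id", "k", "s_1", "y_1"))
  expect_equal(nrow(df), 24)
})
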