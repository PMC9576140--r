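test_that("kernel feature layers match closed-form evaluations", {
  # at a centre the feature attains its maximum of 1
  expect_equal(as.numeric(rbf_features(0.7, matrix(0.7), 2)), 1)
  expect_equal(as.numeric(matern32_features(0.7, matrix(0.7), 2)), 1)
  # s = 0, c = 1, l = 1: exp(-1)
  expect_equal(as.numeric(rbf_features(0, matrix(1), 1)), exp(-1),
               tolerance = 1e-12)
  # r = 1, l = 1: (1 + sqrt(3)) * exp(-sqrt(3))
  expect_equal(as.numeric(matern32_features(0, matrix(1), 1)),
               (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-12)
  expect_error(rbf_features(0, matrix(1), 0), class = "pivae_validation_error")
  # 2-D batch shape
  ftr <- matern32_features(matrix(runif(10), 5, 2), matrix(runif(6), 3, 2), 0.5)
  expect_equal(dim(ftr), c(5, 3))
})

test_that("feature_map_apply composes the kernel layer with the network", {
  set.seed(1)
  fm <- pivae:::feature_map_init("rbf", c(0, 1), n_centres = 3,
                                 hidden = c(4), F_dim = 2, P = 1L)
  s <- matrix(c(0.3, 0.9), ncol = 1)
  out <- feature_map_apply(fm, s)
  # independent by-hand forward pass
  E <- exp(-outer(s[, 1], fm$centres[, 1], function(a, b) (a - b)^2) /
             exp(fm$log_lengthscale)^2)
  H <- tanh(sweep(E %*% fm$net$W[[1]], 2, fm$net$b[[1]], "+"))
  expect_equal(out, sweep(H %*% fm$net$W[[2]], 2, fm$net$b[[2]], "+"),
               tolerance = 1e-12)
  # zero network weights give the zero feature vector everywhere
  fm0 <- fm
  fm0$net$W <- lapply(fm0$net$W, function(w) w * 0)
  fm0$net$b <- lapply(fm0$net$b, function(b) b * 0)
  expect_equal(as.numeric(feature_map_apply(fm0, s)), c(0, 0, 0, 0))
  # identity single linear layer returns the kernel-layer output
  fm1 <- pivae:::new_feature_map("rbf", fm$centres, fm$log_lengthscale,
                                 list(W = list(diag(3)), b = list(numeric(3)),
                                      sizes = c(3, 3)), 3L, 1L)
  expect_equal(feature_map_apply(fm1, s),
               pivae:::kernel_layer_forward(fm1, s)$E)
  expect_error(feature_map_apply(fm, matrix(1, 1, 2)),
               class = "pivae_validation_error")
})

test_that("feature maps are continuous in the location", {
  set.seed(2)
  fm <- pivae:::feature_map_init("matern32", c(0, 1), 5, c(6), 4, 1L)
  s0 <- 0.4
  for (h in 10^(-(2:5))) {
    gap <- max(abs(feature_map_apply(fm, s0 + h) - feature_map_apply(fm, s0)))
    expect_lt(gap, 10 * h)   # locally Lipschitz
  }
})

test_that("the Cholesky feature map is exact on hand-computable cases", {
  # white-noise-like kernel: far-apart points, Gram ~ I, features = unit rows
  k <- kernel_spec("rbf", lengthscale = 1e-3)
  fm <- cholesky_feature_map(k, c(0, 10, 20))
  expect_equal(feature_map_apply(fm, c(0, 10, 20)), diag(3), tolerance = 1e-12)
  # 2-point grid with correlation rho: columns (1, 0), (rho, sqrt(1 - rho^2))
  k2 <- kernel_spec("rbf", lengthscale = 1)
  rho <- exp(-0.25)
  fm2 <- cholesky_feature_map(k2, c(0, 0.5))
  expect_equal(feature_map_apply(fm2, 0), matrix(c(1, 0), 1), tolerance = 1e-12)
  expect_equal(feature_map_apply(fm2, 0.5),
               matrix(c(rho, sqrt(1 - rho^2)), 1), tolerance = 1e-12)
  # off-grid lookups refuse
  expect_error(feature_map_apply(fm2, 0.25), class = "pivae_lookup_error")
  expect_error(cholesky_feature_map(k2, c(0, 0)), class = "pivae_validation_error")
})

test_that("beta ~ N(0,I) through the Cholesky map reproduces the Gram exactly", {
  grid <- seq(0, 1, length.out = 6)
  k <- kernel_spec("rbf", lengthscale = 0.4)
  fm <- cholesky_feature_map(k, grid)
  Phi <- feature_map_apply(fm, grid)        # rows are Phi(s_i)
  # Cov(Phi beta) = Phi Phi^T = L L^T = Gram, to machine precision
  expect_equal(Phi %*% t(Phi), kernel_gram(k, grid), tolerance = 1e-12)
})
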