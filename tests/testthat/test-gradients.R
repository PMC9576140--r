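# The training loop and the samplers rely on hand-derived reverse-mode
# gradients; every parameter group is checked against central finite
# differences on a small random instance.

test_that("loss gradients match finite differences for every parameter group", {
  set.seed(41)
  N <- 3; K <- 5; F_dim <- 4; L <- 2
  d <- draw_gp_functions(kernel_spec("rbf", 0.5), N, K, c(0, 1), seed = 42)
  fm <- pivae:::feature_map_init("matern32", c(0, 1), 3, c(5), F_dim, 1L)
  enc <- pivae:::mlp_init(c(F_dim, 4, 2 * L))
  dec <- pivae:::mlp_init(c(L, 4, F_dim))
  beta <- matrix(rnorm(N * F_dim, 0, 0.3), N, F_dim)
  loc <- matrix(aperm(d$locations, c(2, 1, 3)), N * K, 1)
  y <- matrix(aperm(d$values, c(2, 1, 3)), N * K, 1)
  rep_idx <- rep(seq_len(N), each = K)
  eps <- matrix(rnorm(N * L), N, L)
  res <- pivae:::pivae_loss_core(fm, enc, dec, beta, loc, y, rep_idx, eps, 1)
  lossfun <- function(fm, enc, dec, beta)
    pivae:::pivae_loss_core(fm, enc, dec, beta, loc, y, rep_idx, eps, 1,
                            want_grads = FALSE)$total
  h <- 1e-6
  num_grad <- function(get, set) {
    v <- get()
    vapply(seq_along(v), function(i) {
      vp <- v; vp[i] <- v[i] + h; l1 <- do.call(lossfun, set(vp))
      vp[i] <- v[i] - h; l2 <- do.call(lossfun, set(vp))
      (l1 - l2) / (2 * h)
    }, numeric(1))
  }
  base <- list(fm = fm, enc = enc, dec = dec, beta = beta)
  cases <- list(
    enc_W1 = list(function() as.vector(enc$W[[1]]),
                  function(v) { b <- base; b$enc$W[[1]][] <- v; b },
                  function() as.vector(res$grads$enc_W1)),
    enc_b2 = list(function() enc$b[[2]],
                  function(v) { b <- base; b$enc$b[[2]] <- v; b },
                  function() res$grads$enc_b2),
    dec_W2 = list(function() as.vector(dec$W[[2]]),
                  function(v) { b <- base; b$dec$W[[2]][] <- v; b },
                  function() as.vector(res$grads$dec_W2)),
    phi_W1 = list(function() as.vector(fm$net$W[[1]]),
                  function(v) { b <- base; b$fm$net$W[[1]][] <- v; b },
                  function() as.vector(res$grads$phi_W1)),
    centres = list(function() as.vector(fm$centres),
                   function(v) { b <- base; b$fm$centres[] <- v; b },
                   function() as.vector(res$grads$phi_centres)),
    logell = list(function() fm$log_lengthscale,
                  function(v) { b <- base; b$fm$log_lengthscale <- v; b },
                  function() res$grads$phi_log_lengthscale),
    beta = list(function() as.vector(beta),
                function(v) { b <- base; b$beta[] <- v; b },
                function() as.vector(res$dBeta)))
  for (nm in names(cases)) {
    num <- num_grad(cases[[nm]][[1]], cases[[nm]][[2]])
    expect_equal(num, cases[[nm]][[3]](), tolerance = 1e-5, label = nm)
  }
})

test_that("the stage-2 log-posterior gradient matches finite differences", {
  m <- tiny_trained_model()
  set.seed(43)
  s <- runif(7); y <- rnorm(7)
  for (lik in list(likelihood_gaussian(noise_scale = 2),
                   likelihood_gaussian(sigma = 0.7))) {
    lp_fn <- pivae:::make_log_posterior(m, s, y, lik)
    d <- m$latent_dim + as.integer(is.null(lik$sigma))
    par <- rnorm(d, 0, 0.5)
    g <- lp_fn(par)$grad
    h <- 1e-6
    num <- vapply(seq_len(d), function(i) {
      p1 <- par; p1[i] <- par[i] + h
      p2 <- par; p2[i] <- par[i] - h
      (lp_fn(p1)$lp - lp_fn(p2)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(num, g, tolerance = 1e-5)
  }
})

test_that("the point-process log-posterior gradient matches finite differences", {
  set.seed(44)
  d <- draw_lgcp_functions(kernel_spec("rbf", 0.25), 25, 15, seed = 45)
  d$values[, , 1] <- log(d$values[, , 1])
  m <- pivae(d, latent_dim = 3, n_centres = 5, basis_dim = 6,
             phi_hidden = c(6), enc_hidden = c(6), dec_hidden = c(6),
             epochs = 5, batch_size = 25, seed = 46)
  ev <- d$events[[1]]
  lp_fn <- pivae:::make_log_posterior(m, ev, NULL,
                                      likelihood_poisson_process(max(ev) + 1))
  par <- rnorm(3, 0, 0.5)
  g <- lp_fn(par)$grad
  h <- 1e-6
  num <- vapply(1:3, function(i) {
    p1 <- par; p1[i] <- par[i] + h
    p2 <- par; p2[i] <- par[i] - h
    (lp_fn(p1)$lp - lp_fn(p2)$lp) / (2 * h)
  }, numeric(1))
  expect_equal(num, g, tolerance = 1e-5)
})
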