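#' Latent-Gaussian building blocks
#'
#' `encode` maps a batch of basis-coefficient vectors through the encoder to
#' the latent Gaussian (mean and softplus-positive standard deviation heads);
#' `reparameterize` applies the location-scale reparameterisation
#' \eqn{z = z_\mu + z_{sd} \odot \epsilon}; `decode` maps latent vectors to
#' reconstructed coefficients; `kl_std_normal` is the closed-form
#' Kullback-Leibler divergence
#' \eqn{\tfrac12 \sum_l (z_{sd,l}^2 + z_{\mu,l}^2 - 1 - 2\ln z_{sd,l})}
#' of the latent Gaussian from the standard normal.
#'
#' @param beta Coefficient batch: `n x F` matrix (or length-F vector).
#' @param encoder,decoder Encoder/decoder networks (components of a fitted
#'   [pivae()] model).
#' @return `encode` returns a list with matrices `z_mu` and `z_sd`;
#'   `reparameterize` and `decode` return matrices; `kl_std_normal` a
#'   nonnegative scalar per row.
#' @export
encode <- function(beta, encoder) {
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = 1L)
  check_finite(beta, "beta")
  out <- mlp_forward(encoder, beta)
  L <- ncol(out) / 2L
  list(z_mu = out[, seq_len(L), drop = FALSE],
       z_sd = softplus(out[, L + seq_len(L), drop = FALSE]))
}

#' @rdname encode
#' @param latent A list with `z_mu` and `z_sd` as returned by `encode`.
#' @param eps Standard-normal draw(s), same shape as `latent$z_mu`.
#' @export
reparameterize <- function(latent, eps) {
  stopifnot(all(dim(latent$z_mu) == dim(latent$z_sd)))
  if (!is.matrix(eps)) eps <- matrix(eps, nrow = nrow(latent$z_mu), byrow = TRUE)
  latent$z_mu + latent$z_sd * eps
}

#' @rdname encode
#' @param z Latent batch: `n x L` matrix (or length-L vector).
#' @export
decode <- function(z, decoder) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  mlp_forward(decoder, z)
}

#' @rdname encode
#' @export
kl_std_normal <- function(latent) {
  if (!is.matrix(latent$z_mu)) {
    latent$z_mu <- matrix(latent$z_mu, nrow = 1L)
    latent$z_sd <- matrix(latent$z_sd, nrow = 1L)
  }
  if (any(latent$z_sd <= 0)) {
    stop_pivae("z_sd must be positive", class = "pivae_validation_error")
  }
  0.5 * rowSums(latent$z_sd^2 + latent$z_mu^2 - 1 - 2 * log(latent$z_sd))
}

# ---- loss -----------------------------------------------------------------

# Evaluate the three-part loss on a batch and (optionally) its gradients.
# values/locations are the flattened batch: loc_flat ((B*K) x D),
# y_flat ((B*K) x P) in standardized units, rep_idx = rep(1:B, each = K).
# Returns list(loss1, loss2, kl, total, grads?).
pivae_loss_core <- function(fm, enc, dec, beta_B, loc_flat, y_flat, rep_idx,
                            eps, kl_weight, phi_trainable = TRUE,
                            phi_flat = NULL, want_grads = TRUE) {
  B <- nrow(beta_B); K <- length(rep_idx) / B
  F_dim <- ncol(beta_B); P <- ncol(y_flat)
  if (is.null(phi_flat) && fm$kind == "kernel") {
    # fused compiled path (kernel feature layer + MLPs, with gradients)
    return(.cpp_pivae_batch(loc_flat, y_flat, beta_B, fm$centres,
                            fm$log_lengthscale, fm$flavour, fm$net, enc, dec,
                            eps, kl_weight, as.integer(K), phi_trainable,
                            want_grads))
  }
  if (is.null(phi_flat)) {
    phi_flat <- cholesky_feature_lookup(fm, loc_flat)
  }
  kf <- NULL; phi_fw <- NULL
  phi_trainable <- FALSE

  Bexp <- beta_B[rep_idx, , drop = FALSE]
  lat <- encode(beta_B, enc)
  z <- reparameterize(lat, eps)
  betahat <- decode(z, dec)
  Bhexp <- betahat[rep_idx, , drop = FALSE]

  loss1 <- 0; loss2 <- 0
  G1 <- matrix(0, nrow(y_flat), P); G2 <- G1
  f1 <- matrix(0, nrow(y_flat), P); f2 <- f1
  for (p in seq_len(P)) {
    cols <- (p - 1L) * F_dim + seq_len(F_dim)
    Phi_p <- phi_flat[, cols, drop = FALSE]
    f1[, p] <- rowSums(Bexp * Phi_p)
    f2[, p] <- rowSums(Bhexp * Phi_p)
    loss1 <- loss1 + sum((y_flat[, p] - f1[, p])^2)
    loss2 <- loss2 + sum((y_flat[, p] - f2[, p])^2)
    G1[, p] <- 2 * (f1[, p] - y_flat[, p]) / (B * K)
    G2[, p] <- 2 * (f2[, p] - y_flat[, p]) / (B * K)
  }
  loss1 <- loss1 / (B * K)
  loss2 <- loss2 / (B * K)
  # all three terms share the 1/(NK) normalisation, so the reconstruction/KL
  # balance matches the per-observation evidence lower bound
  kl <- sum(kl_std_normal(lat)) / (B * K)
  total <- loss1 + loss2 + kl_weight * kl
  out <- list(loss1 = loss1, loss2 = loss2, kl = kl, total = total)
  if (!want_grads) return(out)

  L <- ncol(z)
  dPhi <- matrix(0, nrow(y_flat), F_dim * P)
  dBeta <- matrix(0, B, F_dim)
  dBetahat <- matrix(0, B, F_dim)
  for (p in seq_len(P)) {
    cols <- (p - 1L) * F_dim + seq_len(F_dim)
    Phi_p <- phi_flat[, cols, drop = FALSE]
    dPhi[, cols] <- G1[, p] * Bexp + G2[, p] * Bhexp
    dBeta <- dBeta + rowsum(G1[, p] * Phi_p, rep_idx)
    dBetahat <- dBetahat + rowsum(G2[, p] * Phi_p, rep_idx)
  }
  # decoder
  dec_fw <- mlp_forward(dec, z, cache = TRUE)
  dec_bp <- mlp_backprop(dec, dec_fw, dBetahat)
  dZ <- dec_bp$X
  # reparameterisation + KL into the encoder heads
  dmu <- dZ + kl_weight * lat$z_mu / (B * K)
  dsd <- dZ * eps + kl_weight * (lat$z_sd - 1 / lat$z_sd) / (B * K)
  enc_fw <- mlp_forward(enc, beta_B, cache = TRUE)
  raw <- enc_fw$out[, L + seq_len(L), drop = FALSE]
  dhead <- cbind(dmu, dsd * sigmoid(raw))
  enc_bp <- mlp_backprop(enc, enc_fw, dhead)
  dBeta <- dBeta + enc_bp$X

  grads <- c(net_grads(dec_bp, "dec"), net_grads(enc_bp, "enc"))
  if (phi_trainable) {
    phi_bp <- mlp_backprop(fm$net, phi_fw, dPhi)
    grads <- c(grads, net_grads(phi_bp, "phi"))
    klg <- kernel_layer_backprop(fm, loc_flat, kf, phi_bp$X)
    grads$phi_centres <- klg$centres
    grads$phi_log_lengthscale <- klg$log_lengthscale
  }
  out$grads <- grads
  out$dBeta <- dBeta
  out
}

#' Three-part training loss of a pi-VAE model
#'
#' Reports, for a slice of a training set, the loss actually optimised during
#' training: `loss1` (mean squared error of the learned per-realisation
#' coefficients through the feature map), `loss2` (the same with the
#' VAE-reconstructed coefficients), `kl` (Kullback-Leibler divergence of the
#' encoded latents from the standard normal, under the same `1/(NK)`
#' normalisation as the two reconstruction terms, so the reconstruction/KL
#' balance matches the per-observation evidence lower bound), and
#' `total = loss1 + loss2 + kl_weight * kl`. The coefficient reconstruction
#' error \eqn{\|\beta - \hat\beta\|^2} is deliberately not part of the loss.
#'
#' @param model A fitted [pivae()] object.
#' @param draws A [function_draws] training set slice (values in the model's
#'   original units; the model's standardisation is applied internally).
#' @param indices Which rows of the model's coefficient bank align with
#'   `draws` (defaults to the first `n` rows).
#' @param eps Optional fixed standard-normal matrix (one row per draw) for a
#'   deterministic evaluation; defaults to zeros (the latent means).
#' @param kl_weight Weight of the KL term.
#' @return List with `loss1`, `loss2`, `kl`, `total`.
#' @export
pivae_loss <- function(model, draws, indices = NULL, eps = NULL,
                       kl_weight = model$kl_weight) {
  stopifnot(inherits(model, "pivae"), inherits(draws, "function_draws"))
  d <- dim(draws$locations); n <- d[1]; k <- d[2]
  indices <- indices %||% seq_len(n)
  if (length(indices) != n || any(indices < 1) || any(indices > nrow(model$beta))) {
    stop_pivae("indices must align draws with rows of the coefficient bank",
               class = "pivae_validation_error")
  }
  loc_flat <- matrix(aperm(draws$locations, c(2, 1, 3)), n * k, d[3])
  y_flat <- matrix(aperm(draws$values, c(2, 1, 3)), n * k, dim(draws$values)[3])
  y_flat <- sweep(sweep(y_flat, 2L, model$scale$mean), 2L, model$scale$sd, "/")
  eps <- eps %||% matrix(0, n, model$latent_dim)
  res <- pivae_loss_core(model$feature_map, model$encoder, model$decoder,
                         model$beta[indices, , drop = FALSE], loc_flat, y_flat,
                         rep(seq_len(n), each = k), eps, kl_weight,
                         want_grads = FALSE)
  res[c("loss1", "loss2", "kl", "total")]
}

# ---- training -------------------------------------------------------------

#' Fit a prior-encoding variational autoencoder
#'
#' Stage one of the two-stage framework: jointly learns, from `n` draws of a
#' function prior, (i) a feature map \eqn{\Phi(s)} (kernel layer with
#' trainable centres plus a feed-forward network) shared across all draws,
#' (ii) one coefficient vector \eqn{\beta_i} per training realisation, and
#' (iii) a variational autoencoder over the \eqn{\beta_i} (encoder to a
#' latent Gaussian, decoder back to coefficients). The loss is the sum of the
#' two data-space mean-squared errors (with \eqn{\beta_i} and with the
#' reconstruction \eqn{\hat\beta_i}) plus the KL divergence of the latents
#' from the standard normal. Optimisation is Adam over minibatches of
#' realisations.
#'
#' The returned object is a new stochastic process: sample paths are
#' \eqn{f(s) = d(z)^\top \Phi(s)} for \eqn{z \sim N(0, I)} (see
#' [simulate.pivae()]), and the frozen decoder and feature map serve as a
#' prior for fully Bayesian inference on new data (see [fit_pivae()]).
#'
#' Training values are standardised per channel (global mean and standard
#' deviation over the whole draw set) so that the squared-error terms are at
#' unit scale against the KL term; the standardisation is stored in the model
#' and undone by `simulate`/`predict`.
#'
#' @param draws A [function_draws] training set.
#' @param latent_dim Latent dimension L (must be below the basis dimension).
#' @param feature Kernel flavour of the first feature layer, or a prebuilt
#'   feature map object (e.g. [cholesky_feature_map()]), which is then held
#'   fixed.
#' @param n_centres Number of trainable centres in the kernel layer.
#' @param basis_dim Basis dimension F (length of \eqn{\beta}); defaults to
#'   the feature network's output width choice, 20.
#' @param phi_hidden,enc_hidden,dec_hidden Hidden-layer widths of the feature
#'   network, encoder and decoder (use `integer(0)` for a single linear
#'   layer).
#' @param epochs,batch_size,lr Optimiser schedule: number of passes over the
#'   draw set, minibatch size (realisations), Adam learning rate.
#' @param lr_schedule `"constant"`, or `"cosine"` for a half-cosine decay of
#'   the learning rate to 5% of its initial value over the epochs (reaches a
#'   given loss in fewer epochs on the harder multi-channel problems).
#' @param kl_weight Weight of the KL term (1 = the plain variational loss).
#' @param standardize Standardise training values per channel (recommended;
#'   disable only for oracle constructions on unit-scale data).
#' @param seed Integer seed; training is bitwise reproducible per seed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `pivae` with components `feature_map`,
#'   `encoder`, `decoder`, `beta` (the N x F coefficient bank), `scale`,
#'   `history` (per-epoch loss terms) and `meta`.
#' @seealso [simulate.pivae()], [fit_pivae()], [gridvae()]
#' @export
pivae <- function(draws, latent_dim = 10, feature = c("rbf", "matern32"),
                  n_centres = 20, basis_dim = 20,
                  phi_hidden = c(20, 20), enc_hidden = c(20, 20),
                  dec_hidden = c(20, 20), epochs = 200, batch_size = 100,
                  lr = 1e-3, lr_schedule = c("constant", "cosine"),
                  kl_weight = 1, standardize = TRUE, seed = 1,
                  verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(inherits(draws, "function_draws"))
  d <- dim(draws$locations); N <- d[1]; K <- d[2]; D <- d[3]
  P <- dim(draws$values)[3]
  latent_dim <- check_count(latent_dim, "latent_dim")
  epochs <- check_count(epochs, "epochs")
  batch_size <- min(check_count(batch_size, "batch_size"), N)

  prebuilt <- inherits(feature, "pivae_feature_map")
  if (!prebuilt) feature <- match.arg(feature)

  # standardisation per value channel
  if (standardize) {
    mu <- apply(draws$values, 3L, mean)
    sdv <- apply(draws$values, 3L, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- rep(0, P); sdv <- rep(1, P)
  }

  loc_all <- matrix(aperm(draws$locations, c(2, 1, 3)), N * K, D)
  y_all <- matrix(aperm(draws$values, c(2, 1, 3)), N * K, P)
  y_all <- sweep(sweep(y_all, 2L, mu), 2L, sdv, "/")

  arch <- list(latent_dim = latent_dim, n_centres = n_centres,
               basis_dim = basis_dim, phi_hidden = phi_hidden,
               enc_hidden = enc_hidden, dec_hidden = dec_hidden,
               epochs = epochs, batch_size = batch_size, lr = lr,
               kl_weight = kl_weight, standardize = standardize,
               feature = if (prebuilt) "prebuilt" else feature)

  with_seed(seed, {
    if (prebuilt) {
      fm <- feature
      if (fm$P != P && !(fm$kind == "cholesky" && P == 1L)) {
        stop_pivae("prebuilt feature map channel count does not match draws",
                   class = "pivae_validation_error")
      }
      F_dim <- fm$F_dim
      phi_trainable <- FALSE
    } else {
      dom <- apply(loc_all, 2L, range)
      fm <- feature_map_init(feature, dom, n_centres, phi_hidden, basis_dim, P)
      F_dim <- basis_dim
      phi_trainable <- TRUE
    }
    if (latent_dim >= F_dim) {
      stop_pivae("latent_dim must be below the basis dimension F = ", F_dim,
                 class = "pivae_validation_error")
    }
    enc <- mlp_init(c(F_dim, enc_hidden, 2L * latent_dim))
    dec <- mlp_init(c(latent_dim, dec_hidden, F_dim))
    beta <- matrix(stats::rnorm(N * F_dim, 0, 0.1), N, F_dim)

    params <- c(net_params(enc, "enc"), net_params(dec, "dec"))
    if (phi_trainable) {
      params <- c(params, net_params(fm$net, "phi"),
                  list(phi_centres = fm$centres,
                       phi_log_lengthscale = fm$log_lengthscale))
    }
    opt <- adam_init(params)
    beta_opt <- adam_init(list(beta = beta))

    phi_fixed <- if (!phi_trainable) {
      if (fm$kind == "cholesky") cholesky_feature_lookup(fm, loc_all)
      else feature_map_apply(fm, loc_all)
    } else NULL

    n_batches <- ceiling(N / batch_size)
    history <- data.frame(epoch = seq_len(epochs), loss1 = NA_real_,
                          loss2 = NA_real_, kl = NA_real_, total = NA_real_,
                          seconds = NA_real_)
    t0 <- proc.time()[["elapsed"]]
    for (ep in seq_len(epochs)) {
      lr_ep <- if (lr_schedule == "cosine" && epochs > 1) {
        lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - 1) / (epochs - 1))))
      } else lr
      perm <- sample.int(N)
      acc <- c(loss1 = 0, loss2 = 0, kl = 0, total = 0)
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * batch_size + 1L):min(bi * batch_size, N)]
        B <- length(idx)
        flat_idx <- as.vector(outer(seq_len(K), (idx - 1L) * K, "+"))
        loc_flat <- loc_all[flat_idx, , drop = FALSE]
        y_flat <- y_all[flat_idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(B * latent_dim), B, latent_dim)
        res <- pivae_loss_core(fm, enc, dec, beta[idx, , drop = FALSE],
                               loc_flat, y_flat, rep(seq_len(B), each = K),
                               eps, kl_weight, phi_trainable,
                               phi_flat = if (is.null(phi_fixed)) NULL else
                                 phi_fixed[flat_idx, , drop = FALSE])
        if (!is.finite(res$total)) {
          stop_pivae("training loss diverged (non-finite) at epoch ", ep,
                     class = "pivae_numerical_error")
        }
        st <- adam_step(opt, params, res$grads, lr = lr_ep)
        opt <- st$state; params <- st$params
        enc <- net_from_params(enc, params, "enc")
        dec <- net_from_params(dec, params, "dec")
        if (phi_trainable) {
          fm$net <- net_from_params(fm$net, params, "phi")
          fm$centres <- params$phi_centres
          fm$log_lengthscale <- params$phi_log_lengthscale
        }
        # sparse Adam update of the coefficient bank rows in this batch
        beta_opt$t <- beta_opt$t + 1L
        c1 <- 1 - 0.9^beta_opt$t; c2 <- 1 - 0.999^beta_opt$t
        gb <- res$dBeta
        beta_opt$m$beta[idx, ] <- 0.9 * beta_opt$m$beta[idx, ] + 0.1 * gb
        beta_opt$v$beta[idx, ] <- 0.999 * beta_opt$v$beta[idx, ] + 0.001 * gb^2
        beta[idx, ] <- beta[idx, ] -
          lr_ep * (beta_opt$m$beta[idx, ] / c1) /
            (sqrt(beta_opt$v$beta[idx, ] / c2) + 1e-8)
        acc <- acc + c(res$loss1, res$loss2, res$kl, res$total) * B
      }
      history[ep, 2:5] <- acc / N
      history$seconds[ep] <- proc.time()[["elapsed"]] - t0
      if (verbose) {
        message(sprintf("epoch %3d  loss1 %.5f  loss2 %.5f  kl %.4f  total %.5f",
                        ep, history$loss1[ep], history$loss2[ep],
                        history$kl[ep], history$total[ep]))
      }
    }

    structure(list(feature_map = fm, encoder = enc, decoder = dec,
                   beta = beta, latent_dim = latent_dim,
                   scale = list(mean = mu, sd = sdv), P = P,
                   kl_weight = kl_weight, history = history,
                   meta = list(seed = as.integer(seed),
                               prior = draws$meta$generator %||% "unknown",
                               prior_seed = draws$meta$seed,
                               n_draws = N, k_points = K,
                               arch = arch, config_hash = config_hash(arch))),
              class = "pivae")
  })
}

#' @export
print.pivae <- function(x, ...) {
  cat(sprintf("<pivae> stochastic-process prior (latent dim %d, basis dim %d, %d channel%s)\n",
              x$latent_dim, ncol(x$beta), x$P, if (x$P > 1) "s" else ""))
  cat(sprintf("  trained on %d draws x %d points from prior '%s'\n",
              x$meta$n_draws, x$meta$k_points, x$meta$prior))
  h <- x$history
  cat(sprintf("  final losses: loss1 %.4g, loss2 %.4g, kl %.4g (epoch %d)\n",
              h$loss1[nrow(h)], h$loss2[nrow(h)], h$kl[nrow(h)], nrow(h)))
  invisible(x)
}

#' @export
summary.pivae <- function(object, ...) {
  print(object)
  print(object$feature_map)
  cat(sprintf("  value scale: mean %s, sd %s\n",
              paste(signif(object$scale$mean, 4), collapse = "/"),
              paste(signif(object$scale$sd, 4), collapse = "/")))
  cat(sprintf("  config hash %s, seed %d\n", object$meta$config_hash,
              object$meta$seed))
  invisible(object)
}

#' @export
coef.pivae <- function(object, ...) object$beta

#' Simulate sample paths from a trained pi-VAE prior
#'
#' Draws latent vectors \eqn{z \sim N(0, I)} (or uses those supplied) and
#' evaluates the deterministic sample path
#' \eqn{f(s) = d(z)^\top \Phi(s)} at the requested locations. For a fixed
#' `z` the path is a deterministic function defined for arbitrary locations;
#' only the frozen decoder and feature map are used.
#'
#' @param object A fitted [pivae()] model.
#' @param nsim Number of sample paths.
#' @param seed Optional seed for the latent draws.
#' @param locations Locations at which to evaluate the paths.
#' @param z Optional `nsim x L` matrix (or length-L vector) of latent values;
#'   overrides random draws.
#' @param ... Unused.
#' @return For single-channel models an `n_locations x nsim` matrix; for
#'   multi-channel models an `n_locations x P x nsim` array. Values are on
#'   the original (unstandardised) scale.
#' @export
simulate.pivae <- function(object, nsim = 1, seed = NULL, locations, z = NULL,
                           ...) {
  L <- object$latent_dim
  if (is.null(z)) {
    z <- if (is.null(seed)) matrix(stats::rnorm(nsim * L), nsim, L)
         else with_seed(seed, matrix(stats::rnorm(nsim * L), nsim, L))
  }
  if (!is.matrix(z)) {
    if (length(z) %% L != 0) {
      stop_pivae("z must have length (a multiple of) ", L,
                 class = "pivae_validation_error")
    }
    z <- matrix(z, ncol = L, byrow = TRUE)
  }
  if (ncol(z) != L) {
    stop_pivae("z must have width ", L, class = "pivae_validation_error")
  }
  nsim <- nrow(z)
  # evaluate the feature map one location at a time: each location's value
  # must be exactly independent of which other locations are evaluated
  # (finite-marginal consistency is asserted bitwise), and batched BLAS
  # kernels do not guarantee row-count-independent rounding
  fm <- object$feature_map
  s_mat <- as_location_matrix(locations, fm$D)
  phi <- t(vapply(seq_len(nrow(s_mat)), function(i)
    as.numeric(feature_map_apply(fm, s_mat[i, , drop = FALSE])),
    numeric(fm$F_dim * fm$P)))
  n <- nrow(phi); F_dim <- ncol(object$beta); P <- object$P
  betahat <- decode(z, object$decoder)           # nsim x F
  out <- array(0, c(n, P, nsim))
  for (p in seq_len(P)) {
    cols <- (p - 1L) * F_dim + seq_len(F_dim)
    Phi_p <- phi[, cols, drop = FALSE]
    # rowSums accumulates each location independently of the batch size,
    # keeping sample-path values bitwise independent of companion locations
    fp <- vapply(seq_len(nsim), function(i)
      rowSums(Phi_p * rep(betahat[i, ], each = n)), numeric(n))
    out[, p, ] <- object$scale$mean[p] + object$scale$sd[p] * fp
  }
  if (P == 1L) out <- matrix(out[, 1L, ], n, nsim)
  attr(out, "z") <- z
  out
}

#' @export
plot.pivae <- function(x, nsim = 10, locations = NULL, seed = 1, ...) {
  if (is.null(locations)) {
    stop_pivae("supply `locations` at which to draw sample paths",
               class = "pivae_validation_error")
  }
  f <- simulate(x, nsim = nsim, seed = seed, locations = locations)
  if (x$P > 1L) f <- matrix(f[, 1L, ], dim(f)[1], nsim)
  graphics::matplot(locations, f, type = "l", lty = 1,
                    xlab = "location", ylab = "f(s)",
                    main = "pi-VAE prior sample paths", ...)
  invisible(x)
}
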