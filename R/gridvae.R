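#' Fit a plain variational autoencoder on fixed-grid function draws
#'
#' The finite-dimensional precursor of [pivae()]: function realisations
#' observed on one shared grid are treated as vectors, and a standard VAE
#' (encoder to a latent Gaussian, decoder back to the grid) is trained with a
#' Gaussian reconstruction likelihood plus the KL regulariser. A single
#' observation standard deviation of the reconstruction likelihood is learned
#' jointly (as a log-parameter), so the reconstruction and KL terms are
#' automatically balanced. The trained decoder is a prior over grid-valued
#' random vectors: inference and prediction are only possible at the grid
#' locations, which is exactly the limitation the pi-VAE removes.
#'
#' @param x Draw matrix (`n_draws x n_grid`), e.g. from [draw_grid_gp()].
#' @param grid Grid locations (taken from `attr(x, "grid")` when present).
#' @param latent_dim Latent dimension L.
#' @param hidden Hidden-layer widths of encoder (reversed for the decoder).
#' @param epochs,batch_size,lr Adam schedule.
#' @param kl_weight Weight of the KL term.
#' @param seed Integer seed; training is bitwise reproducible per seed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `gridvae` with `encoder`, `decoder`, `grid`,
#'   `scale`, `history`, `meta`.
#' @seealso [fit_pivae()] for posterior inference with the trained decoder.
#' @export
gridvae <- function(x, grid = attr(x, "grid"), latent_dim = 10,
                    hidden = c(64, 32), epochs = 200, batch_size = 100,
                    lr = 1e-3, kl_weight = 1, seed = 1, verbose = FALSE) {
  stopifnot(is.matrix(x))
  if (is.null(grid)) grid <- seq_len(ncol(x))
  stopifnot(length(grid) == ncol(x))
  N <- nrow(x); G <- ncol(x)
  latent_dim <- check_count(latent_dim, "latent_dim")
  batch_size <- min(check_count(batch_size, "batch_size"), N)

  mu <- mean(x); sdv <- stats::sd(as.vector(x)); if (sdv == 0) sdv <- 1
  xs <- (x - mu) / sdv

  arch <- list(latent_dim = latent_dim, hidden = hidden, epochs = epochs,
               batch_size = batch_size, lr = lr, kl_weight = kl_weight)

  with_seed(seed, {
    enc <- mlp_init(c(G, hidden, 2L * latent_dim))
    dec <- mlp_init(c(latent_dim, rev(hidden), G))
    params <- c(net_params(enc, "enc"), net_params(dec, "dec"),
                list(log_sigma = 0))   # reconstruction sd (log scale)
    opt <- adam_init(params)

    n_batches <- ceiling(N / batch_size)
    history <- data.frame(epoch = seq_len(epochs), recon = NA_real_,
                          kl = NA_real_, total = NA_real_, sigma = NA_real_)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(N)
      acc <- c(recon = 0, kl = 0, total = 0)
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * batch_size + 1L):min(bi * batch_size, N)]
        B <- length(idx)
        xb <- xs[idx, , drop = FALSE]
        enc_fw <- mlp_forward(enc, xb, cache = TRUE)
        mu_z <- enc_fw$out[, seq_len(latent_dim), drop = FALSE]
        raw <- enc_fw$out[, latent_dim + seq_len(latent_dim), drop = FALSE]
        sd_z <- softplus(raw)
        eps <- matrix(stats::rnorm(B * latent_dim), B, latent_dim)
        z <- mu_z + sd_z * eps
        dec_fw <- mlp_forward(dec, z, cache = TRUE)
        xhat <- dec_fw$out
        sig2 <- exp(2 * params$log_sigma)
        resid <- xhat - xb
        # negative Gaussian log-likelihood per draw (constants dropped)
        recon <- sum(resid^2) / (2 * sig2 * B) + G * params$log_sigma
        kl <- 0.5 * sum(sd_z^2 + mu_z^2 - 1 - 2 * log(sd_z)) / B
        total <- recon + kl_weight * kl
        if (!is.finite(total)) {
          stop_pivae("training loss diverged (non-finite) at epoch ", ep,
                     class = "pivae_numerical_error")
        }
        dXhat <- resid / (sig2 * B)
        dec_bp <- mlp_backprop(dec, dec_fw, dXhat)
        dZ <- dec_bp$X
        dmu <- dZ + kl_weight * mu_z / B
        dsd <- dZ * eps + kl_weight * (sd_z - 1 / sd_z) / B
        enc_bp <- mlp_backprop(enc, enc_fw, cbind(dmu, dsd * sigmoid(raw)))
        g_logsig <- -sum(resid^2) / (sig2 * B) + G
        grads <- c(net_grads(enc_bp, "enc"), net_grads(dec_bp, "dec"),
                   list(log_sigma = g_logsig))
        st <- adam_step(opt, params, grads, lr = lr)
        opt <- st$state; params <- st$params
        enc <- net_from_params(enc, params, "enc")
        dec <- net_from_params(dec, params, "dec")
        acc <- acc + c(recon, kl, total) * B
      }
      history[ep, 2:4] <- acc / N
      history$sigma[ep] <- exp(params$log_sigma)
      if (verbose) {
        message(sprintf("epoch %3d  recon %.4f  kl %.4f  total %.4f  sigma %.4f",
                        ep, history$recon[ep], history$kl[ep],
                        history$total[ep], history$sigma[ep]))
      }
    }
    structure(list(encoder = enc, decoder = dec, grid = grid,
                   latent_dim = latent_dim, P = 1L,
                   scale = list(mean = mu, sd = sdv),
                   recon_sigma = exp(params$log_sigma),
                   history = history,
                   meta = list(seed = as.integer(seed), n_draws = N,
                               arch = arch, config_hash = config_hash(arch))),
              class = "gridvae")
  })
}

#' @export
print.gridvae <- function(x, ...) {
  cat(sprintf("<gridvae> fixed-grid VAE prior (latent dim %d, grid size %d)\n",
              x$latent_dim, length(x$grid)))
  h <- x$history
  cat(sprintf("  trained on %d draws; final recon %.4g, kl %.4g, recon sd %.4g\n",
              x$meta$n_draws, h$recon[nrow(h)], h$kl[nrow(h)], x$recon_sigma))
  invisible(x)
}

#' Simulate grid-valued draws from a trained fixed-grid VAE prior
#'
#' @param object A fitted [gridvae()] model.
#' @param nsim Number of draws.
#' @param seed Optional seed for the latent draws.
#' @param z Optional latent matrix overriding random draws.
#' @param ... Unused.
#' @return A `n_grid x nsim` matrix on the original scale.
#' @export
simulate.gridvae <- function(object, nsim = 1, seed = NULL, z = NULL, ...) {
  L <- object$latent_dim
  if (is.null(z)) {
    z <- if (is.null(seed)) matrix(stats::rnorm(nsim * L), nsim, L)
         else with_seed(seed, matrix(stats::rnorm(nsim * L), nsim, L))
  }
  if (!is.matrix(z)) z <- matrix(z, ncol = L)
  xhat <- decode(z, object$decoder)
  out <- t(object$scale$mean + object$scale$sd * xhat)
  attr(out, "z") <- z
  out
}
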