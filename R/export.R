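#' Export a trained prior for external probabilistic-programming backends
#'
#' Stage-2 inference needs only a standard-normal prior and the deterministic
#' decoder/feature map, so any probabilistic programming language can host a
#' trained model. `export_model` writes (i) a JSON data file with every
#' array the log density needs (layer weights, activation tags, feature-map
#' parameters, scaling, likelihood spec) and (ii) a Stan-style template
#' program wired to those data. `exported_log_density` is an independent
#' reference evaluator of the exported JSON (it does not touch the R model
#' object), used to verify that the exported description reproduces
#' [pivae_log_posterior()].
#'
#' @param object A fitted [pivae()] model (dense feature-map/decoder layers).
#' @param likelihood A [likelihood_gaussian()] or
#'   [likelihood_poisson_process()].
#' @param file Base path; writes `<file>.json` and `<file>.stan`.
#' @return Invisibly, a list with the two file paths.
#' @export
export_model <- function(object, likelihood = likelihood_gaussian(), file) {
  stopifnot(inherits(object, "pivae"))
  fm <- object$feature_map
  if (fm$kind != "kernel") {
    stop_pivae("only kernel-layer feature maps can be exported",
               class = "pivae_validation_error")
  }
  pack_net <- function(net) list(
    sizes = net$sizes,
    weights = lapply(net$W, identity),
    biases = lapply(net$b, identity),
    activation = "tanh_hidden_linear_output")
  data <- list(
    format = "pivae_export", version = 1L,
    latent_dim = object$latent_dim,
    basis_dim = ncol(object$beta),
    channels = object$P,
    feature_map = list(flavour = fm$flavour, centres = fm$centres,
                       log_lengthscale = fm$log_lengthscale,
                       net = pack_net(fm$net)),
    decoder = pack_net(object$decoder),
    scale = object$scale,
    likelihood = unclass(likelihood))
  json_path <- paste0(file, ".json")
  stan_path <- paste0(file, ".stan")
  jsonlite::write_json(data, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(stan_template(likelihood$family), stan_path)
  invisible(list(json = json_path, stan = stan_path))
}

stan_template <- function(family) {
  lik_block <- if (family == "gaussian") c(
    "  real<lower=0> sigma;",
    "} ",
    "model {",
    "  z ~ std_normal();",
    "  sigma ~ normal(0, noise_scale);",
    "  y ~ normal(f, sigma);") else c(
    "} ",
    "model {",
    "  z ~ std_normal();",
    "  // point process: channel 1 = log-intensity at events, channel 2 = integral",
    "  target += sum(f_log_intensity) - f_integral_at_horizon;")
  c("// template generated by the pivae R package; arrays in the .json data file",
    "// f(s) = scale_mean + scale_sd * dot(decode(z), Phi(s)) with Phi the",
    "// kernel layer (trainable centres) composed with a tanh MLP.",
    "data {",
    "  // see <file>.json: layer weights, centres, lengthscale, scaling",
    "}",
    "parameters {",
    "  vector[latent_dim] z;",
    lik_block,
    "}")
}

#' @rdname export_model
#' @param json Path to the exported `.json` data file.
#' @param z Latent vector.
#' @param s,y Observations (as in [pivae_log_posterior()]).
#' @param sigma Noise standard deviation (Gaussian likelihood).
#' @return `exported_log_density` returns the scalar log density implied by
#'   the exported arrays.
#' @export
exported_log_density <- function(json, z, s = NULL, y = NULL, sigma = NULL) {
  d <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!identical(d$format, "pivae_export")) {
    stop_pivae("not a pivae export file: ", json, class = "pivae_io_error")
  }
  # undo jsonlite's simplification: equal-shaped per-layer arrays may come
  # back as one stacked matrix/array instead of a list
  as_layer_list <- function(x) {
    if (is.list(x)) return(lapply(x, function(v) if (is.null(dim(v))) v else as.matrix(v)))
    if (length(dim(x)) == 3L) return(lapply(seq_len(dim(x)[1]), function(i) {
      m <- x[i, , ]
      matrix(m, dim(x)[2], dim(x)[3])
    }))
    if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
    list(x)
  }
  fwd <- function(net, X) {
    Ws <- as_layer_list(net$weights)
    bs <- as_layer_list(net$biases)
    nl <- length(Ws)
    H <- X
    for (l in seq_len(nl)) {
      H <- sweep(H %*% as.matrix(Ws[[l]]), 2L, as.numeric(bs[[l]]), "+")
      if (l < nl) H <- tanh(H)
    }
    H
  }
  L <- d$latent_dim
  lp <- -0.5 * sum(z^2)
  if (is.null(s)) return(lp)
  s <- if (is.matrix(s)) s else matrix(s, ncol = 1L)
  J <- nrow(s)
  if (d$likelihood$family == "poisson_process") {
    # append the horizon (channel variant) or the quadrature grid
    if (identical(d$likelihood$integral, "channel")) {
      s <- rbind(s, d$likelihood$horizon)
    } else {
      s <- rbind(s, matrix(seq(0, d$likelihood$horizon,
                               length.out = d$likelihood$n_quad), ncol = 1L))
    }
  }
  C <- as.matrix(d$feature_map$centres)
  ell <- exp(d$feature_map$log_lengthscale)
  d2 <- outer(rowSums(s^2), rowSums(C^2), "+") - 2 * s %*% t(C)
  d2 <- pmax(d2, 0)
  E <- if (d$feature_map$flavour == "rbf") exp(-d2 / ell^2) else {
    a <- sqrt(3) / ell
    (1 + a * sqrt(d2)) * exp(-a * sqrt(d2))
  }
  phi <- fwd(d$feature_map$net, E)
  bh <- as.numeric(fwd(d$decoder, matrix(z, nrow = 1L)))
  F_dim <- d$basis_dim
  f <- sapply(seq_len(d$channels), function(p)
    d$scale$mean[p] + d$scale$sd[p] *
      as.numeric(phi[, (p - 1L) * F_dim + seq_len(F_dim), drop = FALSE] %*% bh))
  f <- matrix(f, nrow(s), d$channels)
  if (d$likelihood$family == "gaussian") {
    sig <- sigma %||% d$likelihood$sigma
    if (is.null(sig)) {
      stop_pivae("sigma required for the Gaussian exported density",
                 class = "pivae_validation_error")
    }
    J <- length(y)
    r <- as.numeric(y) - f[, 1L]
    lp <- lp - 0.5 * sum(r^2) / sig^2 - J * log(sig)
    if (is.null(d$likelihood$sigma)) {
      lp <- lp - 0.5 * sig^2 / d$likelihood$noise_scale^2 + log(sig)
    }
  } else if (identical(d$likelihood$integral, "channel")) {
    lp <- lp + sum(f[seq_len(J), 1L]) - f[J + 1L, 2L]
  } else {
    nq <- d$likelihood$n_quad
    dq <- d$likelihood$horizon / (nq - 1)
    wq <- rep(dq, nq); wq[c(1, nq)] <- dq / 2
    lamq <- exp(f[J + seq_len(nq), 1L])
    lp <- lp + sum(f[seq_len(J), 1L]) - sum(wq * lamq)
  }
  lp
}
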