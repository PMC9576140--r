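# Shared fixtures: tiny hand-built models with known parameters, constructed
# in code so every expected value can be verified by direct arithmetic.

# A pivae-classed model with a linear decoder W (identity by default) and a
# Cholesky feature map on `grid`, so that f(s_i) = (L %*% W %*% z)_i exactly.
make_linear_cholesky_model <- function(kernel = kernel_spec("rbf", 0.5),
                                       grid = seq(0, 1, length.out = 5),
                                       W = NULL, latent_dim = length(grid)) {
  fm <- cholesky_feature_map(kernel, grid)
  G <- fm$F_dim
  # decoder is one linear layer: betahat = z %*% W_dec (L x G weights)
  W_dec <- W %||% diag(1, latent_dim, G)
  dec <- list(W = list(W_dec), b = list(numeric(G)),
              sizes = c(latent_dim, G))
  enc <- list(W = list(matrix(0, G, 2 * latent_dim)),
              b = list(numeric(2 * latent_dim)),
              sizes = c(G, 2 * latent_dim))
  structure(list(feature_map = fm, encoder = enc, decoder = dec,
                 beta = matrix(0, 1, G), latent_dim = latent_dim,
                 scale = list(mean = 0, sd = 1), P = 1L, kl_weight = 1,
                 history = data.frame(),
                 meta = list(seed = 0L, prior = "handmade",
                             n_draws = 0L, k_points = 0L,
                             arch = list(), config_hash = "0")),
            class = "pivae")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny trained pivae on GP draws, shared across tests that just need some
# trained model (cached per session).
tiny_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- draw_gp_functions(kernel_spec("rbf", 1.5), n_draws = 300,
                             k_points = 15, domain = c(0, 1), seed = 11)
      cache <<- pivae(d, latent_dim = 4, n_centres = 8, basis_dim = 10,
                      phi_hidden = c(10), enc_hidden = c(10),
                      dec_hidden = c(10), epochs = 40, batch_size = 50,
                      seed = 12)
    }
    cache
  }
})
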