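# Minimal fully-connected network machinery: forward pass with cache,
# reverse-mode gradients, and Adam. Hidden layers use tanh, the output layer
# is linear. Weight matrices are (n_in x n_out); inputs are row-batches.

# tanh evaluated through exp (markedly faster than base tanh on large
# matrices); the |x| formulation avoids overflow for large negative inputs
tanh_fast <- function(x) {
  e <- exp(-2 * abs(x))
  r <- (1 - e) / (1 + e)
  r[x < 0] <- -r[x < 0]
  r
}

mlp_init <- function(sizes) {
  # sizes: c(n_in, hidden..., n_out); Glorot-uniform weights, zero biases.
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X, cache = FALSE) {
  nl <- length(net$W)
  A <- list(X)
  H <- X
  for (l in seq_len(nl)) {
    H <- H %*% net$W[[l]]
    H <- H + rep(net$b[[l]], each = nrow(H))
    if (l < nl) H <- tanh_fast(H)
    if (cache) A[[l + 1L]] <- H
  }
  if (cache) list(out = H, acts = A) else H
}

# Gradients of sum(G * out) w.r.t. weights, biases and the input batch.
# `fw` is the cached forward pass from mlp_forward(..., cache = TRUE).
mlp_backprop <- function(net, fw, G) {
  nl <- length(net$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- G
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (1 - fw$acts[[l + 1L]]^2)
    gW[[l]] <- crossprod(fw$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, X = delta)
}

# ---- flat parameter-list utilities (used by Adam) -------------------------

# A "param list" is a named list of numeric arrays. Gradients mirror its
# structure. Adam keeps first/second-moment lists of the same shape.

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

# Flatten / unflatten a network's weights into a param list with a prefix.
net_params <- function(net, prefix) {
  out <- list()
  for (l in seq_along(net$W)) {
    out[[paste0(prefix, "_W", l)]] <- net$W[[l]]
    out[[paste0(prefix, "_b", l)]] <- net$b[[l]]
  }
  out
}

net_from_params <- function(net, params, prefix) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- params[[paste0(prefix, "_W", l)]]
    net$b[[l]] <- params[[paste0(prefix, "_b", l)]]
  }
  net
}

net_grads <- function(bp, prefix) {
  out <- list()
  for (l in seq_along(bp$W)) {
    out[[paste0(prefix, "_W", l)]] <- bp$W[[l]]
    out[[paste0(prefix, "_b", l)]] <- bp$b[[l]]
  }
  out
}
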