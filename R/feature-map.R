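#' Kernel-flavoured feature layers
#'
#' First layer of the trainable basis \eqn{\Phi(s)}: unnormalised kernel
#' evaluations of a batch of locations against a set of (trainable) centres.
#' `rbf_features` uses \eqn{\exp(-\|s - c_m\|^2/\ell^2)}; `matern32_features`
#' uses the Matern-3/2 profile \eqn{(1 + \sqrt3 r/\ell)\exp(-\sqrt3 r/\ell)}
#' with \eqn{r = \|s - c_m\|}.
#'
#' @param s Location batch: numeric matrix (rows are locations) or vector
#'   (1-D).
#' @param centres `M x D` matrix of centres.
#' @param lengthscale Positive lengthscale.
#' @return An `n x M` feature matrix.
#' @examples
#' rbf_features(0, centres = matrix(1), lengthscale = 1)  # exp(-1)
#' @export
rbf_features <- function(s, centres, lengthscale) {
  check_scalar_positive(lengthscale, "lengthscale")
  s <- as_location_matrix(s, ncol(centres))
  exp(-pairwise_sqdist(s, centres) / lengthscale^2)
}

#' @rdname rbf_features
#' @export
matern32_features <- function(s, centres, lengthscale) {
  check_scalar_positive(lengthscale, "lengthscale")
  s <- as_location_matrix(s, ncol(centres))
  a <- sqrt(3) / lengthscale
  r <- sqrt(pairwise_sqdist(s, centres))
  (1 + a * r) * exp(-a * r)
}

as_location_matrix <- function(s, D) {
  if (!is.matrix(s)) {
    if (D == 1L) s <- matrix(s, ncol = 1L)
    else if (length(s) == D) s <- matrix(s, nrow = 1L)
    else stop_pivae("locations must be a matrix with ", D, " columns",
                    class = "pivae_validation_error")
  }
  if (ncol(s) != D) {
    stop_pivae("location dimension ", ncol(s), " does not match feature map (",
               D, ")", class = "pivae_validation_error")
  }
  s
}

# Build a trainable feature map: kernel layer (M centres, shared lengthscale)
# composed with an MLP (tanh hidden layers, linear output of width F * P).
new_feature_map <- function(flavour, centres, log_lengthscale, net, F_dim, P) {
  structure(list(kind = "kernel", flavour = flavour, centres = centres,
                 log_lengthscale = log_lengthscale, net = net,
                 D = ncol(centres), M = nrow(centres), F_dim = F_dim, P = P),
            class = "pivae_feature_map")
}

feature_map_init <- function(flavour, domain, n_centres, hidden, F_dim, P = 1L) {
  domain <- as_domain(domain)
  D <- ncol(domain)
  centres <- sapply(seq_len(D), function(j)
    stats::runif(n_centres, domain[1, j], domain[2, j]))
  centres <- matrix(centres, n_centres, D)
  # lengthscale initialised to a quarter of the mean domain width
  ell0 <- mean(domain[2, ] - domain[1, ]) / 4
  net <- mlp_init(c(n_centres, hidden, F_dim * P))
  new_feature_map(flavour, centres, log(ell0), net, F_dim, P)
}

kernel_layer_forward <- function(fm, s) {
  ell <- exp(fm$log_lengthscale)
  d2 <- pairwise_sqdist(s, fm$centres)
  if (fm$flavour == "rbf") {
    E <- exp(-d2 / ell^2)
  } else {
    a <- sqrt(3) / ell
    E <- (1 + a * sqrt(d2)) * exp(-a * sqrt(d2))
  }
  list(E = E, d2 = d2)
}

# Gradients of sum(G * E) w.r.t. centres and log-lengthscale.
kernel_layer_backprop <- function(fm, s, kf, G) {
  ell <- exp(fm$log_lengthscale)
  if (fm$flavour == "rbf") {
    dE_dd2 <- -kf$E / ell^2
    g_logell <- sum(G * kf$E * 2 * kf$d2 / ell^2)
  } else {
    a <- sqrt(3) / ell
    r <- sqrt(kf$d2)
    expar <- exp(-a * r)
    dE_dd2 <- -(a^2 / 2) * expar
    g_logell <- sum(G * a^2 * kf$d2 * expar)
  }
  TT <- G * dE_dd2
  g_centres <- 2 * (fm$centres * colSums(TT) - crossprod(TT, s))
  list(centres = g_centres, log_lengthscale = g_logell)
}

#' Evaluate a feature map at a batch of locations
#'
#' Deterministic map from locations to the F-dimensional basis features
#' (F x P columns when the model has P output channels): kernel layer against
#' the centres, then the feed-forward network. Defined for arbitrary
#' locations, not only those seen in training.
#'
#' @param fm A feature map (component `$feature_map` of a fitted [pivae()]
#'   model, or a [cholesky_feature_map()]).
#' @param s Location batch (matrix with D columns, or vector for 1-D).
#' @return An `n x (F*P)` numeric matrix.
#' @export
feature_map_apply <- function(fm, s) {
  stopifnot(inherits(fm, "pivae_feature_map"))
  if (fm$kind == "cholesky") return(cholesky_feature_lookup(fm, s))
  s <- as_location_matrix(s, fm$D)
  mlp_forward(fm$net, kernel_layer_forward(fm, s)$E)
}

#' @export
print.pivae_feature_map <- function(x, ...) {
  if (x$kind == "cholesky") {
    cat(sprintf("<pivae_feature_map> Cholesky lookup on %d grid points\n",
                x$F_dim))
  } else {
    cat(sprintf(
      "<pivae_feature_map> %s layer: %d centres in %d-D (lengthscale %.4g), MLP %s\n",
      x$flavour, x$M, x$D, exp(x$log_lengthscale),
      paste(x$net$sizes, collapse = "-")))
  }
  invisible(x)
}

#' Cholesky feature map (Gaussian-process equivalence oracle)
#'
#' A non-trainable feature map defined only on a fixed grid: the feature
#' vector of grid point \eqn{s_i} is the i-th column of \eqn{L^\top}, where
#' \eqn{L} is the Cholesky factor of the kernel Gram matrix. With
#' coefficients \eqn{\beta \sim N(0, I)} and a linear decoder, the implied
#' process \eqn{f(s_i) = \beta^\top \Phi(s_i)} is exactly a zero-mean Gaussian
#' process with the kernel's covariance, which makes this map the exactness
#' oracle for the learned model.
#'
#' @param kernel A [kernel_spec()].
#' @param grid Numeric vector (1-D) or matrix of distinct grid locations.
#' @param jitter Diagonal jitter fraction (of the kernel variance) for the
#'   factorisation; set to 0 for exact machine-precision equivalence on
#'   well-conditioned grids.
#' @return A `pivae_feature_map` of kind `"cholesky"`.
#' @export
cholesky_feature_map <- function(kernel, grid, jitter = 0) {
  if (!is.matrix(grid)) grid <- matrix(grid, ncol = 1L)
  if (anyDuplicated(grid)) {
    stop_pivae("grid locations must be distinct", class = "pivae_validation_error")
  }
  L <- gram_chol(kernel, grid, jitter = jitter, context = "Cholesky feature map")
  structure(list(kind = "cholesky", grid = grid, Lt = t(L), D = ncol(grid),
                 F_dim = nrow(grid), P = 1L),
            class = "pivae_feature_map")
}

cholesky_feature_lookup <- function(fm, s) {
  s <- as_location_matrix(s, fm$D)
  idx <- match_grid_rows(s, fm$grid)
  if (anyNA(idx)) {
    stop_pivae("location not on the Cholesky feature map's grid",
               class = "pivae_lookup_error")
  }
  # row j of the output is the idx[j]-th column of L^T
  t(fm$Lt[, idx, drop = FALSE])
}

match_grid_rows <- function(s, grid, tol = 1e-9) {
  apply(s, 1L, function(row) {
    d <- rowSums(sweep(grid, 2L, row)^2)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  })
}
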