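#' Covariance kernel specification
#'
#' Describes a stationary covariance kernel used both by the prior samplers
#' (to draw Gaussian-process training functions) and by the Cholesky feature
#' map. Supported families are the squared-exponential (`"rbf"`,
#' \eqn{k(\delta) = \sigma^2 \exp(-\delta^2/\ell^2)}) and the Matern 3/2 and
#' 5/2 kernels.
#'
#' When `lengthscale_range` is supplied, prior samplers resample a fresh
#' lengthscale per function draw, log-uniformly over the range: ranges used in
#' practice span orders of magnitude, so a log scale is the natural one.
#'
#' @param family One of `"rbf"`, `"matern32"`, `"matern52"`.
#' @param lengthscale Positive lengthscale, in input units.
#' @param variance Positive marginal variance \eqn{\sigma^2}.
#' @param lengthscale_range Optional length-2 numeric; when set, each function
#'   draw uses its own lengthscale sampled log-uniformly from this range.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("rbf", lengthscale = 0.5)
#' kernel_gram(k, matrix(c(0, 0.25, 1), ncol = 1))
#' @export
kernel_spec <- function(family = c("rbf", "matern32", "matern52"),
                        lengthscale = 1, variance = 1,
                        lengthscale_range = NULL) {
  family <- match.arg(family)
  check_scalar_positive(lengthscale, "lengthscale")
  check_scalar_positive(variance, "variance")
  if (!is.null(lengthscale_range)) {
    if (length(lengthscale_range) != 2L || any(lengthscale_range <= 0) ||
        lengthscale_range[1] >= lengthscale_range[2]) {
      stop_pivae("lengthscale_range must be an increasing positive pair",
                 class = "pivae_validation_error")
    }
  }
  structure(list(family = family, lengthscale = lengthscale,
                 variance = variance, lengthscale_range = lengthscale_range),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s: lengthscale %g, variance %g%s\n", x$family,
              x$lengthscale, x$variance,
              if (is.null(x$lengthscale_range)) "" else
                sprintf(", per-draw lengthscale in [%g, %g] (log-uniform)",
                        x$lengthscale_range[1], x$lengthscale_range[2])))
  invisible(x)
}

# Kernel profile as a function of distance r >= 0.
kernel_profile <- function(family, r, lengthscale, variance) {
  switch(family,
    rbf = variance * exp(-(r / lengthscale)^2),
    matern32 = {
      a <- sqrt(3) * r / lengthscale
      variance * (1 + a) * exp(-a)
    },
    matern52 = {
      a <- sqrt(5) * r / lengthscale
      variance * (1 + a + a^2 / 3) * exp(-a)
    },
    stop_pivae("unknown kernel family: ", family,
               class = "pivae_validation_error"))
}

#' Kernel Gram matrix
#'
#' Dense covariance matrix of a kernel evaluated on a set of locations.
#'
#' @param kernel A [kernel_spec()].
#' @param x Numeric matrix of locations (rows) or a numeric vector (1-D).
#' @param lengthscale Optional override of the kernel's lengthscale (used for
#'   per-draw resampling).
#' @return A symmetric positive semi-definite matrix.
#' @export
kernel_gram <- function(kernel, x, lengthscale = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  ell <- lengthscale %||% kernel$lengthscale
  r <- sqrt(pmax(pairwise_sqdist(x, x), 0))
  m <- kernel_profile(kernel$family, r, ell, kernel$variance)
  matrix(m, nrow(x), nrow(x))
}

# Squared Euclidean distances between rows of a (n x d) and rows of b (m x d).
pairwise_sqdist <- function(a, b) {
  d2 <- -2 * tcrossprod(a, b)
  d2 <- d2 + rowSums(a^2)                      # recycles down columns
  d2 <- d2 + rep(rowSums(b^2), each = nrow(a)) # per-column constants
  d2[d2 < 0] <- 0
  d2
}

# Cholesky factor of Gram + jitter. Returns lower-triangular L with
# L %*% t(L) = K + jitter * variance * I. Errors with context on failure.
gram_chol <- function(kernel, x, lengthscale = NULL, jitter = 1e-6,
                      context = "Gram matrix") {
  K <- kernel_gram(kernel, x, lengthscale)
  K <- K + diag(jitter * kernel$variance, nrow(K))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    stop_pivae("Cholesky factorisation failed for ", context,
               " (non-positive-definite after jitter)",
               class = "pivae_numerical_error")
  }
  t(ch)
}
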