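#' Sets of function draws from a stochastic-process prior
#'
#' Stage-1 training data: `n_draws` function realisations, each observed at
#' `k_points` locations. Locations are a `N x K x D` array, values a
#' `N x K x P` array (`P = 1` except for log-Gaussian Cox process draws, which
#' carry intensity and cumulative-integral channels, `P = 2`).
#'
#' @name function_draws
NULL

new_function_draws <- function(locations, values, events = NULL, meta = list()) {
  stopifnot(length(dim(locations)) == 3L, length(dim(values)) == 3L)
  check_finite(locations, "locations")
  check_finite(values, "values")
  if (dim(locations)[1] < 1L || dim(locations)[2] < 1L ||
      dim(locations)[1] != dim(values)[1] || dim(locations)[2] != dim(values)[2]) {
    stop_pivae("locations and values must agree in draws and points",
               class = "pivae_validation_error")
  }
  structure(list(locations = locations, values = values, events = events,
                 meta = meta),
            class = "function_draws")
}

#' @export
print.function_draws <- function(x, ...) {
  d <- dim(x$locations)
  p <- dim(x$values)[3]
  cat(sprintf("<function_draws> %d draws x %d points, input dim %d, %d value channel%s\n",
              d[1], d[2], d[3], p, if (p > 1) "s" else ""))
  if (!is.null(x$meta$generator))
    cat("  generator:", x$meta$generator,
        if (!is.null(x$meta$seed)) sprintf("(seed %d)", x$meta$seed) else "", "\n")
  invisible(x)
}

#' @export
dim.function_draws <- function(x) dim(x$locations)

#' @rdname function_draws
#' @param x A `function_draws` object.
#' @param ... Unused.
#' @return `as.data.frame` returns a long-format data frame with columns
#'   `draw_id`, `k`, `s_1..s_D`, `y_1..y_P`.
#' @export
as.data.frame.function_draws <- function(x, ...) {
  d <- dim(x$locations); n <- d[1]; k <- d[2]; D <- d[3]
  P <- dim(x$values)[3]
  out <- data.frame(draw_id = rep(seq_len(n), each = k), k = rep(seq_len(k), n))
  for (j in seq_len(D))
    out[[paste0("s_", j)]] <- as.vector(t(x$locations[, , j]))
  for (p in seq_len(P))
    out[[paste0("y_", p)]] <- as.vector(t(x$values[, , p]))
  out
}

#' Persist and restore function-draw sets
#'
#' `write_function_draws` stores a draw set as a single versioned archive
#' (written atomically); with `csv = TRUE` a long-format CSV
#' (`draw_id, k, s_1.., y_1..`) is written instead.
#'
#' @param draws A `function_draws` object.
#' @param path Output/input file path.
#' @param csv Write/read long-format CSV instead of the binary archive.
#' @return `read_function_draws` returns a `function_draws` object.
#' @export
write_function_draws <- function(draws, path, csv = FALSE) {
  stopifnot(inherits(draws, "function_draws"))
  if (csv) {
    utils::write.csv(as.data.frame(draws), path, row.names = FALSE)
  } else {
    atomic_save(list(format = "pivae_function_draws", version = 1L,
                     locations = draws$locations, values = draws$values,
                     events = draws$events, meta = draws$meta), path)
  }
  invisible(path)
}

#' @rdname write_function_draws
#' @export
read_function_draws <- function(path, csv = FALSE) {
  if (csv) {
    df <- utils::read.csv(path)
    n <- max(df$draw_id); k <- max(df$k)
    scol <- grep("^s_", names(df), value = TRUE)
    ycol <- grep("^y_", names(df), value = TRUE)
    loc <- array(NA_real_, c(n, k, length(scol)))
    val <- array(NA_real_, c(n, k, length(ycol)))
    ord <- order(df$draw_id, df$k)
    df <- df[ord, ]
    for (j in seq_along(scol)) loc[, , j] <- matrix(df[[scol[j]]], n, k, byrow = TRUE)
    for (p in seq_along(ycol)) val[, , p] <- matrix(df[[ycol[p]]], n, k, byrow = TRUE)
    return(new_function_draws(loc, val))
  }
  obj <- readRDS(path)
  if (!identical(obj$format, "pivae_function_draws")) {
    stop_pivae("not a function-draws archive: ", path, class = "pivae_io_error")
  }
  if (!identical(obj$version, 1L)) {
    stop_pivae("unknown function-draws archive version: ", obj$version,
               class = "pivae_version_error")
  }
  new_function_draws(obj$locations, obj$values, obj$events, obj$meta)
}

draw_lengthscales <- function(kernel, n) {
  if (is.null(kernel$lengthscale_range)) return(rep(kernel$lengthscale, n))
  lo <- log(kernel$lengthscale_range[1]); hi <- log(kernel$lengthscale_range[2])
  exp(stats::runif(n, lo, hi))
}

#' Draw training functions from a Gaussian-process prior
#'
#' Each of the `n_draws` realisations gets a fresh set of `k_points` locations
#' sampled uniformly in `domain`, and values drawn jointly from a zero-mean
#' Gaussian process with the kernel's Gram covariance. When the kernel carries
#' a `lengthscale_range`, a fresh lengthscale is drawn log-uniformly per
#' realisation.
#'
#' @param kernel A [kernel_spec()].
#' @param n_draws Number of function realisations N.
#' @param k_points Observation locations per realisation K (dense Cholesky:
#'   keep below ~2000).
#' @param domain Either a length-2 interval (1-D) or a `2 x D` matrix whose
#'   rows are lower/upper bounds per input dimension.
#' @param seed Integer seed; draws are reproducible bitwise.
#' @param jitter Diagonal jitter added to the Gram matrix, as a fraction of
#'   the kernel variance.
#' @return A [function_draws] object with `P = 1`.
#' @examples
#' d <- draw_gp_functions(kernel_spec("rbf", 0.3), n_draws = 5, k_points = 20,
#'                        domain = c(0, 1), seed = 1)
#' dim(d)
#' @export
draw_gp_functions <- function(kernel, n_draws, k_points, domain, seed,
                              jitter = 1e-6) {
  stopifnot(inherits(kernel, "kernel_spec"))
  n_draws <- check_count(n_draws, "n_draws")
  k_points <- check_count(k_points, "k_points")
  if (k_points > 2000) {
    stop_pivae("k_points too large for dense Cholesky (<= 2000)",
               class = "pivae_validation_error")
  }
  domain <- as_domain(domain)
  D <- ncol(domain)
  with_seed(seed, {
    ells <- draw_lengthscales(kernel, n_draws)
    loc <- array(0, c(n_draws, k_points, D))
    val <- array(0, c(n_draws, k_points, 1L))
    for (i in seq_len(n_draws)) {
      s <- sapply(seq_len(D), function(j)
        stats::runif(k_points, domain[1, j], domain[2, j]))
      s <- matrix(s, k_points, D)
      L <- gram_chol(kernel, s, ells[i], jitter,
                     context = sprintf("draw %d", i))
      loc[i, , ] <- s
      val[i, , 1L] <- L %*% stats::rnorm(k_points)
    }
    new_function_draws(loc, val,
                       meta = list(generator = "gp", seed = as.integer(seed),
                                   kernel = kernel))
  })
}

as_domain <- function(domain) {
  if (is.matrix(domain)) {
    stopifnot(nrow(domain) == 2L)
  } else {
    stopifnot(length(domain) == 2L)
    domain <- matrix(domain, 2L, 1L)
  }
  if (any(domain[1, ] >= domain[2, ])) {
    stop_pivae("domain must have lower < upper in every dimension",
               class = "pivae_validation_error")
  }
  domain
}

#' Draw Gaussian-process realisations on a shared fixed grid
#'
#' Input for the plain fixed-grid VAE: independent zero-mean GP draws on a
#' common strictly increasing 1-D grid, one Cholesky factorisation reused
#' across all draws.
#'
#' @inheritParams draw_gp_functions
#' @param grid Strictly increasing numeric vector of locations.
#' @return A numeric matrix of dimension `n_draws x length(grid)` with the
#'   grid attached as attribute `"grid"`.
#' @export
draw_grid_gp <- function(kernel, grid, n_draws, seed, jitter = 1e-6) {
  stopifnot(inherits(kernel, "kernel_spec"))
  n_draws <- check_count(n_draws, "n_draws")
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE)) {
    stop_pivae("grid must be strictly increasing", class = "pivae_validation_error")
  }
  L <- gram_chol(kernel, matrix(grid, ncol = 1L), jitter = jitter,
                 context = "grid Gram")
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * length(grid)), length(grid), n_draws)
    t(L %*% z)
  })
  attr(out, "grid") <- grid
  out
}

#' Draw monotone cubic training functions
#'
#' Each realisation is \eqn{f(s) = a s^3 + b s + c} with `a` from a
#' positive-support distribution and `b >= 0`, so every draw is monotone
#' nondecreasing (derivative \eqn{3 a s^2 + b \ge 0}). Defaults:
#' `a ~ LogNormal(0, 0.5)`, `b ~ HalfNormal(1)`, `c ~ Normal(0, 1)`.
#'
#' @inheritParams draw_gp_functions
#' @param domain Finite interval (length 2) over which locations are sampled
#'   uniformly.
#' @param coef List with elements `a_meanlog`, `a_sdlog` (log-normal
#'   parameters for `a`), `b_scale` (half-normal scale for `b`, may be 0 for
#'   `b = 0`), `c_sd` (normal sd for `c`).
#' @return A [function_draws] object with `P = 1`.
#' @export
draw_cubic_functions <- function(n_draws, k_points, domain = c(-6, 6),
                                 coef = list(), seed = 1) {
  n_draws <- check_count(n_draws, "n_draws")
  k_points <- check_count(k_points, "k_points")
  stopifnot(length(domain) == 2L, all(is.finite(domain)), domain[1] < domain[2])
  spec <- utils::modifyList(
    list(a_meanlog = 0, a_sdlog = 0.5, b_scale = 1, c_sd = 1), coef)
  bad <- setdiff(names(spec), c("a_meanlog", "a_sdlog", "b_scale", "c_sd"))
  if (length(bad)) {
    stop_pivae("unknown cubic coefficient fields: ", paste(bad, collapse = ", "),
               class = "pivae_validation_error")
  }
  if (spec$a_sdlog < 0 || spec$b_scale < 0 || spec$c_sd < 0) {
    stop_pivae("cubic coefficient scales must be nonnegative (a has positive support)",
               class = "pivae_validation_error")
  }
  with_seed(seed, {
    a <- stats::rlnorm(n_draws, spec$a_meanlog, spec$a_sdlog)
    b <- abs(stats::rnorm(n_draws, 0, spec$b_scale))
    cc <- stats::rnorm(n_draws, 0, spec$c_sd)
    s <- matrix(stats::runif(n_draws * k_points, domain[1], domain[2]),
                n_draws, k_points)
    y <- a * s^3 + b * s + cc
    new_function_draws(array(s, c(n_draws, k_points, 1L)),
                       array(y, c(n_draws, k_points, 1L)),
                       meta = list(generator = "cubic", seed = as.integer(seed),
                                   coef = spec))
  })
}

#' Draw log-Gaussian Cox process training functionals
#'
#' Per draw: a 1-D GP log-intensity `g` is sampled on a fine reference grid on
#' the unit interval; the time horizon is rescaled so the expected event count
#' (trapezoid integral of \eqn{\lambda = \exp g}) equals `n_events`; events
#' are sampled by thinning against \eqn{\max \lambda}; and at each of the
#' `K = n_events` retained event locations both the intensity
#' \eqn{\lambda(s)} and the cumulative integral
#' \eqn{\Lambda(s) = \int_0^s \lambda(u) du} (trapezoid rule on the reference
#' grid) are recorded as the two value channels.
#'
#' @inheritParams draw_gp_functions
#' @param n_events Target number of events per draw; also the number of
#'   observation locations K.
#' @param grid_size Reference-grid resolution for the log-intensity draw and
#'   the quadrature.
#' @param max_tries Thinning retry budget per draw.
#' @return A [function_draws] object with `P = 2` (intensity, cumulative
#'   integral); `x$events` holds the per-draw event times, and
#'   `x$meta$horizon` the per-draw horizon T.
#' @export
draw_lgcp_functions <- function(kernel, n_draws, n_events, seed,
                                grid_size = 1024L, max_tries = 1000L) {
  stopifnot(inherits(kernel, "kernel_spec"))
  n_draws <- check_count(n_draws, "n_draws")
  n_events <- check_count(n_events, "n_events")
  ref <- seq(0, 1, length.out = grid_size)
  L <- gram_chol(kernel, matrix(ref, ncol = 1L), context = "LGCP reference grid")
  with_seed(seed, {
    loc <- array(0, c(n_draws, n_events, 1L))
    val <- array(0, c(n_draws, n_events, 2L))
    events <- vector("list", n_draws)
    horizon <- numeric(n_draws)
    raw_counts <- integer(n_draws)
    dx <- ref[2] - ref[1]
    for (i in seq_len(n_draws)) {
      g <- as.vector(L %*% stats::rnorm(grid_size))
      lam <- exp(g)
      if (!all(is.finite(lam))) {
        stop_pivae("non-finite intensity in LGCP draw ", i,
                   class = "pivae_numerical_error")
      }
      # expected count on [0,1]; stretch time so the integral equals n_events
      c0 <- sum((lam[-1] + lam[-grid_size]) / 2) * dx
      T_i <- n_events / c0
      # on [0, T_i] the intensity is lam(t / T_i); integral = n_events
      # thinning: homogeneous candidates at rate max(lambda), accepted with
      # probability lambda(u)/max(lambda); expected accepted count = n_events.
      # Realisations with fewer than n_events accepted events are redrawn, and
      # K = n_events locations are subsampled uniformly from the accepted set
      # (the raw accepted counts are kept in meta$raw_counts).
      lam_max <- max(lam)
      ev <- numeric(0)
      tries <- 0L
      raw <- NA_integer_
      while (length(ev) < n_events) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop_pivae("thinning failed to produce enough events in draw ", i,
                     class = "pivae_numerical_error")
        }
        m <- stats::rpois(1, lam_max * T_i)
        if (m == 0) next
        u <- stats::runif(m, 0, T_i)
        lam_u <- stats::approx(ref * T_i, lam, xout = u)$y
        keep <- stats::runif(m) < lam_u / lam_max
        if (is.na(raw)) raw <- sum(keep)
        ev <- u[keep]
      }
      ev <- sort(sample(ev, n_events))
      cum <- c(0, cumsum((lam[-1] + lam[-grid_size]) / 2 * dx * T_i))
      loc[i, , 1L] <- ev
      val[i, , 1L] <- stats::approx(ref * T_i, lam, xout = ev)$y
      val[i, , 2L] <- stats::approx(ref * T_i, cum, xout = ev)$y
      events[[i]] <- ev
      horizon[i] <- T_i
      raw_counts[i] <- raw
    }
    new_function_draws(loc, val, events = events,
                       meta = list(generator = "lgcp", seed = as.integer(seed),
                                   kernel = kernel, horizon = horizon,
                                   n_events = n_events, grid_size = grid_size,
                                   raw_counts = raw_counts))
  })
}
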