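# Convergence diagnostics: split rank-normalised R-hat and bulk effective
# sample size, following the modern definitions used by Stan
# (split chains, rank-normalisation, Geyer initial-monotone-sequence ESS).

split_chains <- function(x) {
  # x: chains x draws matrix -> (2*chains) x floor(draws/2)
  n <- ncol(x); half <- floor(n / 2)
  rbind(x[, seq_len(half), drop = FALSE],
        x[, (n - half + 1):n, drop = FALSE])
}

rank_normalize <- function(x) {
  # fractional ranks over all chains/draws -> normal scores
  r <- matrix(rank(x, ties.method = "average"), nrow(x), ncol(x))
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

rhat_basic <- function(x) {
  # x: chains x draws (already split); classic potential scale reduction
  m <- nrow(x); n <- ncol(x)
  mu <- rowMeans(x)
  B <- n * stats::var(mu)
  W <- mean(apply(x, 1L, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x) {
  # x: chains x draws (already split); Geyer initial monotone sequence,
  # combined across chains as in Stan
  m <- nrow(x); n <- ncol(x)
  if (n < 4L) {
    stop_pivae("chains too short for ESS (need >= 4 draws)",
               class = "pivae_validation_error")
  }
  chain_var <- apply(x, 1L, stats::var)
  W <- mean(chain_var)
  mu <- rowMeans(x)
  var_plus <- W * (n - 1) / n + (if (m > 1) stats::var(mu) else 0)
  if (var_plus == 0) return(m * n)
  # lagged autocovariances computed on demand: the Geyer summation stops at
  # the first negative pair, so only the needed lags are evaluated
  xc <- x - rowMeans(x)
  acov_lag <- function(t) {
    mean(vapply(seq_len(m), function(i)
      sum(xc[i, 1:(n - t)] * xc[i, (1 + t):n]) / n, numeric(1)))
  }
  rho_lag <- function(t) {
    if (t == 0L) return(1)
    1 - (W - acov_lag(t)) / var_plus
  }
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0; prev <- Inf
  t <- 1L
  while (t + 1L <= n - 1L) {
    pair <- rho_lag(t) + rho_lag(t + 1L)
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  tau <- max(2 * tau - 1, 1 / log10(m * n + 1))  # tau = 1 + 2 sum_{t>=1} rho_t
  min(m * n / tau, m * n * log10(m * n))
}

#' Split R-hat and effective sample size
#'
#' `mcmc_rhat` computes the split-chain potential scale reduction factor and
#' `mcmc_ess` the effective sample size; with `rank_normalized = TRUE`
#' (default) both operate on rank-normalised draws (robust "bulk"
#' versions).
#'
#' @param x A `chains x draws` matrix for one parameter, or a
#'   `chains x draws x parameters` array (a vector is treated as one chain).
#' @param rank_normalized Rank-normalise draws first.
#' @return Numeric scalar (or vector, one per parameter).
#' @export
mcmc_rhat <- function(x, rank_normalized = TRUE) {
  apply_param(x, function(m) {
    s <- split_chains(m)
    if (rank_normalized) s <- rank_normalize(s)
    rhat_basic(s)
  })
}

#' @rdname mcmc_rhat
#' @export
mcmc_ess <- function(x, rank_normalized = TRUE) {
  apply_param(x, function(m) {
    s <- split_chains(m)
    if (rank_normalized) s <- rank_normalize(s)
    ess_basic(s)
  })
}

apply_param <- function(x, f) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (length(dim(x)) == 2L) return(f(x))
  vapply(seq_len(dim(x)[3]), function(j) f(x[, , j, drop = TRUE]), numeric(1))
}

#' Per-parameter convergence diagnostics table
#'
#' Split rank-normalised R-hat, bulk effective sample size and ESS per
#' retained draw for every parameter of a posterior sample, sorted by worst
#' R-hat.
#'
#' @param post A `pivae_mcmc` object (from [nuts_sample()] or [fit_pivae()]),
#'   or a `chains x draws x parameters` array.
#' @param names Optional parameter names.
#' @return A data frame with columns `parameter`, `rhat`, `ess`,
#'   `ess_per_draw`, sorted by decreasing `rhat`.
#' @export
mcmc_diagnostics <- function(post, names = NULL) {
  x <- if (inherits(post, "pivae_mcmc")) post$draws else post
  if (length(dim(x)) != 3L) {
    stop_pivae("expected a chains x draws x parameters array",
               class = "pivae_validation_error")
  }
  if (dim(x)[1] < 2L) {
    stop_pivae("diagnostics need at least 2 chains",
               class = "pivae_validation_error")
  }
  if (dim(x)[2] < 4L) {
    stop_pivae("diagnostics need at least 4 draws per chain",
               class = "pivae_validation_error")
  }
  d <- dim(x)[3]
  names <- names %||% dimnames(x)[[3]] %||% paste0("par", seq_len(d))
  out <- data.frame(parameter = names,
                    rhat = mcmc_rhat(x),
                    ess = mcmc_ess(x))
  out$ess_per_draw <- out$ess / (dim(x)[1] * dim(x)[2])
  out[order(-out$rhat), , drop = FALSE]
}
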