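# No-U-Turn sampler (multinomial variant) with dual-averaging step-size
# adaptation and windowed diagonal mass-matrix estimation. The target is
# supplied as a callable returning the log density and its gradient; this is
# the stage-2 engine that samples the latent variables of a trained prior.

#' Sample a differentiable target with the No-U-Turn sampler
#'
#' Adaptive Hamiltonian Monte Carlo over an unconstrained parameter vector.
#' The step size is tuned by dual averaging towards `target_accept` and a
#' diagonal mass matrix is estimated from the warmup draws in expanding
#' windows (both frozen after warmup). Chains are run sequentially and
#' reproducibly from `seed`.
#'
#' @param log_prob Function of the parameter vector returning a list with
#'   elements `lp` (log density) and `grad` (its gradient).
#' @param init Either an `chains x d` matrix of initial values, a single
#'   vector reused for all chains, or a function(chain) returning a vector.
#' @param chains Number of chains (at least 2 for diagnostics).
#' @param warmup,iter Warmup and retained iterations per chain.
#' @param seed Integer seed.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum tree doubling depth.
#' @param divergence_tol Energy-error threshold for flagging a divergence.
#' @param divergence_warn_frac Post-warmup divergence fraction above which a
#'   warning is surfaced in the result (and emitted).
#' @return An object of class `pivae_mcmc`: list with `draws`
#'   (`chains x iter x d` array), `accept_stat`, `divergences`, `step_size`,
#'   `inv_mass`, and `warnings`.
#' @seealso [mcmc_diagnostics()]
#' @export
nuts_sample <- function(log_prob, init, chains = 4, warmup = 1000, iter = 1000,
                        seed = 1, target_accept = 0.8, max_treedepth = 10,
                        divergence_tol = 1000, divergence_warn_frac = 0.02) {
  chains <- check_count(chains, "chains")
  warmup <- check_count(warmup, "warmup", min = 20L)
  iter <- check_count(iter, "iter")

  init_fn <- if (is.function(init)) init
    else if (is.matrix(init)) function(ch) init[ch, ]
    else function(ch) init
  d <- length(init_fn(1L))

  draws <- array(NA_real_, c(chains, iter, d))
  accept <- matrix(NA_real_, chains, iter)
  diverg <- matrix(0L, chains, iter)
  treedepth <- matrix(NA_integer_, chains, iter)
  step_sizes <- numeric(chains)
  inv_mass_out <- matrix(NA_real_, chains, d)

  with_seed(seed, {
    for (ch in seq_len(chains)) {
      q <- as.numeric(init_fn(ch))
      st <- log_prob(q)
      if (!is.finite(st$lp) || !all(is.finite(st$grad))) {
        stop_pivae("non-finite log density or gradient at the initial value",
                   class = "pivae_numerical_error")
      }
      inv_mass <- rep(1, d)
      eps <- find_reasonable_eps(log_prob, q, st, inv_mass)
      da <- da_init(eps)

      # mass-adaptation windows within [75, warmup - 50] (collapsed for
      # short warmups)
      wins <- adapt_windows(warmup)
      win_ptr <- 1L
      acc_n <- 0L; acc_mean <- rep(0, d); acc_m2 <- rep(0, d)

      total <- warmup + iter
      for (it in seq_len(total)) {
        res <- nuts_transition(log_prob, q, st, eps, inv_mass, max_treedepth,
                               divergence_tol)
        q <- res$q; st <- res$st
        if (it <= warmup) {
          da <- da_update(da, res$accept_stat, target_accept)
          eps <- da$eps
          if (win_ptr <= length(wins$end) && it >= wins$start[win_ptr]) {
            acc_n <- acc_n + 1L
            delta <- q - acc_mean
            acc_mean <- acc_mean + delta / acc_n
            acc_m2 <- acc_m2 + delta * (q - acc_mean)
            if (it == wins$end[win_ptr]) {
              v <- acc_m2 / max(acc_n - 1L, 1L)
              inv_mass <- v * acc_n / (acc_n + 5) + 1e-3 * 5 / (acc_n + 5)
              acc_n <- 0L; acc_mean <- rep(0, d); acc_m2 <- rep(0, d)
              eps <- find_reasonable_eps(log_prob, q, st, inv_mass)
              da <- da_init(eps)
              win_ptr <- win_ptr + 1L
            }
          }
          if (it == warmup) eps <- da$eps_bar
        } else {
          k <- it - warmup
          draws[ch, k, ] <- q
          accept[ch, k] <- res$accept_stat
          diverg[ch, k] <- res$divergent
          treedepth[ch, k] <- res$depth
        }
      }
      step_sizes[ch] <- eps
      inv_mass_out[ch, ] <- inv_mass
    }
  })

  div_frac <- mean(diverg)
  warnings <- character(0)
  if (div_frac > divergence_warn_frac) {
    msg <- sprintf("%.1f%% divergent transitions post-warmup", 100 * div_frac)
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }
  structure(list(draws = draws, accept_stat = accept, divergences = diverg,
                 treedepth = treedepth, step_size = step_sizes,
                 inv_mass = inv_mass_out, warmup = warmup,
                 warnings = warnings),
            class = "pivae_mcmc")
}

#' @export
print.pivae_mcmc <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<pivae_mcmc> %d chains x %d draws x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  mean accept %.3f, divergent %.2f%%, step sizes %s\n",
              mean(x$accept_stat), 100 * mean(x$divergences),
              paste(signif(x$step_size, 3), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# ---- internals ------------------------------------------------------------

adapt_windows <- function(warmup) {
  if (warmup < 200L) {
    # one window over the middle half
    s <- max(2L, floor(warmup * 0.25)); e <- floor(warmup * 0.75)
    return(list(start = s, end = e))
  }
  init_buf <- 75L; term_buf <- 50L
  starts <- integer(0); ends <- integer(0)
  s <- init_buf + 1L; w <- 25L
  while (s + w - 1L <= warmup - term_buf) {
    e <- s + w - 1L
    if (s + 3L * w > warmup - term_buf) e <- warmup - term_buf  # absorb rest
    starts <- c(starts, s); ends <- c(ends, e)
    s <- e + 1L; w <- 2L * w
  }
  list(start = starts, end = ends)
}

da_init <- function(eps) {
  list(eps = eps, eps_bar = eps, mu = log(10 * eps), h_bar = 0, t = 0L,
       gamma = 0.05, t0 = 10, kappa = 0.75)
}

da_update <- function(da, accept_stat, target) {
  da$t <- da$t + 1L
  eta <- 1 / (da$t + da$t0)
  da$h_bar <- (1 - eta) * da$h_bar + eta * (target - accept_stat)
  log_eps <- da$mu - sqrt(da$t) / da$gamma * da$h_bar
  w <- da$t^(-da$kappa)
  da$eps <- exp(log_eps)
  da$eps_bar <- exp(w * log_eps + (1 - w) * log(da$eps_bar))
  da
}

find_reasonable_eps <- function(log_prob, q, st, inv_mass) {
  eps <- 1
  p <- stats::rnorm(length(q)) / sqrt(inv_mass)
  H0 <- st$lp - 0.5 * sum(p^2 * inv_mass)
  lf <- leapfrog(log_prob, q, p, st$grad, eps, inv_mass)
  H1 <- if (is.finite(lf$lp)) lf$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
  a <- if (H1 - H0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    lf <- leapfrog(log_prob, q, p, st$grad, eps, inv_mass)
    H1 <- if (is.finite(lf$lp)) lf$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
    if (a * (H1 - H0) <= a * log(0.5)) break
  }
  max(eps, 1e-10)
}

leapfrog <- function(log_prob, q, p, grad, eps, inv_mass) {
  p1 <- p + 0.5 * eps * grad
  q1 <- q + eps * inv_mass * p1
  st <- log_prob(q1)
  if (!is.finite(st$lp) || !all(is.finite(st$grad))) {
    return(list(q = q1, p = p1, lp = -Inf, grad = grad))
  }
  p1 <- p1 + 0.5 * eps * st$grad
  list(q = q1, p = p1, lp = st$lp, grad = st$grad)
}

# One NUTS transition (multinomial sampling over the trajectory, biased
# progressive doubling, generalized U-turn on the leftmost/rightmost states).
nuts_transition <- function(log_prob, q, st, eps, inv_mass, max_depth,
                            div_tol) {
  d <- length(q)
  p0 <- stats::rnorm(d) / sqrt(inv_mass)
  H0 <- st$lp - 0.5 * sum(p0^2 * inv_mass)

  env <- new.env(parent = emptyenv())
  env$n_steps <- 0L
  env$sum_accept <- 0
  env$divergent <- FALSE

  # tree node: q,p,grad,lp at both ends, proposal, log weight
  leaf <- function(q, p, grad, dir) {
    lf <- leapfrog(log_prob, q, p, grad, dir * eps, inv_mass)
    H <- if (is.finite(lf$lp)) lf$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
    env$n_steps <- env$n_steps + 1L
    env$sum_accept <- env$sum_accept + min(1, exp(min(H - H0, 0)))
    div <- !is.finite(H) || (H0 - H) > div_tol
    if (div) env$divergent <- TRUE
    list(q_minus = lf$q, p_minus = lf$p, g_minus = lf$grad,
         q_plus = lf$q, p_plus = lf$p, g_plus = lf$grad,
         prop_q = lf$q, prop_lp = lf$lp, prop_grad = lf$grad,
         logw = H - H0, turning = FALSE, divergent = div)
  }

  build <- function(q, p, grad, dir, depth) {
    if (depth == 0L) return(leaf(q, p, grad, dir))
    a <- build(q, p, grad, dir, depth - 1L)
    if (a$divergent || a$turning) return(a)
    b <- if (dir == 1L) build(a$q_plus, a$p_plus, a$g_plus, dir, depth - 1L)
         else build(a$q_minus, a$p_minus, a$g_minus, dir, depth - 1L)
    out <- if (dir == 1L) {
      list(q_minus = a$q_minus, p_minus = a$p_minus, g_minus = a$g_minus,
           q_plus = b$q_plus, p_plus = b$p_plus, g_plus = b$g_plus)
    } else {
      list(q_minus = b$q_minus, p_minus = b$p_minus, g_minus = b$g_minus,
           q_plus = a$q_plus, p_plus = a$p_plus, g_plus = a$g_plus)
    }
    out$divergent <- b$divergent
    out$logw <- logsumexp(a$logw, b$logw)
    # multinomial sampling within the subtree
    take_b <- log(stats::runif(1)) < b$logw - out$logw
    if (take_b && is.finite(b$prop_lp)) {
      out$prop_q <- b$prop_q; out$prop_lp <- b$prop_lp; out$prop_grad <- b$prop_grad
    } else {
      out$prop_q <- a$prop_q; out$prop_lp <- a$prop_lp; out$prop_grad <- a$prop_grad
    }
    dq <- out$q_plus - out$q_minus
    out$turning <- b$turning ||
      sum(dq * inv_mass * out$p_minus) < 0 || sum(dq * inv_mass * out$p_plus) < 0
    out
  }

  tree <- list(q_minus = q, p_minus = p0, g_minus = st$grad,
               q_plus = q, p_plus = p0, g_plus = st$grad,
               prop_q = q, prop_lp = st$lp, prop_grad = st$grad, logw = 0)
  depth <- 0L
  while (depth < max_depth) {
    dir <- if (stats::runif(1) < 0.5) -1L else 1L
    sub <- if (dir == 1L)
      build(tree$q_plus, tree$p_plus, tree$g_plus, dir, depth)
    else
      build(tree$q_minus, tree$p_minus, tree$g_minus, dir, depth)
    # a divergent or internally U-turning subtree is discarded outright
    if (sub$divergent || sub$turning) break
    # biased progressive sampling: favour the new subtree
    if (is.finite(sub$prop_lp) &&
        log(stats::runif(1)) < sub$logw - tree$logw) {
      tree$prop_q <- sub$prop_q; tree$prop_lp <- sub$prop_lp
      tree$prop_grad <- sub$prop_grad
    }
    if (dir == 1L) {
      tree$q_plus <- sub$q_plus; tree$p_plus <- sub$p_plus; tree$g_plus <- sub$g_plus
    } else {
      tree$q_minus <- sub$q_minus; tree$p_minus <- sub$p_minus; tree$g_minus <- sub$g_minus
    }
    tree$logw <- logsumexp(tree$logw, sub$logw)
    dq <- tree$q_plus - tree$q_minus
    if (sum(dq * inv_mass * tree$p_minus) < 0 ||
        sum(dq * inv_mass * tree$p_plus) < 0) { depth <- depth + 1L; break }
    depth <- depth + 1L
  }

  list(q = tree$prop_q,
       st = list(lp = tree$prop_lp, grad = tree$prop_grad),
       accept_stat = if (env$n_steps > 0) env$sum_accept / env$n_steps else 0,
       divergent = as.integer(env$divergent),
       depth = depth)
}
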