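# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_pivae <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pivae_error")))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_pivae(name, " must be a single positive finite number",
               class = "pivae_validation_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop_pivae(name, " must be a single integer >= ", min,
               class = "pivae_validation_error")
  }
  invisible(as.integer(x))
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop_pivae(name, " contains non-finite values",
               class = "pivae_validation_error")
  }
  invisible(x)
}

softplus <- function(x) {
  # log(1 + exp(x)) computed stably for large |x|
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logsumexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# Short stable hash of a configuration list (order-insensitive at top level),
# used to stamp artifacts with the configuration that produced them.
config_hash <- function(x) {
  if (is.list(x)) x <- x[order(names(x))]
  txt <- paste(deparse(x, control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
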