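# Internal helpers: classed conditions and seeded evaluation.

mer_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mertopo_error"), call = call))
}

stop_insufficient <- function(msg) mer_stop(msg, "mertopo_insufficient_data")
stop_config <- function(msg) mer_stop(msg, "mertopo_config_error")
stop_generation <- function(msg) mer_stop(msg, "mertopo_generation_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from the active stream (kept below 2^31).
child_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

# Draw from a normal truncated to [lo, hi]; when `match_mean` the location
# parameter is adjusted so the *truncated* mean equals `mean`.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf, match_mean = FALSE) {
  if (sd <= 0) return(rep(mean, n))
  mu <- mean
  if (match_mean) {
    tm <- function(m) {
      a <- (lo - m) / sd; b <- (hi - m) / sd
      za <- pnorm(a); zb <- pnorm(b)
      m + sd * (dnorm(a) - dnorm(b)) / (zb - za)
    }
    f <- function(m) tm(m) - mean
    mu <- tryCatch(uniroot(f, lower = mean - 6 * sd, upper = mean + 6 * sd)$root,
                   error = function(e) mean)
  }
  u <- runif(n, pnorm((lo - mu) / sd), pnorm((hi - mu) / sd))
  qnorm(u, mu, sd)
}

# Shifted-lognormal sampler with support >= shift, matching mean/sd exactly.
rshiftlnorm <- function(n, mean, sd, shift = 1) {
  m <- mean - shift
  if (m <= 0) stop_config("shifted-lognormal mean must exceed the shift")
  s2 <- log(1 + (sd / m)^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2)) + shift
}

# Shifted-lognormal quantile (used by the Gaussian copula coupling).
qshiftlnorm <- function(p, mean, sd, shift = 1) {
  m <- mean - shift
  s2 <- log(1 + (sd / m)^2)
  qlnorm(p, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2)) + shift
}

`%||%` <- function(a, b) if (is.null(a)) b else a
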