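# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and integer indices
#'
#' A small multiplicative hash over the index vector, reduced modulo 2^31 - 1
#' so the result is always a valid 32-bit integer seed. Distinct index tuples
#' give distinct streams for all practical purposes, and a gene's stream does
#' not depend on how many other genes are simulated.
#'
#' @keywords internal
#' @noRd
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% m
  for (k in seq_along(idx)) {
    # 48271 and 69621 are classic Lehmer multipliers; mixing two keeps
    # (sim, replicate) and (replicate, sim) streams distinct.
    h <- (h * 48271 + (as.numeric(idx[k]) + 1) * 69621 + k) %% m
  }
  as.integer(h)
}

#' Geometric mean of strictly positive values
#' @keywords internal
#' @noRd
geom_mean <- function(x) exp(mean(log(x)))

#' Mean of a normal distribution clamped (not conditioned) at zero
#'
#' If X ~ N(mu, sd) then E[max(X, 0)] = mu * pnorm(mu/sd) + sd * dnorm(mu/sd).
#' Used as the closed-form oracle for the truncated sampler and as the
#' expected ribosome load in deterministic computations.
#'
#' @keywords internal
#' @noRd
clamped_normal_mean <- function(mean, sd) {
  z <- mean / sd
  mean * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Largest-remainder apportionment of n into parts proportional to fractions
#' @keywords internal
#' @noRd
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties in remainders resolved by position for determinism
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stop unless condition holds
#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
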