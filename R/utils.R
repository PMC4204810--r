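# Internal numerical helpers shared across modules.

# Floor used to clamp impossible (log-probability -Inf) outcomes so that
# optimisation and log-sum-exp stay finite.
LOGLIK_FLOOR <- -1e12

# Emission/transition probabilities are kept strictly interior.
PROB_EPS <- 1e-4

#' Numerically stable log(sum(exp(x))) along matrix rows
#' @param x numeric matrix (rows = units, cols = components)
#' @return numeric vector of length nrow(x)
#' @keywords internal
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible 32-bit sub-seed from a master seed and a tag
#'
#' Deterministic, collision-unlikely integer hash so that every stage of a
#' pipeline (per restart, per hold-out split, per sweep combination) gets its
#' own seed derived from one user-supplied master seed.
#'
#' @param seed master integer seed
#' @param ... further integers or strings identifying the sub-stream
#' @return integer between 0 and 2^31 - 1
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.numeric(p) + 11) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards (bit-reproducibility contract).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Round half away from zero (display convention for printed tables)
#' @param x numeric
#' @param digits integer
#' @return numeric
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Inverse Mills ratio phi(x)/Phi(x), computed on the log scale for stability.
inv_mills <- function(x) {
  exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))
}

#' MAP estimate of a Bernoulli probability on the probit scale
#'
#' Maximises k*log(Phi(theta)) + (m-k)*log(Phi(-theta)) - theta^2/2, i.e. a
#' (possibly fractionally) weighted Bernoulli log-likelihood with a standard
#' Gaussian prior on the probit score. Vectorised damped Newton; the objective
#' is strictly concave so convergence is global.
#'
#' @param k vector of (expected) success counts
#' @param m vector of (expected) trial counts, m >= k >= 0
#' @param max_iter Newton iteration cap
#' @return vector of probabilities Phi(theta_hat), clamped to the interior
#' @keywords internal
probit_map_prob <- function(k, m, max_iter = 50) {
  stopifnot(length(k) == length(m))
  k <- pmax(k, 0); m <- pmax(m, k)
  # good starting point: empirical with light smoothing
  theta <- stats::qnorm(pmin(pmax((k + 0.5) / (m + 1), 1e-6), 1 - 1e-6))
  obj <- function(th) {
    k * stats::pnorm(th, log.p = TRUE) +
      (m - k) * stats::pnorm(-th, log.p = TRUE) - th^2 / 2
  }
  obj_at <- function(th, i) {
    k[i] * stats::pnorm(th, log.p = TRUE) +
      (m[i] - k[i]) * stats::pnorm(-th, log.p = TRUE) - th^2 / 2
  }
  f <- obj(theta)
  for (it in seq_len(max_iter)) {
    hp <- inv_mills(theta)     # d/dtheta log Phi(theta)
    hm <- inv_mills(-theta)    # -d/dtheta log Phi(-theta) = phi/Phi(-theta)
    g1 <- k * hp - (m - k) * hm - theta
    g2 <- -k * hp * (theta + hp) - (m - k) * hm * (hm - theta) - 1
    step <- -g1 / g2
    # damped update with step halving (guards rare overshoot at large |theta|)
    new_theta <- theta + step
    f_new <- obj(new_theta)
    bad <- which(f_new < f - 1e-12)
    tries <- 0L
    while (length(bad) && tries < 30L) {
      step[bad] <- step[bad] / 2
      new_theta[bad] <- theta[bad] + step[bad]
      f_new[bad] <- obj_at(new_theta[bad], bad)
      bad <- bad[f_new[bad] < f[bad] - 1e-12]
      tries <- tries + 1L
    }
    moved <- max(abs(new_theta - theta))
    theta <- new_theta
    f <- f_new
    if (moved < 1e-10) break
  }
  pmin(pmax(stats::pnorm(theta), PROB_EPS), 1 - PROB_EPS)
}
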