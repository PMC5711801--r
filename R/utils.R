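# Internal numeric helpers shared across modules.

# Wrap angles (degrees) into (-180, 180].
wrap180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# Wrap angles (degrees) into [-90, 270), the reporting interval that keeps
# both coordination attractors (0 and 180) in the interior.
wrap_phase <- function(x) {
  y <- x %% 360
  y[y >= 270] <- y[y >= 270] - 360
  y
}

# Circular distance in degrees, in [0, 180].
circ_dist <- function(a, b) abs(wrap180(a - b))

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x < 33
  out[small] <- log1p(exp(x[small]))
  out
}

invlogit <- function(x) stats::plogis(x)

# von Mises(0, kappa) sampler (Best & Fisher 1979 wrapped-Cauchy envelope),
# returning radians in (-pi, pi].
rvonmises0 <- function(n, kappa) {
  stopifnot(kappa > 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# von Mises(0, kappa) truncated to +/- half_width degrees, by rejection.
# Returns degrees.
rvonmises_trunc <- function(n, kappa, half_width) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rvonmises0(2L * (n - length(out)) + 8L, kappa) * 180 / pi
    out <- c(out, draw[abs(draw) <= half_width])
  }
  out[seq_len(n)]
}

# Inverse-Gaussian(mu, lambda) sampler (Michael, Schucany & Haas 1976).
rinvgauss1 <- function(mu, lambda) {
  nu <- stats::rnorm(1)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  if (x <= 0 || !is.finite(x)) {
    # extreme tail draw; fall back to the reciprocal branch directly
    return(mu^2 / max(mu * y, .Machine$double.eps))
  }
  if (stats::runif(1) <= mu / (mu + x)) x else mu^2 / x
}

# Univariate slice sampler with stepping out (Neal 2003); logf is the
# unnormalised log target density.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice_sample1: initial point has zero density")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Deterministic sub-stream seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 131071 + as.numeric(index) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
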