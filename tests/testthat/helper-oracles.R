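# Independent oracles, deliberately implemented with different numerics
# than the package code paths they check.

# bisection root finding for the cantilever characteristic equation
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

oracle_eigenvalue <- function(k) {
  f <- function(x) cosh(x) * cos(x) + 1
  bisect_root(f, (k - 0.5) * pi - 1, (k - 0.5) * pi + 1)
}

# moments of the normalized product of two Gaussian densities, by
# numerical integration on a fine grid
oracle_gaussian_product <- function(m1, v1, m2, v2) {
  lo <- min(m1 - 8 * sqrt(v1), m2 - 8 * sqrt(v2))
  hi <- max(m1 + 8 * sqrt(v1), m2 + 8 * sqrt(v2))
  x <- seq(lo, hi, length.out = 20001)
  w <- dnorm(x, m1, sqrt(v1)) * dnorm(x, m2, sqrt(v2))
  w <- w / sum(w)
  mu <- sum(w * x)
  list(mean = mu, variance = sum(w * (x - mu)^2))
}

# Monte-Carlo SD of a truncated normal by rejection-free inverse sampling
oracle_truncated_sd <- function(L, sigma, a, b, n = 1e6) {
  u <- runif(n, pnorm(a, L, sigma), pnorm(b, L, sigma))
  sd(qnorm(u, L, sigma))
}
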