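# Shared oracles and generators for the test suite.

# numerical spatiotemporal Fourier transform of a delayed kernel:
# integral of kern(x) * exp(i*omega*upsilon*|x|) * exp(-i*k*x) dx
# (adaptive quadrature on a finite support scaled to the decay rate)
ft_quadrature <- function(kern, k, omega, upsilon, upper, breaks = 0) {
  # piecewise integration split at the kernel's kinks for robustness
  pts <- sort(unique(c(-upper, -abs(breaks), abs(breaks), upper)))
  one <- function(f) sum(vapply(seq_len(length(pts) - 1), function(i)
    stats::integrate(f, pts[i], pts[i + 1], subdivisions = 4000L,
                     rel.tol = 1e-11, abs.tol = 1e-13)$value, numeric(1)))
  re <- one(function(x) kern(x) * cos(omega * upsilon * abs(x) - k * x))
  im <- one(function(x) kern(x) * sin(omega * upsilon * abs(x) - k * x))
  complex(real = re, imaginary = im)
}

# random symmetric positive-definite correlation matrix
random_correlation <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.5
  stats::cov2cor(S)
}

# random parameter draw around the priors (log-normal jitter)
jittered_parameters <- function(seed, sd = 0.2) {
  set.seed(seed)
  p <- cmc_params()
  p$m_e <- p$m_e * exp(rnorm(1, 0, sd))
  p$kappa <- p$kappa * exp(rnorm(4, 0, sd))
  p$r <- p$r * exp(rnorm(1, 0, sd))
  p$a <- p$a * exp(rnorm(10, 0, sd))
  fp <- field_params(c_diag = 2 * exp(rnorm(1, 0, sd)),
                     c_off = 0.6 * exp(rnorm(1, 0, sd)),
                     h = 4.5 * exp(rnorm(1, 0, sd)),
                     upsilon = 0.6 * exp(rnorm(1, 0, sd)))
  list(params = p, field = fp)
}

# ground truth used by the recovery experiments: columnar decay scaled
# up by exp(0.4), interneuron drive a_23 scaled down by exp(-0.4)
recovery_truth <- function(seed) {
  p <- cmc_params()
  fp <- field_params()
  fp$c_diag <- fp$c_diag * exp(0.4)
  p$a["a_23"] <- p$a["a_23"] * exp(-0.4)
  ground_truth(p, fp, seed = seed)
}
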