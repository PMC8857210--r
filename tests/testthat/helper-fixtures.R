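# Shared small fixtures; everything is generated in code.

psf1 <- psf_model(sigma = 1, dim = 1)

small_basis <- function(M = 24) computation_basis(psf1, M)

# dense trapezoid quadrature of an integrand over [lo, hi]
trapz_int <- function(f, lo, hi, n = 4001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# field PSF profile for oracles
psi_R <- function(x, R, sigma = 1)
  (2 * pi * sigma^2)^(-1/4) * exp(-(x - R)^2 / (4 * sigma^2))

random_spd <- function(K, seed) {
  set.seed(seed)
  A <- matrix(rnorm(K * K), K)
  crossprod(A) + diag(K) * 0.1
}
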