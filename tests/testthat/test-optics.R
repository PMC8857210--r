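test_that("psf_overlap matches the Gaussian closed form and a quadrature oracle", {
  expect_equal(psf_overlap(0, 0, psf1), 1)
  expect_equal(psf_overlap(0, 2, psf1), exp(-0.5), tolerance = 1e-12)
  oracle <- trapz_int(function(x) psi_R(x, 0) * psi_R(x, 2), -15, 15)
  expect_equal(psf_overlap(0, 2, psf1), oracle, tolerance = 1e-10)
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(1, sd = 3); b <- rnorm(1, sd = 3)
    expect_identical(psf_overlap(a, b, psf1), psf_overlap(b, a, psf1))
  }
  psf2 <- psf_model(1.3, dim = 2)
  expect_equal(psf_overlap(c(0, 0), c(1, 2), psf2),
               exp(-(1 + 4) / (8 * 1.3^2)))
  expect_error(psf_overlap(0, Inf, psf1), "finite")
})

test_that("shifted-PSF coefficients reproduce overlaps and captured energy", {
  cb <- small_basis(40)
  g <- psf_coefficients(cb, c(0, 1.5))
  # inner product of two expansions equals the closed-form PSF overlap
  expect_equal(sum(g[, 1] * g[, 2]), exp(-1.5^2 / 8), tolerance = 1e-10)
  expect_gt(min(captured_energy(cb, seq(-3, 3, by = 0.5))), 1 - 1e-10)
})

test_that("matched single mode captures a point source completely", {
  cb <- small_basis()
  src <- point_comb(1, 1, normalize = FALSE)
  modes <- mode_set(diag(cb$size)[, 1, drop = FALSE], cb)  # phi_0 = psi_0
  pt <- probability_tensor(src$basis, modes)
  expect_equal(as.numeric(pt), 1, tolerance = 1e-12)
})

test_that("a complete computation basis conserves probability (Parseval)", {
  cb <- small_basis(40)
  src <- extended_source("bump", 0.8, 4, normalize = FALSE)  # 10 bins
  modes <- mode_set(diag(cb$size), cb)
  pt <- probability_tensor(src$basis, modes)
  expect_lt(max(abs(colSums(unclass(pt)) - attr(pt, "s"))), 1e-10)
  # captured mass of each 0.8-wide bin is close to the bin width
  expect_lt(max(abs(attr(pt, "s") - 0.8)), 1e-6)
})

test_that("bin-integrated probabilities match a brute-force double quadrature", {
  cb <- small_basis()
  src <- extended_source("uniform", 0.8, 0.4, normalize = FALSE)  # single bin [-0.4, 0.4)
  modes <- mode_set(diag(cb$size)[, 1, drop = FALSE], cb)
  pt <- probability_tensor(src$basis, modes, nq = 24)
  inner <- function(r) stats::integrate(function(x)
    (2 * pi)^(-1/4) * exp(-x^2 / 4) * psi_R(x, r), -Inf, Inf,
    rel.tol = 1e-12)$value
  oracle <- stats::integrate(Vectorize(function(r) inner(r)^2), -0.4, 0.4,
                             rel.tol = 1e-12)$value
  expect_equal(as.numeric(pt), oracle, tolerance = 1e-8)
})

test_that("probabilities are stable under quadrature refinement", {
  cb <- small_basis()
  src <- extended_source("bump", 0.8, 4, normalize = FALSE)
  modes <- mode_set(diag(cb$size)[, 1:6], cb)
  p1 <- probability_tensor(src$basis, modes, nq = 12)
  p2 <- probability_tensor(src$basis, modes, nq = 24)
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("detection probabilities are linear and flux-bounded", {
  cb <- small_basis()
  src <- point_comb(3, 0.5)
  modes <- mode_set(diag(cb$size)[, 1:3], cb)
  pt <- probability_tensor(src$basis, modes)
  expect_equal(detection_probs(rep(0, 3), pt), rep(0, 3))
  expect_equal(detection_probs(c(0, 1, 0), pt), unclass(pt)[, 2])
  P <- detection_probs(src, pt)
  expect_true(all(P >= 0) && sum(P) <= sum(src$c) + 1e-12)
  expect_error(detection_probs(c(-1, 0, 0), pt), "non-negative")
})

test_that("direct-imaging pixel modes are orthonormal and converge with refinement", {
  cb <- computation_basis(psf1, 64)
  src <- point_comb(5, 0.4)
  crbs <- vapply(c(1, 0.5, 0.25), function(w) {
    dm <- direct_imaging_modes(cb, w, 6)
    expect_lt(orthonormality_defect(dm$V), 1e-10)
    mean_crb(src, dm)
  }, numeric(1))
  # halving the pixel width changes the CRB by < 1% once pixels are fine
  expect_lt(abs(crbs[3] - crbs[2]) / crbs[3], 0.01)

  # one huge pixel: a single binning mode, hence rank-1 information
  dm1 <- direct_imaging_modes(cb, 12, 6)
  expect_equal(dm1$J, 1)
  pt <- probability_tensor(src$basis, dm1)
  I <- fisher_matrix(src$c, pt)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-12)
  expect_error(crb_objective(I), "singular")
})
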