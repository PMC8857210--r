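test_that("Euclidean gradient matches central finite differences", {
  set.seed(12)
  cb <- computation_basis(psf1, 10)
  src <- point_comb(3, 0.8)
  for (rep in 1:3) {
    obj <- mode_objective(src, cb)
    V <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
    g <- obj$grad(V)
    h <- 1e-6
    fd <- matrix(0, 10, 3)
    for (i in 1:10) for (j in 1:3) {
      E <- matrix(0, 10, 3); E[i, j] <- h
      fd[i, j] <- (obj$fn(V + E) - obj$fn(V - E)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("gradient vanishes for a zero weighting matrix", {
  cb <- computation_basis(psf1, 8)
  src <- point_comb(2, 1)
  obj <- mode_objective(src, cb, W = matrix(0, 2, 2))
  V <- qr.Q(qr(matrix(rnorm(16), 8, 2)))
  expect_equal(obj$grad(V), matrix(0, 8, 2), tolerance = 1e-12)
})

test_that("objective is invariant under mode permutations and sign flips", {
  cb <- computation_basis(psf1, 12)
  src <- point_comb(3, 0.5)
  obj <- mode_objective(src, cb)
  V <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  f0 <- obj$fn(V)
  expect_lt(abs(obj$fn(V[, c(2, 3, 1)]) - f0) / f0, 1e-12)
  expect_lt(abs(obj$fn(V %*% diag(c(1, -1, 1))) - f0) / f0, 1e-12)
})

test_that("descent is monotone, feasible and stationary at an optimum", {
  cb <- computation_basis(psf1, 24)
  src <- point_comb(3, 0.5)
  phi <- optimal_modes(src, cb, 3, whiten = FALSE,
                       config = optimizer_config(max_iters = 2000))
  tr <- attr(phi, "trace")
  expect_true(all(diff(tr$objective) <= 1e-12 * max(tr$objective)))
  expect_lt(tr$final_defect, 1e-10)
  expect_lt(orthonormality_defect(phi$V), 1e-10)
  # restarting at the optimum does not move the objective
  obj <- mode_objective(src, cb)
  again <- optimize_modes(obj, phi$V, cbasis = cb,
                          config = optimizer_config(max_iters = 500))
  expect_lt(abs(attr(again, "trace")$objective_final - tr$objective_final),
            1e-9 * tr$objective_final + 1e-12)
})

test_that("a single source yields the analytically matched mode", {
  cb <- small_basis()
  src <- point_comb(1, 1, normalize = FALSE)
  phi <- optimal_modes(src, cb, 1, whiten = FALSE)
  pt <- probability_tensor(src$basis, phi)
  # the matched mode phi_0 = psi_0 captures everything: I = 1/c = 1
  I <- fisher_matrix(src$c, pt)
  expect_gt(I[1, 1], 0.999)
})

test_that("two well-separated points beat the orthonormalized shifted-PSF baseline", {
  cb <- computation_basis(psf1, 32)
  src <- point_comb(2, 4)
  baseline <- matched_mode_init(src, cb, 2)
  phi <- optimal_modes(src, cb, 2, whiten = FALSE)
  expect_lte(mean_crb(src, phi), mean_crb(src, baseline) * (1 + 1e-6))
})

test_that("optimized modes for the close 5-point comb beat direct imaging by > 2x", {
  cb <- computation_basis(psf1, 48)
  src <- point_comb(5, 0.3)
  dm <- direct_imaging_modes(cb, 0.25, src$basis$extent + 5)
  phi <- optimal_modes(src, cb, 5)
  expect_gt(mean_crb(src, dm) / mean_crb(src, phi), 2)
})

test_that("optimizer output is deterministic and canonically ordered", {
  cb <- small_basis()
  src <- point_comb(3, 0.4)
  phi1 <- optimal_modes(src, cb, 3)
  phi2 <- optimal_modes(src, cb, 3)
  expect_identical(phi1$V, phi2$V)
  pt <- probability_tensor(src$basis, phi1)
  P <- detection_probs(src, pt)
  expect_true(all(diff(P) <= 1e-12))  # sorted by descending probability
})

test_that("physics-derived initializations are feasible Stiefel points", {
  cb <- small_basis(32)
  src <- extended_source("bump", 1.6, 3.2)
  inits <- list(eigenmode_init(src, cb, 5),
                sld_signal_init(src, cb, 5),
                hg_ladder_init(cb, 5),
                matched_mode_init(src, cb, 5))
  for (f in inits) expect_lt(orthonormality_defect(f$V), 1e-10)
})
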