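test_that("NNLS recovers exact coefficients from noiseless full-rank data", {
  cb <- small_basis()
  src <- point_comb(4, 0.8, amplitudes = c(1, 3, 2, 4))
  dm <- direct_imaging_modes(cb, 0.5, 5)
  pt <- probability_tensor(src$basis, dm)
  N <- 1e6
  rec <- structure(list(counts = N * detection_probs(src, pt), modes = dm,
                        pt = pt, budget = N, seed = NULL,
                        P = detection_probs(src, pt)),
                   class = "mospade_record")
  est <- nnls_reconstruct(rec)
  expect_lt(max(abs(est$c_est - src$c)), 1e-8)
})

test_that("all-zero counts give the zero estimate", {
  cb <- small_basis()
  src <- point_comb(3, 0.5)
  modes <- direct_imaging_modes(cb, 0.5, 4)
  pt <- probability_tensor(src$basis, modes)
  rec <- structure(list(counts = rep(0, modes$J), modes = modes, pt = pt,
                        budget = 10, seed = NULL, P = detection_probs(src, pt)),
                   class = "mospade_record")
  est <- nnls_reconstruct(rec)
  expect_equal(est$c_est, rep(0, 3))
})

test_that("estimates are non-negative and scale-equivariant", {
  cb <- small_basis()
  src <- point_comb(3, 0.4)
  dm <- direct_imaging_modes(cb, 0.5, 4)
  pt <- probability_tensor(src$basis, dm)
  r1 <- simulate_counts(src, dm, 1e6, seed = 5, pt = pt)
  e1 <- nnls_reconstruct(r1)$c_est
  expect_true(all(e1 >= 0))
  # doubling both the counts and the design budget leaves the estimate fixed
  r2 <- r1; r2$counts <- 2 * r1$counts; r2$budget <- 2 * r1$budget
  e2 <- nnls_reconstruct(r2)$c_est
  expect_equal(e2, e1, tolerance = 1e-10)
})

test_that("rank-deficient stacked systems warn with the null-space dimension", {
  cb <- small_basis()
  src <- point_comb(3, 0.5)
  modes <- mode_set(diag(cb$size)[, 1:2], cb)  # 2 modes for 3 parameters
  pt <- probability_tensor(src$basis, modes)
  rec <- simulate_counts(src, modes, 1e5, seed = 2, pt = pt)
  expect_warning(nnls_reconstruct(rec), "dimension 1")
})

test_that("mse_report implements the trial-averaged per-coefficient convention", {
  c_true <- c(1, 2, 3)
  est <- rbind(c(1, 2, 3), c(2, 2, 2))
  r <- mse_report(est, c_true)
  expect_equal(r$mse_k, c(0.5, 0, 0.5))
  expect_equal(r$mse, 1/3)
  expect_equal(mse_report(rbind(c_true), c_true)$mse, 0)
  single <- rbind(c_true + c(0.1, -0.2, 0.3))
  expect_equal(mse_report(single, c_true)$mse_k, c(0.01, 0.04, 0.09))
  expect_error(mse_report(est, c(1, 2)), "mismatch")
})

test_that("high-photon direct-imaging MSE tracks the CRB line", {
  cb <- computation_basis(psf1, 48)
  src <- point_comb(5, 0.3)
  dm <- direct_imaging_modes(cb, 0.25, 4)
  pt <- probability_tensor(src$basis, dm)
  crbN <- crb_objective(fisher_matrix(src$c, pt))$mean_crb
  N <- 1e6   # the CRB-following regime for direct imaging
  recs <- lapply(1:60, function(t)
    nnls_reconstruct(simulate_counts(src, dm, N, seed = 300 + t, pt = pt)))
  r <- mse_report(recs, src$c)
  expect_lt(r$mse, 1.3 * crbN / N)
  expect_gt(r$mse, 0.6 * crbN / N)
})

test_that("low-photon MSE saturates at the source-amplitude scale", {
  cb <- small_basis()
  src <- point_comb(5, 0.3)
  dm <- direct_imaging_modes(cb, 0.5, 5)
  pt <- probability_tensor(src$basis, dm)
  recs <- lapply(1:40, function(t)
    nnls_reconstruct(simulate_counts(src, dm, 10, seed = 600 + t, pt = pt)))
  r <- mse_report(recs, src$c)
  # errors of the same order as the amplitudes themselves, not unbounded
  expect_lt(r$mse, 10 * mean(src$c^2))
  expect_gt(r$mse, 0.1 * mean(src$c^2))
})
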