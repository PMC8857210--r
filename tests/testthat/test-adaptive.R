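test_that("accumulated Fisher information is the exact weighted sum", {
  cb <- small_basis()
  src <- point_comb(3, 0.5)
  V <- qr.Q(qr(matrix(rnorm(cb$size * 6), cb$size)))
  pts <- list(probability_tensor(src$basis, mode_set(V[, 1:3], cb)),
              probability_tensor(src$basis, mode_set(V[, 4:6], cb)))
  budgets <- c(1e4, 3e4)
  acc <- accumulated_fisher(src$c, pts, budgets)
  manual <- budgets[1] * fisher_matrix(src$c, pts[[1]]) +
    budgets[2] * fisher_matrix(src$c, pts[[2]])
  expect_identical(acc, manual)
})

test_that("a one-period schedule reduces exactly to direct imaging plus NNLS", {
  cb <- computation_basis(psf1, 48)
  src <- extended_source("bump", 0.8, 4)
  cfg <- adaptive_config(periods = 1, total_photons = 1e5, seed = 9,
                         pixel_width = 0.5, weighting = "none")
  ad <- run_adaptive(src, cb, cfg, trial = 2)
  dm <- direct_imaging_modes(cb, 0.5, src$basis$extent + 3)
  rec <- simulate_counts(src, dm, 1e5, seed = cfg$seed + 1000L * 2L + 1L)
  manual <- nnls_reconstruct(rec, weighting = "none")
  expect_equal(ad$c_est, manual$c_est, tolerance = 1e-12)
})

test_that("the adaptive loop is deterministic and accumulates information monotonically", {
  cb <- computation_basis(psf1, 48)
  src <- extended_source("bump", 0.8, 4)
  cfg <- adaptive_config(periods = 3, total_photons = 2e5, J_adaptive = 5,
                         seed = 13, optimizer = optimizer_config(max_iters = 600))
  ad1 <- run_adaptive(src, cb, cfg, trial = 1)
  ad2 <- run_adaptive(src, cb, cfg, trial = 1)
  expect_identical(ad1$c_est, ad2$c_est)
  # Loewner monotonicity of the accumulated FIM across periods
  pts <- lapply(ad1$log$records, function(r) r$pt)
  budgets <- ad1$budgets
  set.seed(31)
  for (i in 2:length(pts)) {
    Ia <- accumulated_fisher(ad1$c_est, pts[seq_len(i - 1)], budgets[seq_len(i - 1)])
    Ib <- accumulated_fisher(ad1$c_est, pts[seq_len(i)], budgets[seq_len(i)])
    for (r in 1:5) {
      v <- rnorm(ncol(Ia))
      expect_gte(sum(v * (Ib %*% v)), sum(v * (Ia %*% v)) - 1e-8)
    }
  }
  # the adaptive mode sets stay orthonormal
  for (m in ad1$modes) expect_lt(orthonormality_defect(m$V), 1e-10)
})

test_that("adaptive imaging beats direct imaging on a sub-Rayleigh extended source", {
  cb <- computation_basis(psf1, 64)
  src <- extended_source("bump", 0.8, 6.4)   # 16 bins
  N <- 1e6
  cfg <- adaptive_config(periods = 3, total_photons = N, J_adaptive = 6,
                         seed = 17, optimizer = optimizer_config(max_iters = 800))
  err_ad <- sapply(1:3, function(t)
    mean((run_adaptive(src, cb, cfg, trial = t)$c_est - src$c)^2))
  md <- run_direct(src, cb, N, trials = 3, seed = 23, pixel_width = 0.5)
  expect_lt(mean(err_ad), md$mse / 2)
})

test_that("single-source direct and optimized measurements agree when nothing is to optimize", {
  cb <- small_basis(32)
  src <- point_comb(1, 1, normalize = FALSE)
  N <- 1e5
  mm <- run_known_source(src, cb, J = 1, N = N, trials = 40, seed = 3,
                         weighting = "poisson")
  md <- run_direct(src, cb, N, trials = 40, seed = 4, pixel_width = 0.5,
                   pixel_extent = 4, weighting = "poisson")
  expect_lt(abs(mm$mse - md$mse) / md$mse, 0.2)
})

test_that("MSE versus photon number shows the bias floor and the CRB-following regimes", {
  cb <- computation_basis(psf1, 48)
  src <- point_comb(5, 0.3)
  phi <- optimal_modes(src, cb, 5)
  pt <- probability_tensor(src$basis, phi)
  crb <- crb_objective(fisher_matrix(src$c, pt))$mean_crb
  mse_at <- function(N, trials = 30) {
    recs <- lapply(seq_len(trials), function(t)
      nnls_reconstruct(simulate_counts(src, phi, N, seed = 900 + t, pt = pt)))
    mse_report(recs, src$c)$mse
  }
  low <- mse_at(10); mid <- mse_at(1e4); high <- mse_at(1e6)
  # low-N floor of order the amplitude scale, below the (huge) CRB/N line
  expect_lt(low, crb / 10)
  expect_lt(low, 10 * mean(src$c^2))
  # high-N follows the CRB line
  expect_lt(abs(high - crb / 1e6) / (crb / 1e6), 0.5)
  expect_lt(high, mid); expect_lt(mid, low)
})

test_that("adaptive two-dimensional imaging beats direct on a low-contrast star", {
  psf2 <- psf_model(1, dim = 2)
  cb2 <- computation_basis(psf2, 14)
  src <- scene_2d("siemens", grid_n = 8, bin_width = 0.9, contrast = 0.1)
  N <- 1e8
  cfg <- adaptive_config(periods = 3, total_photons = N,
                         J_adaptive = src$basis$K + 1, pixel_width = 1.0,
                         seed = 7, optimizer = optimizer_config(max_iters = 600))
  err_ad <- mean((run_adaptive(src, cb2, cfg, trial = 1)$c_est - src$c)^2)
  md <- run_direct(src, cb2, N, trials = 2, seed = 3, pixel_width = 1.0)
  expect_lt(err_ad, md$mse)
})
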