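test_that("single matched mode gives the hand-computed information 1/c", {
  p <- matrix(1, 1, 1)
  for (c1 in c(0.2, 1, 3)) {
    expect_equal(fisher_matrix(c1, p), matrix(1 / c1, 1, 1))
  }
})

test_that("Fisher matrix is symmetric and equivariant under relabeling", {
  cb <- small_basis()
  src <- point_comb(4, 0.6, amplitudes = c(1, 2, 3, 4))
  modes <- mode_set(qr.Q(qr(matrix(rnorm(cb$size * 4), cb$size))), cb)
  pt <- probability_tensor(src$basis, modes)
  I <- fisher_matrix(src$c, pt)
  expect_identical(I, t(I))
  perm <- c(3, 1, 4, 2)
  Ip <- fisher_matrix(src$c[perm], unclass(pt)[, perm])
  expect_equal(Ip, I[perm, perm], tolerance = 1e-12)
})

test_that("Fisher matrix matches the expected Poisson log-likelihood curvature", {
  # oracle: numerical Hessian of the expected log-likelihood
  # E l(c) = sum_j [mu_j(c0) log mu_j(c) - mu_j(c)], FIM = -Hessian at c0
  set.seed(7)
  for (rep in 1:4) {
    K <- sample(2:4, 1); J <- sample(K:4, 1)
    p <- matrix(runif(J * K, 0.05, 1), J, K)
    c0 <- runif(K, 0.3, 1.5)
    mu <- function(c) as.numeric(p %*% c)
    El <- function(c) sum(mu(c0) * log(mu(c)) - mu(c))
    h <- 1e-4
    H <- matrix(0, K, K)
    for (i in 1:K) for (j in 1:K) {
      ei <- ej <- rep(0, K); ei[i] <- h; ej[j] <- h
      H[i, j] <- (El(c0 + ei + ej) - El(c0 + ei - ej) -
                    El(c0 - ei + ej) + El(c0 - ei - ej)) / (4 * h^2)
    }
    I <- fisher_matrix(c0, p)
    expect_lt(max(abs(I + H)) / max(abs(I)), 1e-5)
  }
})

test_that("adding an imaging mode never loses information", {
  cb <- small_basis()
  src <- point_comb(3, 0.5)
  V <- qr.Q(qr(matrix(rnorm(cb$size * 4), cb$size)))
  I3 <- fisher_matrix(src$c, probability_tensor(src$basis, mode_set(V[, 1:3], cb)))
  I4 <- fisher_matrix(src$c, probability_tensor(src$basis, mode_set(V, cb)))
  set.seed(11)
  for (i in 1:10) {
    v <- rnorm(3)
    expect_gte(sum(v * (I4 %*% v)), sum(v * (I3 %*% v)) - 1e-10)
  }
})

test_that("crb_objective handles identity, diagonal and random SPD cases", {
  r <- crb_objective(diag(5))
  expect_equal(r$value, 5)
  expect_equal(r$crb_diag, rep(1, 5))
  r2 <- crb_objective(diag(c(4, 1)))
  expect_equal(r2$value, 1.25)
  expect_equal(r2$crb_diag, c(0.25, 1))
  for (seed in 1:5) {
    I <- random_spd(6, seed)
    r3 <- crb_objective(I)
    expect_equal(r3$crb_diag, diag(solve(I)), tolerance = 1e-9)
    expect_true(all(r3$crb_diag >= 1 / diag(I) - 1e-12))  # CRB dominance
  }
  expect_error(crb_objective(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("well-separated point sources decouple into independent single-source problems", {
  cb <- computation_basis(psf1, 64)
  src <- point_comb(5, 5)
  dm <- direct_imaging_modes(cb, 0.5, src$basis$extent + 5)
  crb5 <- mean_crb(src, dm)
  single <- point_comb(1, 1, amplitudes = 1, normalize = FALSE)
  single$c <- 0.2   # same per-source brightness as the comb
  crb1 <- mean_crb(single, dm)   # identical pixel grid
  expect_lt(abs(crb5 - crb1) / crb1, 0.05)
})

test_that("resolution_gain recovers synthetic shifts and the identity", {
  sc <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  crb <- 10^(5 - 4 * sc)
  d <- data.frame(scale = sc, crb = crb)
  expect_equal(as.numeric(resolution_gain(d, d)), 1, tolerance = 1e-10)
  m <- data.frame(scale = sc / 2, crb = crb)
  expect_equal(as.numeric(resolution_gain(d, m)), 2, tolerance = 1e-10)
  far <- data.frame(scale = sc, crb = crb * 1e12)
  expect_error(resolution_gain(d, far), "no CRB range")
})

test_that("whitened CRB evaluation agrees with the plain inverse on benign problems", {
  cb <- small_basis(40)
  src <- extended_source("bump", 2, 4, normalize = TRUE)
  Tw <- whitening_transform(src, cb)
  dm <- direct_imaging_modes(cb, 0.5, 7)
  pt <- probability_tensor(src$basis, dm)
  plain <- crb_objective(fisher_matrix(src$c, pt))$crb_diag
  white <- crb_diag_whitened(src$c, pt, Tw)
  expect_equal(white, plain, tolerance = 1e-6)
})
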