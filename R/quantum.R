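#' Single-photon density operator of an incoherent source
#'
#' Assembles the (per detected photon) density matrix of the image-plane field
#' as the incoherent mixture of shifted-PSF pure states weighted by the source
#' brightness, represented in the truncated Hermite-Gaussian basis:
#' `rho = sum_k c_k A_k / tr(sum_k c_k A_k)` with
#' `A_k = integral over bin k of |psi_R><psi_R| dR` (for delta modes, the
#' outer product at the point position). The coefficient derivatives are those
#' of the unnormalized brightness family evaluated at the unit-flux point,
#' `drho_k = A_k / tr(rho_unnorm)`: this convention retains the photon-number
#' information carried by the total flux, exactly as the classical per-photon
#' Poisson Fisher matrix does, so classical and quantum bounds are directly
#' comparable per photon.
#'
#' @param source A source model (unit-flux normalized coefficients recommended).
#' @param cbasis A [computation_basis()]. Truncation is checked: a captured-
#'   energy deficit above `trace_tol` at the source extent is an error.
#' @param nq Quadrature nodes per bin.
#' @param trace_tol Maximum tolerated truncation deficit (default 1e-4).
#' @param c_floor Relative floor applied to zero coefficients before mixing
#'   (default 0 = exact coefficients). A zero-amplitude bin is a boundary
#'   point of the model where both classical and quantum information diverge;
#'   curve computations evaluate both bounds at the same floored point.
#' @return List with `rho` (size x size), `drho` (list of K matrices),
#'   `trace_raw` (trace before normalization), `lambda`, `U` (eigensystem).
#' @export
source_density <- function(source, cbasis, nq = 12, trace_tol = 1e-4,
                           c_floor = 0) {
  if (c_floor > 0)
    source <- new_source_model(source$basis,
                               floor_coefficients(source$c, c_floor))
  basis <- source$basis
  q <- basis_quadrature(basis, nq)
  G <- psf_coefficients(cbasis, q$nodes)
  deficit <- 1 - min(colSums(G * G))
  if (deficit > trace_tol)
    stop(sprintf("basis truncation too severe: captured-energy deficit %.3g (increase M)",
                 deficit))
  K <- basis$K
  drho <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- q$bin == k
    Gk <- G[, sel, drop = FALSE]
    drho[[k]] <- Gk %*% (q$w[sel] * t(Gk))
  }
  rho_u <- Reduce(`+`, Map(`*`, drho, source$c))
  tr <- sum(diag(rho_u))
  if (tr <= 0) stop("source has no captured flux")
  rho <- (rho_u + t(rho_u)) / (2 * tr)
  drho <- lapply(drho, function(A) (A + t(A)) / (2 * tr))
  eg <- eigen(rho, symmetric = TRUE)
  list(rho = rho, drho = drho, trace_raw = tr,
       lambda = eg$values, U = eg$vectors, K = K)
}

#' Symmetric logarithmic derivatives and the quantum Fisher matrix
#'
#' In the eigenbasis of `rho` the SLD of coefficient `k` is
#' `L_k[q, p] = 2 <e_q| drho_k |e_p> / (lambda_q + lambda_p)` over eigenpairs
#' with `lambda_q + lambda_p` above `support_tol`, and the quantum Fisher
#' information matrix is `Q[k, l] = Re tr(L_k L_l rho)`. The quantum
#' Cramer-Rao bound on each coefficient is the corresponding diagonal of
#' `solve(Q)`. Attainability diagnostics are attached: the weak-commutativity
#' residual `max |tr(rho [L_i, L_j])|` (identically ~0 for incoherent
#' sources — states and SLDs are real symmetric here) and the worst SLD
#' defining-equation residual on the support of `rho`.
#'
#' @param dens Output of [source_density()].
#' @param support_tol Eigenpair threshold for the SLD sum (default 1e-12).
#' @return List with `qfim` (K x K), `qcrb_diag`, `mean_qcrb`, `sld` (list of
#'   SLDs in the eigenbasis), `weak_commutativity`, `sld_residual`.
#' @export
sld_qfim <- function(dens, support_tol = 1e-12) {
  lam <- pmax(dens$lambda, 0)
  U <- dens$U
  M <- length(lam); K <- dens$K
  D <- outer(lam, lam, `+`)
  mask <- D > support_tol
  Dm <- ifelse(mask, D, Inf)
  Et <- lapply(dens$drho, function(A) crossprod(U, A) %*% U)
  H <- vapply(Et, function(E) as.numeric(E / sqrt(Dm)), numeric(M * M))
  qfim <- 2 * crossprod(H)
  qfim <- (qfim + t(qfim)) / 2
  sld <- lapply(Et, function(E) 2 * ifelse(mask, E / Dm, 0))
  # diagnostics on the support of rho
  sup <- lam > support_tol
  res <- 0
  for (k in seq_len(K)) {
    R <- dens$drho[[k]]
    Rk <- crossprod(U, R) %*% U
    recon <- (sld[[k]] * matrix(lam, M, M, byrow = TRUE) +
                matrix(lam, M, M) * sld[[k]]) / 2
    res <- max(res, max(abs((Rk - recon)[sup, sup])))
  }
  wc <- 0
  if (K >= 2) {
    # tr(rho [L_i, L_j]) with tr(Lambda A B) = sum((lam * A) * t(B))
    kk <- min(K, 6)
    for (i in seq_len(kk - 1)) for (j in (i + 1):kk)
      wc <- max(wc, abs(sum((lam * sld[[i]]) * t(sld[[j]])) -
                          sum((lam * sld[[j]]) * t(sld[[i]]))))
  }
  ch <- tryCatch(chol(qfim), error = function(e) NULL)
  if (!is.null(ch)) {
    qinv <- chol2inv(ch)
  } else {
    s <- 1 / sqrt(pmax(diag(qfim), .Machine$double.xmin))
    eg <- eigen(qfim * outer(s, s), symmetric = TRUE)
    if (any(eg$values <= max(eg$values) * 1e-14))
      stop("quantum Fisher matrix is singular: unidentifiable parameter combination")
    qinv <- (eg$vectors %*% (t(eg$vectors) / eg$values)) * outer(s, s)
  }
  list(qfim = qfim, qcrb_diag = diag(qinv), mean_qcrb = mean(diag(qinv)),
       sld = sld, weak_commutativity = wc, sld_residual = res)
}

#' Mean quantum CRB of a source
#'
#' @inheritParams source_density
#' @param c_floor Evaluation-point floor (see [source_density()]).
#' @return Mean of the QCRB diagonal over the K coefficients.
#' @export
mean_qcrb <- function(source, cbasis, nq = 12, c_floor = 0) {
  sld_qfim(source_density(source, cbasis, nq = nq, c_floor = c_floor))$mean_qcrb
}

#' Quantum whitening transform of the coefficient space
#'
#' Returns `T = qfim^(-1/2)` (symmetric inverse square root of the quantum
#' Fisher matrix). In the coordinates `theta = T^-1 c` every classical Fisher
#' matrix satisfies `0 <= T' I T <= 1` (the quantum bound), so near-optimal
#' mode sets have a whitened information matrix with eigenvalues of order
#' one: assembling Fisher matrices from `T`-transformed design rows sidesteps
#' the enormous dynamic range of the raw sub-Rayleigh information and is the
#' numerically sound way to evaluate and optimize CRBs deep below the
#' diffraction limit.
#'
#' @inheritParams source_density
#' @param floor_rel Eigenvalues of the quantum Fisher matrix below
#'   `floor_rel * max` are clipped before the inverse square root (those
#'   directions are quantum-unidentifiable at working precision).
#' @param c_floor Evaluation-point floor for the density operator (default
#'   1e-6, matching the classical Fisher evaluation).
#' @return A symmetric `K x K` matrix with attributes `qfim` and `qcrb_diag`.
#' @export
whitening_transform <- function(source, cbasis, nq = 12, floor_rel = 1e-13,
                                c_floor = 1e-6) {
  qb <- sld_qfim(source_density(source, cbasis, nq = nq, c_floor = c_floor))
  eg <- eigen(qb$qfim, symmetric = TRUE)
  lam <- pmax(eg$values, max(eg$values) * floor_rel)
  T <- eg$vectors %*% (t(eg$vectors) / sqrt(lam))
  structure((T + t(T)) / 2, qfim = qb$qfim, qcrb_diag = qb$qcrb_diag)
}
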