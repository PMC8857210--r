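#' Orthonormal imaging-mode sets
#'
#' A set of `J` orthonormal spatial imaging modes is represented by the
#' `size x J` coefficient matrix `V` of the modes over the Hermite-Gaussian
#' computation basis. Orthonormality (`t(V) %*% V = I`) is then an algebraic
#' constraint: the feasible set is the Stiefel manifold.
#'
#' @param V Coefficient matrix with orthonormal columns.
#' @param cbasis The [computation_basis()] the coefficients refer to.
#' @param label Optional strategy label (e.g. `"direct"`, `"mospade"`).
#' @return An object of class `mospade_modes`.
#' @export
mode_set <- function(V, cbasis, label = NULL) {
  V <- as.matrix(V)
  stopifnot(inherits(cbasis, "mospade_cbasis"), nrow(V) == cbasis$size,
            ncol(V) <= nrow(V))
  defect <- orthonormality_defect(V)
  if (defect > 1e-8)
    stop(sprintf("mode coefficients are not orthonormal (defect %.3g)", defect))
  structure(list(V = V, J = ncol(V), cbasis = cbasis, label = label),
            class = "mospade_modes")
}

#' Orthonormality defect of a coefficient matrix
#' @param V Matrix whose columns should be orthonormal.
#' @return `max(abs(t(V) %*% V - I))`.
#' @export
orthonormality_defect <- function(V) {
  max(abs(crossprod(V) - diag(ncol(V))))
}

#' @export
print.mospade_modes <- function(x, ...) {
  cat(sprintf("Imaging mode set: J = %d modes over %d HG basis functions%s\n",
              x$J, nrow(x$V),
              if (is.null(x$label)) "" else sprintf(" [%s]", x$label)))
  cat(sprintf("  orthonormality defect %.2e\n", orthonormality_defect(x$V)))
  invisible(x)
}

# QR orthonormalization with the sign of diag(R) fixed positive, so results
# are deterministic and continuous in the input.
qr_orthonormalize <- function(X, ncols = ncol(X)) {
  k <- qr(X)
  Q <- qr.Q(k, complete = FALSE)
  s <- sign(diag(qr.R(k)))
  s[s == 0] <- 1
  Q <- sweep(Q, 2, s[seq_len(ncol(Q))], `*`)
  Q[, seq_len(ncols), drop = FALSE]
}

#' Direct-imaging (pixel-basis) mode set
#'
#' Conventional position-basis detection modeled as a tiling of the image
#' plane by indicator pixels of width `pixel_width` over `[-extent, extent)`,
#' projected onto the computation basis and re-orthonormalized. Fine pixels
#' approach continuum direct imaging; use the self-convergence of the CRB
#' under pixel halving as the resolution check. In 2D the pixels are squares.
#'
#' @param cbasis A [computation_basis()].
#' @param pixel_width Pixel width in units of sigma (> 0).
#' @param extent Half-width of the detector region. Must cover the source
#'   support plus a few sigma of PSF spread.
#' @param nq Quadrature nodes per pixel for the projection integrals.
#' @return A `mospade_modes` with `label = "direct"` and attribute `pixels`
#'   (pixel edges).
#' @export
direct_imaging_modes <- function(cbasis, pixel_width, extent, nq = 20) {
  stopifnot(pixel_width > 0, extent > 0)
  if (2 * extent < 4 * cbasis$sigma)
    warning("detector extent is smaller than the PSF support; flux will be lost")
  n <- max(1L, as.integer(round(2 * extent / pixel_width)))
  edges <- -extent + (0:n) * (2 * extent / n)
  U1 <- matrix(0, cbasis$M, n)
  for (i in seq_len(n)) {
    gl <- pracma::gaussLegendre(nq, edges[i], edges[i + 1])
    phi <- hg_eval_1d(gl$x, cbasis$sigma, cbasis$M)
    U1[, i] <- as.numeric(phi %*% gl$w) / sqrt(edges[i + 1] - edges[i])
  }
  if (cbasis$dim == 1) {
    if (n > cbasis$M)
      stop("more pixels than computation-basis functions; increase M or pixel width")
    V <- qr_orthonormalize(U1)
  } else {
    if (n^2 > cbasis$M^2)
      stop("more pixels than computation-basis functions; increase M or pixel width")
    U <- matrix(0, cbasis$M^2, n^2)
    for (j in seq_len(n)) for (i in seq_len(n))
      U[, (j - 1) * n + i] <- kronecker(U1[, i], U1[, j])
    V <- qr_orthonormalize(U)
  }
  out <- mode_set(V, cbasis, label = "direct")
  attr(out, "pixels") <- edges
  out
}

#' Matched-mode initialization for the optimizer
#'
#' Builds a feasible starting point from the source itself: the images of the
#' source modes (shifted PSFs for point sources, bin-integrated PSF images for
#' rectangle bins) weighted by the current coefficient estimate. For
#' `J >= K` the orthonormalized images are completed with computation-basis
#' columns; for `J < K` the leading `J` left singular vectors of the weighted
#' image matrix are used.
#'
#' @param source A source model (its `c` is the evaluation/estimate vector).
#' @param cbasis A [computation_basis()].
#' @param J Number of modes.
#' @param nq Per-bin quadrature nodes for rectangle bases.
#' @return A `mospade_modes`.
#' @export
matched_mode_init <- function(source, cbasis, J, nq = 12) {
  basis <- source$basis
  q <- basis_quadrature(basis, nq)
  G <- psf_coefficients(cbasis, q$nodes)
  # bin-image columns: integral of the shifted-PSF coefficients over each bin
  img <- matrix(0, cbasis$size, basis$K)
  for (k in seq_len(basis$K)) {
    sel <- q$bin == k
    img[, k] <- G[, sel, drop = FALSE] %*% q$w[sel]
  }
  if (J >= basis$K) {
    V <- qr_orthonormalize(cbind(img, diag(cbasis$size)), ncols = J)
  } else {
    wts <- pmax(source$c, max(source$c) * 1e-3)
    sv <- svd(img %*% diag(wts, basis$K), nu = J, nv = 0)
    V <- qr_orthonormalize(sv$u)
  }
  mode_set(V, cbasis, label = "matched-init")
}

#' Principal-mode initialization from the source density operator
#'
#' Takes the leading `J` eigenvectors of the single-photon density operator of
#' the source estimate — the principal modes of the PSF-blurred scene — and
#' mixes successive pairs by a 45-degree rotation. The rotation deliberately
#' breaks the parity degeneracy of a symmetric scene (pure parity eigenmodes
#' yield detection probabilities blind to left/right, i.e. a singular Fisher
#' matrix); the mixed modes are localized half-scene wave packets and make an
#' excellent deterministic starting point deep in the sub-Rayleigh regime.
#'
#' @param source Source model (coefficients = evaluation point).
#' @param cbasis A [computation_basis()].
#' @param J Number of modes (`J <= cbasis$size`).
#' @param nq Per-bin quadrature nodes.
#' @return A `mospade_modes`.
#' @export
eigenmode_init <- function(source, cbasis, J, nq = 12) {
  dens <- source_density(source, cbasis, nq = nq)
  U <- dens$U[, seq_len(J), drop = FALSE]
  if (J >= 2) for (j in seq(1, J - 1, by = 2)) {
    a <- U[, j]; b <- U[, j + 1]
    U[, j] <- (a + b) / sqrt(2); U[, j + 1] <- (a - b) / sqrt(2)
  }
  mode_set(qr_orthonormalize(U), cbasis, label = "eigenmode-init")
}

#' SLD signal-mode initialization
#'
#' For each source coefficient, the top eigenvector of `L_k rho L_k` — the
#' state component actually carrying that parameter's information, with `L_k`
#' the symmetric logarithmic derivative — is collected, together with the
#' brightest eigenmode of `rho`, and the set is orthonormalized. Deep in the
#' sub-Rayleigh regime this start already extracts most of the quantum-
#' attainable information and is the strongest initialization known to the
#' package.
#'
#' @inheritParams eigenmode_init
#' @param c_floor Relative floor applied to the coefficients before building
#'   the density operator (zero-amplitude bins are boundary points of the
#'   model; see [fisher_matrix()]).
#' @return A `mospade_modes`.
#' @export
sld_signal_init <- function(source, cbasis, J, nq = 12, c_floor = 1e-6) {
  srcf <- new_source_model(source$basis, floor_coefficients(source$c, c_floor))
  dens <- source_density(srcf, cbasis, nq = nq)
  qb <- sld_qfim(dens)
  lam <- pmax(dens$lambda, 0)
  K <- source$basis$K
  sig <- vapply(seq_len(K), function(k) {
    S <- qb$sld[[k]] %*% (lam * t(qb$sld[[k]]))
    eigen((S + t(S)) / 2, symmetric = TRUE)$vectors[, 1]
  }, numeric(length(lam)))
  cols <- cbind(dens$U %*% sig, dens$U[, seq_len(max(1, J - K)), drop = FALSE])
  mode_set(qr_orthonormalize(cols, ncols = min(J, ncol(cols))), cbasis,
           label = "sld-signal-init")
}

#' Parity-mixed Hermite-Gaussian ladder initialization
#'
#' The first `J` Hermite-Gaussian computation-basis modes with successive
#' even/odd pairs mixed by 45 degrees. The plain HG ladder measures the
#' symmetric moments of a sub-diffraction scene nearly optimally but is blind
#' to parity; the pairwise mixing restores left/right sensitivity.
#'
#' @param cbasis A [computation_basis()].
#' @param J Number of modes.
#' @return A `mospade_modes`.
#' @export
hg_ladder_init <- function(cbasis, J) {
  U <- diag(cbasis$size)[, seq_len(J), drop = FALSE]
  if (J >= 2) for (j in seq(1, J - 1, by = 2)) {
    a <- U[, j]; b <- U[, j + 1]
    U[, j] <- (a + b) / sqrt(2); U[, j + 1] <- (a - b) / sqrt(2)
  }
  mode_set(U, cbasis, label = "hg-ladder-init")
}

#' Render 1D imaging modes on a position grid
#' @param modes A `mospade_modes` over a 1D basis.
#' @param x Positions at which to evaluate.
#' @return A `length(x) x J` matrix of mode profiles.
#' @export
render_modes <- function(modes, x) {
  stopifnot(modes$cbasis$dim == 1)
  phi <- hg_eval_1d(x, modes$cbasis$sigma, modes$cbasis$M)
  t(phi) %*% modes$V
}
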