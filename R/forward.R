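#' Modal detection-probability tensor
#'
#' Per-unit-coefficient detection probabilities
#' `p[j, k] = integral over bin k of |<phi_j | psi_R>|^2 dR`
#' (for delta source modes, the integrand evaluated at the point position), so
#' that the probability of detecting a photon in imaging mode `j` is the
#' linear form `P_j = sum_k c_k p[j, k]`. Overlaps are evaluated through the
#' closed-form Hermite-Gaussian expansion of the shifted PSF; bin integrals
#' use per-bin Gauss-Legendre rules.
#'
#' @param basis A source basis (from a source model: `source$basis`).
#' @param modes A [mode_set()].
#' @param nq Quadrature nodes per bin (per axis in 2D).
#' @return A `J x K` matrix of class `mospade_ptensor` with attributes
#'   `s` (captured quadrature mass of each source mode within the truncated
#'   basis) and `quad` (the quadrature used).
#' @export
probability_tensor <- function(basis, modes, nq = 12) {
  stopifnot(inherits(modes, "mospade_modes"))
  if (basis$dim != modes$cbasis$dim)
    stop("source basis and mode set have different dimensions")
  q <- basis_quadrature(basis, nq)
  G <- psf_coefficients(modes$cbasis, q$nodes)
  A <- crossprod(modes$V, G)              # J x Q mode amplitudes
  S <- A * A
  B <- bin_weight_matrix(q, basis$K)      # Q x K
  p <- S %*% B
  s <- as.numeric(colSums(G * G) %*% B)   # captured mass per source mode
  structure(p, class = c("mospade_ptensor", class(p)), s = s,
            quad = list(nq = nq), J = modes$J, K = basis$K)
}

bin_weight_matrix <- function(q, K) {
  Q <- length(q$w)
  B <- matrix(0, Q, K)
  B[cbind(seq_len(Q), q$bin)] <- q$w
  B
}

#' Detection probabilities of a source through a mode set
#'
#' `P_j = sum_k c_k p[j, k]` — linear in the coefficients.
#'
#' @param source A source model (or a bare non-negative coefficient vector).
#' @param pt A [probability_tensor()] built on the same source basis.
#' @return Length-`J` vector of per-photon detection probabilities.
#' @export
detection_probs <- function(source, pt) {
  c <- if (inherits(source, "mospade_source")) source$c else as.numeric(source)
  if (any(c < 0)) stop("source coefficients must be non-negative")
  if (length(c) != ncol(pt)) stop("coefficient length does not match the tensor")
  as.numeric(pt %*% c)
}
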