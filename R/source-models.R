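#' Orthogonal source-mode bases
#'
#' An incoherent source brightness `F(R)` is decomposed over a finite set of
#' `K` mutually orthogonal source modes `f_k`: a Dirac comb (point sources at
#' known locations), a tiling of half-open 1D rectangle bins `[left, right)`,
#' or a grid of 2D square bins. Rectangle modes are unit-height indicator
#' functions (not unit L2 norm), so the coefficients `c_k` are brightnesses
#' per bin and non-negative least-squares estimates of them are directly
#' interpretable.
#'
#' @name source_basis
#' @keywords internal
NULL

new_source_basis <- function(kind, dim, K, positions = NULL, edges = NULL,
                             width = NA_real_, extent = NA_real_, grid_n = NA_integer_) {
  structure(list(kind = kind, dim = dim, K = as.integer(K), positions = positions,
                 edges = edges, width = width, extent = extent, grid_n = grid_n),
            class = "mospade_source_basis")
}

new_source_model <- function(basis, c) {
  c <- as.numeric(c)
  if (length(c) != basis$K)
    stop(sprintf("coefficient vector has length %d but the basis has K = %d modes",
                 length(c), basis$K))
  if (any(!is.finite(c))) stop("source coefficients must be finite")
  if (any(c < 0)) stop("source coefficients must be non-negative")
  structure(list(basis = basis, c = c), class = "mospade_source")
}

#' @export
print.mospade_source <- function(x, ...) {
  b <- x$basis
  cat(sprintf("Incoherent source model: %s basis, K = %d, dim = %d\n", b$kind, b$K, b$dim))
  cat(sprintf("  total flux %.6g, %d nonzero coefficients\n",
              source_flux(x), sum(x$c > 0)))
  invisible(x)
}

# flux integral of F(R): delta modes carry unit mass, rect bins carry width^dim
mode_mass <- function(basis) {
  switch(basis$kind,
         "delta-comb" = rep(1, basis$K),
         "rect-1d"    = diff(basis$edges),
         "rect-2d"    = rep(basis$width^2, basis$K))
}

#' Total flux of a source model
#' @param source A source model.
#' @return `sum(c_k * mass_k)` where `mass_k` is 1 for delta modes and the bin
#'   area for rectangle modes.
#' @export
source_flux <- function(source) sum(source$c * mode_mass(source$basis))

#' Equidistant point-source comb
#'
#' A line of `n_points` point sources with spacing `dx`, centered on the
#' origin, as used for sub-Rayleigh brightness estimation of sources whose
#' locations are known a priori. The source modes are Dirac deltas at the
#' point positions; the estimation task is the amplitude vector.
#'
#' @param n_points Number of point sources (>= 1).
#' @param dx Spacing between adjacent sources, in units of the PSF sigma.
#' @param amplitudes Non-negative amplitudes, length `n_points`.
#' @param normalize If `TRUE` (default), rescale amplitudes to unit total flux
#'   so per-photon detection probabilities are on the correct scale.
#' @return A `mospade_source`.
#' @export
#' @examples
#' point_comb(5, 0.3)              # the 5-point sub-Rayleigh test scene
point_comb <- function(n_points, dx, amplitudes = rep(1, n_points), normalize = TRUE) {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 1, dx > 0)
  if (length(amplitudes) != n_points)
    stop(sprintf("amplitudes has length %d but n_points = %d", length(amplitudes), n_points))
  pos <- (seq_len(n_points) - (n_points + 1) / 2) * dx
  basis <- new_source_basis("delta-comb", 1L, n_points, positions = pos,
                            extent = max(abs(pos)))
  c <- as.numeric(amplitudes)
  if (normalize && sum(c) > 0) c <- c / sum(c)
  new_source_model(basis, c)
}

#' Named 1D extended-source profiles
#'
#' Parametrized stand-ins for smooth finite-extent test sources: a uniform
#' plateau, a raised-cosine bump and an asymmetric double bump, all supported
#' on `[-8, 8]` sigma (so with `a = 0.8` sigma bins tiling `+/-12` sigma,
#' exactly bins 6..25 of 30 carry nonzero amplitude).
#'
#' @param name One of `"uniform"`, `"bump"`, `"double_bump"`.
#' @return A vectorized profile function of position (units of sigma).
#' @export
fixture_profile <- function(name = c("uniform", "bump", "double_bump")) {
  name <- match.arg(name)
  lobe <- function(x, center, halfwidth)
    ifelse(abs(x - center) < halfwidth,
           (1 + cos(pi * (x - center) / halfwidth)) / 2, 0)
  switch(name,
         uniform = function(x) as.numeric(abs(x) <= 8),
         bump = function(x) lobe(x, 0, 8),
         double_bump = function(x) lobe(x, -4, 3.5) + 0.75 * lobe(x, 4, 3.5))
}

#' Discretize an extended 1D source into rectangle bins
#'
#' Tiles `[-extent, extent)` with `K = 2 * extent / a` half-open bins of width
#' `a` and sets each coefficient to the mean of `profile` over its bin
#' (Gauss-Legendre quadrature), clipped at zero.
#'
#' @param profile A function of position, or a name accepted by
#'   [fixture_profile()].
#' @param a Bin width (units of sigma), > 0.
#' @param extent Half-width of the discretized region (units of sigma);
#'   `2 * extent` must be an integer multiple of `a` (within rounding).
#' @param normalize Rescale to unit total flux (default `TRUE`).
#' @param nq Quadrature nodes per bin for the bin average.
#' @return A `mospade_source`.
#' @export
#' @examples
#' extended_source("bump", a = 0.8, extent = 12)   # 30 bins, 20 nonzero
extended_source <- function(profile, a, extent = 12, normalize = TRUE, nq = 24) {
  stopifnot(a > 0, 2 * extent >= a)
  if (is.character(profile)) profile <- fixture_profile(profile)
  K <- round(2 * extent / a)
  if (abs(2 * extent / a - K) > 1e-9)
    stop("bins of width a must tile [-extent, extent] exactly")
  edges <- -extent + a * (0:K)
  basis <- new_source_basis("rect-1d", 1L, K, edges = edges, width = a, extent = extent)
  c <- vapply(seq_len(K), function(k) {
    gl <- pracma::gaussLegendre(nq, edges[k], edges[k + 1])
    v <- profile(gl$x)
    if (any(!is.finite(v))) stop("profile returned non-finite values")
    sum(gl$w * v) / a
  }, numeric(1))
  c <- pmax(c, 0)
  if (normalize && sum(c) > 0) c <- c / (sum(c) * a)
  new_source_model(basis, c)
}

#' Michelson contrast of a coefficient vector
#'
#' `(max - min) / (max + min)` of the brightness values; the standard
#' characterization of low-contrast scenes.
#'
#' @param c Non-negative brightness values (vector or matrix).
#' @export
michelson_contrast <- function(c) {
  r <- range(c)
  if (sum(r) == 0) return(0)
  (r[2] - r[1]) / (r[2] + r[1])
}

#' Low-contrast 2D test scenes
#'
#' Generates a `grid_n x grid_n` square-bin discretization of a low-contrast
#' 2D pattern atop a uniform background: a radial frequency chirp
#' (`cos(freq * r^2)`, quadratic phase in radius) or an `spokes`-spoke Siemens
#' star (`cos(spokes * theta)`). The modulation depth is solved so that the
#' Michelson contrast of the generated coefficients equals `contrast` exactly.
#'
#' @param pattern `"chirp"` or `"siemens"`.
#' @param grid_n Bins per side (>= 2).
#' @param bin_width Bin width in units of sigma.
#' @param contrast Requested Michelson contrast in `[0, 1]`.
#' @param background Uniform background level (> 0 whenever `contrast < 1`).
#' @param spokes Number of Siemens-star spokes (default 8).
#' @param chirp_freq Chirp rate in rad / sigma^2 (default tuned so the local
#'   spatial period falls below the Rayleigh scale near the scene edge).
#' @param normalize Rescale to unit total flux (default `TRUE`).
#' @return A `mospade_source` with a rect-2d basis of `grid_n^2` modes
#'   (column-major bin order).
#' @export
#' @examples
#' s <- scene_2d("siemens", grid_n = 24, bin_width = 0.9, contrast = 0.025)
#' michelson_contrast(s$c)
scene_2d <- function(pattern = c("chirp", "siemens"), grid_n, bin_width,
                     contrast, background = 1, spokes = 8, chirp_freq = NULL,
                     normalize = TRUE) {
  pattern <- match.arg(pattern)
  grid_n <- as.integer(grid_n)
  stopifnot(grid_n >= 2, bin_width > 0, contrast >= 0, contrast <= 1)
  if (contrast < 1 && background <= 0)
    stop("a contrast below 1 requires a positive background level")
  extent <- grid_n * bin_width / 2
  centers <- -extent + bin_width * (seq_len(grid_n) - 0.5)
  xy <- expand.grid(x = centers, y = centers)   # column-major: x fastest
  v <- if (contrast == 0) {
    rep(0, nrow(xy))
  } else if (pattern == "chirp") {
    if (is.null(chirp_freq)) chirp_freq <- pi / (2 * extent)
    r2 <- xy$x^2 + xy$y^2
    cos(chirp_freq * r2)
  } else {
    th <- atan2(xy$y, xy$x)
    cos(spokes * th)
  }
  if (contrast == 0) {
    c <- rep(background, nrow(xy))
  } else {
    vmax <- max(v); vmin <- min(v)
    # solve m in: contrast = m (vmax - vmin) / (2 + m (vmax + vmin)), values bg (1 + m v)
    den <- (vmax - vmin) - contrast * (vmax + vmin)
    if (den <= 0) stop("requested contrast is incompatible with this pattern/background")
    m <- 2 * contrast / den
    c <- background * (1 + m * v)
    if (any(c < 0)) stop("requested contrast is incompatible with the background level")
  }
  basis <- new_source_basis("rect-2d", 2L, grid_n^2, width = bin_width,
                            extent = extent, grid_n = grid_n)
  if (normalize && sum(c) > 0) c <- c / (sum(c) * bin_width^2)
  new_source_model(basis, c)
}

#' Arrange 2D scene coefficients as an image matrix
#' @param source A rect-2d source model (or a coefficient vector plus `grid_n`).
#' @param c Optional coefficient vector overriding `source$c` (same basis).
#' @return A `grid_n x grid_n` matrix (rows = x, columns = y).
#' @export
scene_matrix <- function(source, c = NULL) {
  stopifnot(source$basis$kind == "rect-2d")
  matrix(if (is.null(c)) source$c else c, source$basis$grid_n, source$basis$grid_n)
}

# Quadrature over the source support: nodes, weights, owning bin.
# Delta combs use the point positions with unit weight; rectangle bins use a
# per-bin Gauss-Legendre rule (tensor-product in 2D), which keeps bin
# membership exact for the half-open tiling.
basis_quadrature <- function(basis, nq = 12) {
  if (basis$kind == "delta-comb") {
    list(nodes = basis$positions, w = rep(1, basis$K), bin = seq_len(basis$K))
  } else if (basis$kind == "rect-1d") {
    nodes <- numeric(0); w <- numeric(0); bin <- integer(0)
    for (k in seq_len(basis$K)) {
      gl <- pracma::gaussLegendre(nq, basis$edges[k], basis$edges[k + 1])
      nodes <- c(nodes, gl$x); w <- c(w, gl$w); bin <- c(bin, rep(k, nq))
    }
    list(nodes = nodes, w = w, bin = bin)
  } else {
    n <- basis$grid_n; a <- basis$width; ext <- basis$extent
    nq1 <- max(4L, as.integer(ceiling(nq / 2)))
    lefts <- -ext + a * (0:(n - 1))
    glu <- pracma::gaussLegendre(nq1, 0, a)
    npb <- nq1^2
    nodes <- matrix(0, 2, n^2 * npb); w <- numeric(n^2 * npb); bin <- integer(n^2 * npb)
    wxy <- as.numeric(outer(glu$w, glu$w))
    for (j in seq_len(n)) for (i in seq_len(n)) {   # column-major (x fastest)
      k <- (j - 1) * n + i
      idx <- (k - 1) * npb + seq_len(npb)
      grid <- expand.grid(x = lefts[i] + glu$x, y = lefts[j] + glu$x)
      nodes[1, idx] <- grid$x; nodes[2, idx] <- grid$y
      w[idx] <- wxy; bin[idx] <- k
    }
    list(nodes = nodes, w = w, bin = bin)
  }
}
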