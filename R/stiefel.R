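#' Optimizer settings for Stiefel-manifold descent
#'
#' @param max_iters Maximum iterations (default 4000).
#' @param tol_f Relative objective-change tolerance: convergence when the
#'   relative decrease stays below this over `patience` consecutive iterations
#'   (default 1e-9).
#' @param tol_g Riemannian gradient-norm tolerance (default 1e-6).
#' @param patience Window for the objective-change test (default 25).
#' @param armijo Sufficient-decrease constant for backtracking (default 1e-4).
#' @param shrink Backtracking contraction factor (default 0.5).
#' @param max_backtracks Line-search backtracking cap (default 30).
#' @param restarts Number of additional random orthonormal restarts (default
#'   0; the matched/direct-derived start is usually excellent).
#' @param seed Seed for the random restarts.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(max_iters = 4000, tol_f = 1e-9, tol_g = 1e-6,
                             patience = 25, armijo = 1e-4, shrink = 0.5,
                             max_backtracks = 30, restarts = 0, seed = 1L) {
  stopifnot(max_iters >= 1, tol_f > 0, tol_g > 0, patience >= 1)
  structure(list(max_iters = as.integer(max_iters), tol_f = tol_f, tol_g = tol_g,
                 patience = as.integer(patience), armijo = armijo, shrink = shrink,
                 max_backtracks = as.integer(max_backtracks),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Build the CRB objective over mode sets
#'
#' Precomputes the forward-model context for a source basis and evaluation
#' coefficients and returns the objective `L(V) = tr(W %*% solve(I_tot))` with
#' `I_tot = prior_fim + weight * I(c; V)`, together with its Euclidean
#' gradient in `V`. The `prior_fim` term carries accumulated information from
#' earlier measurement periods (zero matrix for the single-period problem);
#' `weight` is the photon weight of the candidate period.
#'
#' @param source Source model holding the basis and evaluation coefficients
#'   (true values or the running estimate — never more than the caller knows).
#' @param cbasis A [computation_basis()].
#' @param W Weighting matrix (default identity).
#' @param prior_fim Accumulated `K x K` information from past periods, or `NULL`.
#' @param weight Photon weight multiplying the candidate-period information.
#' @param nq Quadrature nodes per bin.
#' @param c_floor Relative floor for zero coefficients (see [fisher_matrix()]).
#' @param drop_tol Detection probabilities below this are dropped.
#' @param transform Optional `K x K` parameter-space transform `T` (columns =
#'   new coordinate directions, `c = T theta`). The objective
#'   `tr(W I_c^-1)` is algebraically identical in the new coordinates but is
#'   computed as `tr((T' W T) I_theta^-1)` with `I_theta = T' I_c T`
#'   assembled directly from transformed design rows — with the quantum
#'   whitening `T = qfim^(-1/2)` (see [whitening_transform()]) `I_theta` is
#'   near-identity-scaled at the optimum, which removes the catastrophic
#'   conditioning of the raw sub-Rayleigh Fisher matrix.
#' @return List with functions `fn(V)`, `grad(V)`, and the context (`G`, `B`,
#'   `cf`, dimensions).
#' @export
mode_objective <- function(source, cbasis, W = NULL, prior_fim = NULL,
                           weight = 1, nq = 12, c_floor = 1e-6, drop_tol = 1e-15,
                           transform = NULL) {
  basis <- source$basis
  q <- basis_quadrature(basis, nq)
  G <- psf_coefficients(cbasis, q$nodes)
  B <- bin_weight_matrix(q, basis$K)
  cf <- floor_coefficients(source$c, c_floor)
  K <- basis$K
  I0 <- if (is.null(prior_fim)) matrix(0, K, K) else prior_fim
  if (!is.null(transform)) {
    B <- B %*% transform
    cf <- solve(transform, cf)
    W <- if (is.null(W)) crossprod(transform) else t(transform) %*% W %*% transform
    I0 <- t(transform) %*% I0 %*% transform
  }

  core <- function(V) {
    A <- crossprod(V, G)            # J x Q
    p <- (A * A) %*% B              # J x K
    P <- as.numeric(p %*% cf)
    keep <- P > drop_tol
    X <- p[keep, , drop = FALSE] / sqrt(P[keep])
    I <- I0 + weight * crossprod(X)
    list(A = A, p = p, P = P, keep = keep, I = (I + t(I)) / 2)
  }
  value_of <- function(I) {
    ch <- tryCatch(chol(I), error = function(e) NULL)
    if (!is.null(ch)) {
      Iinv <- chol2inv(ch)
    } else {
      # near-singular deep sub-Rayleigh information: equilibrated eigen-inverse
      s <- 1 / sqrt(pmax(diag(I), .Machine$double.xmin))
      eg <- tryCatch(eigen(I * outer(s, s), symmetric = TRUE),
                     error = function(e) NULL)
      if (is.null(eg) || any(eg$values <= max(eg$values) * 1e-14))
        return(list(value = Inf, Iinv = NULL))
      Iinv <- (eg$vectors %*% (t(eg$vectors) / eg$values)) * outer(s, s)
    }
    v <- if (is.null(W)) sum(diag(Iinv)) else sum(W * t(Iinv))
    if (!is.finite(v)) return(list(value = Inf, Iinv = NULL))
    list(value = v, Iinv = Iinv)
  }
  fn <- function(V) value_of(core(V)$I)$value
  grad <- function(V) {
    ctx <- core(V)
    vo <- value_of(ctx$I)
    if (!is.finite(vo$value)) stop("objective is singular at this point")
    Iinv <- vo$Iinv
    Lam <- if (is.null(W)) -(Iinv %*% Iinv) else {
      Z <- Iinv %*% W %*% Iinv; -(Z + t(Z)) / 2
    }
    p <- ctx$p; P <- ctx$P; keep <- ctx$keep
    Y <- p %*% Lam                              # J x K
    Gam <- matrix(0, nrow(p), ncol(p))
    u <- rowSums(Y[keep, , drop = FALSE] * p[keep, , drop = FALSE]) / P[keep]^2
    Gam[keep, ] <- 2 * Y[keep, , drop = FALSE] / P[keep] -
      outer(u, cf)
    dA <- 2 * ctx$A * (Gam %*% t(B))            # J x Q
    weight * (G %*% t(dA))                      # size x J
  }
  list(fn = fn, grad = grad, K = K, G = G, B = B, cf = cf, W = W,
       prior_fim = I0, weight = weight)
}

# project a Euclidean gradient to the tangent space of the Stiefel manifold
# at V (embedded metric): g - V sym(V' g)
riemannian_gradient <- function(V, g) {
  S <- crossprod(V, g)
  g - V %*% ((S + t(S)) / 2)
}

qr_retract <- function(X) qr_orthonormalize(X)

#' Minimize the CRB objective over the Stiefel manifold
#'
#' Riemannian Polak-Ribiere+ conjugate gradient on the log objective, with QR
#' retraction, projection vector transport and monotone Armijo backtracking.
#' Every iterate is exactly feasible (orthonormality defect below 1e-10); the
#' accepted objective sequence is non-increasing. On return the modes are
#' sorted by descending
#' detection probability at the evaluation coefficients and sign-fixed so
#' each mode's largest-magnitude coefficient is positive, making serialized
#' results reproducible.
#'
#' @param objective An objective context from [mode_objective()].
#' @param V0 Feasible starting point: a `mospade_modes` or a bare matrix with
#'   orthonormal columns.
#' @param cbasis The computation basis (taken from `V0` when it is a mode set).
#' @param config An [optimizer_config()].
#' @return A `mospade_modes` (label `"mospade"`) with attribute `trace`: a list
#'   holding per-iteration objective values, gradient norms, the final
#'   orthonormality defect and a convergence flag.
#' @export
optimize_modes <- function(objective, V0, cbasis = NULL,
                           config = optimizer_config()) {
  if (inherits(V0, "mospade_modes")) {
    if (is.null(cbasis)) cbasis <- V0$cbasis
    V0 <- V0$V
  }
  if (is.null(cbasis)) stop("cbasis must be supplied when V0 is a bare matrix")
  starts <- list(V0)
  if (config$restarts > 0) {
    rng <- local_rng(config$seed)
    for (r in seq_len(config$restarts))
      starts[[r + 1]] <- qr_orthonormalize(
        matrix(stats::rnorm(nrow(V0) * ncol(V0)), nrow(V0)))
    rng$restore()
  }
  best <- NULL
  for (V in starts) {
    res <- stiefel_descent(objective, V, config)
    if (is.null(best) || res$value < best$value) best <- res
  }
  V <- canonical_mode_order(best$V, objective)
  out <- mode_set(V, cbasis, label = "mospade")
  attr(out, "trace") <- best$trace
  out
}

# Riemannian conjugate gradient (Polak-Ribiere+ with projection transport,
# monotone Armijo backtracking, automatic steepest-descent restarts). The
# descent works on log(L): the objective spans many decades across the
# sub-Rayleigh regimes and the log makes steps and tolerances scale-free;
# monotonicity in log(L) is monotonicity in L. A start with a singular Fisher
# matrix (e.g. a parity-degenerate mode set) is nudged by seeded
# perturbations of growing size until the objective is finite.
stiefel_descent <- function(objective, V, config) {
  fraw <- objective$fn(V)
  scale <- 1e-6
  while (!is.finite(fraw) && scale < 0.5) {
    rng <- local_rng(config$seed)
    V <- qr_retract(V + scale * matrix(stats::rnorm(length(V)), nrow(V)))
    rng$restore()
    fraw <- objective$fn(V)
    scale <- scale * 20
  }
  if (!is.finite(fraw)) stop("objective is not finite at any perturbation of the starting point")
  log_grad <- function(V, fr)
    tryCatch(riemannian_gradient(V, objective$grad(V) / fr),
             error = function(e) NULL)
  f <- log(max(fraw, .Machine$double.xmin))
  g <- log_grad(V, fraw)
  if (is.null(g)) stop("objective gradient is singular at the starting point")
  d <- -g
  step <- 0.1 / max(sqrt(sum(g * g)), 1e-12)
  fvals <- numeric(0); gnorms <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iters)) {
    gn2 <- sum(g * g)
    fvals <- c(fvals, fraw); gnorms <- c(gnorms, sqrt(gn2))
    if (sqrt(gn2) < config$tol_g) { converged <- TRUE; break }
    if (it > config$patience) {
      recent <- fvals[(it - config$patience):it]
      if (max(abs(diff(recent))) < config$tol_f * max(abs(fraw), 1e-300)) {
        converged <- TRUE; break
      }
    }
    dg <- sum(d * g)
    if (!is.finite(dg) || dg > -1e-14 * sqrt(gn2 * sum(d * d))) {
      d <- -g; dg <- -gn2            # restart on a non-descent direction
    }
    t <- step; accepted <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      Vn <- qr_retract(V + t * d)
      fnraw <- objective$fn(Vn)
      if (is.finite(fnraw) && log(max(fnraw, .Machine$double.xmin)) <= f + config$armijo * t * dg) {
        accepted <- TRUE; break
      }
      t <- t * config$shrink
    }
    if (!accepted) {
      if (isTRUE(all.equal(d, -g))) { converged <- sqrt(gn2) < 1e-3; break }
      d <- -g; step <- 0.1 / sqrt(gn2)
      next
    }
    g_new <- log_grad(Vn, fnraw)
    if (is.null(g_new)) break                    # borderline-singular accept
    g_old <- riemannian_gradient(Vn, g)          # transported old gradient
    beta <- max(0, sum(g_new * (g_new - g_old)) / gn2)
    d <- -g_new + beta * riemannian_gradient(Vn, d)
    V <- Vn; fraw <- fnraw; f <- log(max(fraw, .Machine$double.xmin)); g <- g_new
    step <- 2 * t
  }
  list(V = V, value = fraw,
       trace = list(objective = fvals, grad_norm = gnorms,
                    objective_final = fraw,
                    final_defect = orthonormality_defect(V),
                    converged = converged, iterations = length(fvals)))
}

# deterministic presentation: sort modes by descending detection probability
# at the evaluation coefficients, fix signs
canonical_mode_order <- function(V, objective) {
  A <- crossprod(V, objective$G)
  p <- (A * A) %*% objective$B
  P <- as.numeric(p %*% objective$cf)
  V <- V[, order(P, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# isolated RNG scope: save and restore the global state around seeded draws
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

#' Optimize imaging modes for a known (or estimated) source
#'
#' Convenience wrapper for the single-period problem: given an evaluation
#' coefficient vector, find `J` orthonormal modes minimizing the mean CRB.
#' The CRB landscape is non-convex and, deep in the sub-Rayleigh regime,
#' spans many decades of conditioning, so the wrapper combines two numerical
#' defenses with a battery of physics-derived starting points:
#'
#' * unless `whiten = FALSE`, the objective is assembled in quantum-whitened
#'   coordinates (see [whitening_transform()]), in which any near-optimal
#'   information matrix is well conditioned;
#' * descent is run from each available initialization — [sld_signal_init()],
#'   [hg_ladder_init()], [matched_mode_init()] — with short re-descents until
#'   stagnation, and the best end point is returned.
#'
#' @inheritParams mode_objective
#' @param J Number of imaging modes.
#' @param V0 Optional starting point (skips the initialization battery).
#' @param config An [optimizer_config()].
#' @param whiten Use the quantum whitening transform (default: on for the
#'   single-period problem with identity weighting; off when a `prior_fim` or
#'   explicit `W` is supplied).
#' @return A `mospade_modes` with optimization trace attached.
#' @export
optimal_modes <- function(source, cbasis, J, V0 = NULL, W = NULL,
                          prior_fim = NULL, weight = 1, nq = 12,
                          c_floor = 1e-6, config = optimizer_config(),
                          whiten = is.null(prior_fim) && is.null(W),
                          transform = NULL) {
  Tw <- if (!is.null(transform)) transform
  else if (whiten)
    tryCatch(whitening_transform(source, cbasis, nq = nq, c_floor = max(c_floor, 1e-6)),
             error = function(e) NULL)
  else NULL
  obj <- mode_objective(source, cbasis, W = W, prior_fim = prior_fim,
                        weight = weight, nq = nq, c_floor = c_floor,
                        transform = Tw)
  polish <- function(res) {
    # re-descend with a fresh conjugate-gradient state until stagnation
    for (round in 1:5) {
      res2 <- optimize_modes(obj, res$V, cbasis = cbasis, config = config)
      better <- attr(res2, "trace")$objective_final <
        attr(res, "trace")$objective_final * (1 - 3e-4)
      res <- res2
      if (!better) break
    }
    res
  }
  if (!is.null(V0)) {
    if (inherits(V0, "mospade_modes")) V0 <- V0$V
    return(polish(optimize_modes(obj, V0, cbasis = cbasis, config = config)))
  }
  cands <- list()
  if (source$basis$kind != "delta-comb")
    cands$sld <- tryCatch(sld_signal_init(source, cbasis, J, nq = nq,
                                          c_floor = max(c_floor, 1e-6))$V,
                          error = function(e) NULL)
  cands$hg <- if (J <= cbasis$size) hg_ladder_init(cbasis, J)$V
  if (source$basis$kind == "delta-comb" || J < source$basis$K)
    cands$matched <- tryCatch(matched_mode_init(source, cbasis, J, nq = nq)$V,
                              error = function(e) NULL)
  cands <- Filter(Negate(is.null), cands)
  # one descent per start, then polish only the front-runner
  best <- NULL
  for (V0c in cands) {
    res <- tryCatch(optimize_modes(obj, V0c, cbasis = cbasis, config = config),
                    error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) ||
         attr(res, "trace")$objective_final < attr(best, "trace")$objective_final))
      best <- res
  }
  if (is.null(best)) stop("optimization failed from every starting point")
  polish(best)
}
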