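#' Non-negative least-squares source reconstruction
#'
#' Stacks all measurement periods into one linear system with design rows
#' `N_m * p_m[j, k]` (expected counts per unit coefficient) and observed
#' counts `y`, and solves `min_{c >= 0} || D (A c - y) ||^2` by Lawson-Hanson
#' NNLS. The default weighting is none (plain NNLS); `"poisson"` applies the
#' standard variance stabilization `D = diag(1 / sqrt(max(y, 1)))`.
#'
#' @param log A `mospade_log` (or a single `mospade_record`).
#' @param weighting `"none"` (default) or `"poisson"`.
#' @return A `mospade_recon`: list with `c_est` (non-negative, length K),
#'   `residual_norm`, `weighting`, `n_records`. A rank-deficient stacked
#'   design triggers a warning naming the null-space dimension.
#' @export
nnls_reconstruct <- function(log, weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  if (inherits(log, "mospade_record")) log <- experiment_log(list(log))
  A <- do.call(rbind, lapply(log$records, function(r) r$budget * unclass(r$pt)))
  y <- unlist(lapply(log$records, function(r) r$counts))
  if (nrow(A) < 1) stop("no measurement rows")
  d <- if (weighting == "poisson") 1 / sqrt(pmax(y, 1)) else rep(1, length(y))
  rk <- qr(A)$rank
  if (rk < ncol(A))
    warning(sprintf("stacked design is rank-deficient: null space of dimension %d; the reconstruction is not unique",
                    ncol(A) - rk))
  sol <- pracma::lsqnonneg(d * A, d * y)
  structure(list(c_est = sol$x, residual_norm = sqrt(sol$resid.norm),
                 weighting = weighting, n_records = length(log$records)),
            class = "mospade_recon")
}

#' Mean-squared-error report over Monte-Carlo reconstructions
#'
#' Per-coefficient squared error averaged over trials,
#' `MSE_k = mean_t (c_est[t, k] - c_true[k])^2`, and its average over the `K`
#' coefficients — the quantity plotted against the CRB-per-photon lines.
#'
#' @param trials List of `mospade_recon` objects (or a matrix with one row of
#'   estimates per trial).
#' @param c_true True coefficient vector.
#' @return A `mospade_mse`: list with `mse_k`, `mse` (mean over k), `trials`.
#' @export
mse_report <- function(trials, c_true) {
  est <- if (is.matrix(trials)) trials
  else do.call(rbind, lapply(trials, function(r) r$c_est))
  if (ncol(est) != length(c_true)) stop("estimate/truth dimension mismatch")
  err2 <- sweep(est, 2, c_true)^2
  structure(list(mse_k = colMeans(err2), mse = mean(err2), trials = nrow(est)),
            class = "mospade_mse")
}

#' @export
print.mospade_mse <- function(x, ...) {
  cat(sprintf("MSE over %d trials: %.4g (mean over %d coefficients)\n",
              x$trials, x$mse, length(x$mse_k)))
  invisible(x)
}
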