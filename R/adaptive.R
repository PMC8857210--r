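#' Configuration of the adaptive measurement protocol
#'
#' The total photon budget is divided among an initial direct-imaging
#' bootstrap period and subsequent adaptive mode-optimized periods. The
#' defaults follow the protocol that works well empirically: three equal
#' periods (one direct + two adaptive) and a small number of adaptive modes.
#'
#' @param periods Total measurement periods including the bootstrap (>= 1).
#' @param total_photons Mean photon number summed over all periods.
#' @param split Budget fractions, length `periods`, positive, summing to 1
#'   (default equal).
#' @param J_adaptive Imaging modes per adaptive period (may be far fewer than
#'   the number of source modes; accumulated information keeps the
#'   reconstruction identifiable).
#' @param pixel_width,pixel_extent Direct-imaging bootstrap pixel grid.
#' @param nq Quadrature nodes per bin.
#' @param c_floor Relative coefficient floor for Fisher evaluation (prevents a
#'   zero estimate from locking a bin out of later iterations).
#' @param weighting NNLS weighting (default `"poisson"`): the stacked
#'   multi-basis system mixes modes whose counts differ by orders of
#'   magnitude, and unweighted least squares is statistically inefficient on
#'   such heteroscedastic Poisson data — inverse-variance weighting restores
#'   CRB-following behaviour of the combined estimate.
#' @param optimizer An [optimizer_config()].
#' @param seed Base seed; period `i` of trial `t` draws with
#'   `seed + 1000 * t + i`.
#' @return An `adaptive_config` list.
#' @export
adaptive_config <- function(periods = 3, total_photons = 1e6, split = NULL,
                            J_adaptive = 8, pixel_width = NULL, pixel_extent = NULL,
                            nq = 12, c_floor = 1e-6,
                            weighting = "poisson",
                            optimizer = optimizer_config(), seed = 1L) {
  periods <- as.integer(periods)
  stopifnot(periods >= 1, total_photons > 0)
  if (is.null(split)) split <- rep(1 / periods, periods)
  stopifnot(length(split) == periods, all(split > 0),
            abs(sum(split) - 1) < 1e-8)
  structure(list(periods = periods, total_photons = total_photons, split = split,
                 J_adaptive = as.integer(J_adaptive), pixel_width = pixel_width,
                 pixel_extent = pixel_extent, nq = nq, c_floor = c_floor,
                 weighting = weighting, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "adaptive_config")
}

#' Accumulated estimated Fisher information across measurement periods
#'
#' `I_acc = sum_m N_m * I(c_eval; Phi_m)`: per-period per-photon Fisher
#' matrices evaluated at a common coefficient vector, weighted by the photon
#' budget of each period.
#'
#' @param c_eval Coefficient vector at which all terms are evaluated.
#' @param pts List of probability tensors, one per period.
#' @param budgets Photon budgets `N_m`, same length.
#' @param c_floor Relative coefficient floor.
#' @return The `K x K` accumulated information matrix.
#' @export
accumulated_fisher <- function(c_eval, pts, budgets, c_floor = 1e-6) {
  stopifnot(length(pts) == length(budgets))
  Reduce(`+`, Map(function(pt, N) N * fisher_matrix(c_eval, pt, c_floor = c_floor),
                  pts, budgets))
}

#' Run the adaptive measurement protocol on an unknown source
#'
#' Implements the full alternating scheme: (1) measure one period in the
#' direct-imaging pixel basis; (2) at each adaptive iteration, reconstruct the
#' source by NNLS from all data so far, build the accumulated estimated
#' Fisher information at that estimate, and choose the next mode set by
#' minimizing `tr(W * solve(I_prev + N_i * I(c_est; Phi)))` over the Stiefel
#' manifold (past-period terms are constants; only the candidate term varies);
#' (3) measure with the optimized modes. The true source enters only the
#' photon-count simulator — the optimizer and estimator see estimates alone.
#'
#' @param source_true The scene being imaged (drives the simulated counts).
#' @param cbasis A [computation_basis()].
#' @param cfg An [adaptive_config()].
#' @param trial Trial index folded into the per-period seeds.
#' @return A `mospade_adaptive` state: `c_est` (final estimate), `c_history`
#'   (one row per completed estimate), `modes` (list of per-period mode sets),
#'   `log`, `fim_acc` (accumulated estimated FIM), `budgets`.
#' @export
run_adaptive <- function(source_true, cbasis, cfg = adaptive_config(), trial = 0L) {
  basis <- source_true$basis
  budgets <- cfg$total_photons * cfg$split
  pw <- if (is.null(cfg$pixel_width)) min(0.5 * cbasis$sigma, basis$width, na.rm = TRUE)
        else cfg$pixel_width
  px <- if (is.null(cfg$pixel_extent)) basis$extent + 3 * cbasis$sigma else cfg$pixel_extent
  direct <- direct_imaging_modes(cbasis, pw, px)
  seeds <- cfg$seed + 1000L * as.integer(trial) + seq_len(cfg$periods)

  records <- list(); pts <- list(); mode_sets <- list(direct)
  records[[1]] <- simulate_counts(source_true, direct, budgets[1], seed = seeds[1],
                                  nq = cfg$nq)
  pts[[1]] <- records[[1]]$pt
  recon <- nnls_reconstruct(experiment_log(records), weighting = cfg$weighting)
  c_hist <- matrix(recon$c_est, nrow = 1)

  if (cfg$periods >= 2) for (i in 2:cfg$periods) {
    c_est <- recon$c_est
    if (all(c_est == 0)) stop("bootstrap produced an all-zero estimate; increase the budget")
    prior <- accumulated_fisher(c_est, pts, budgets[seq_len(i - 1)],
                                c_floor = cfg$c_floor)
    est_source <- new_source_model(basis, c_est)
    obj <- mode_objective(est_source, cbasis, prior_fim = prior,
                          weight = budgets[i], nq = cfg$nq, c_floor = cfg$c_floor)
    V0 <- matched_mode_init(est_source, cbasis, cfg$J_adaptive, nq = cfg$nq)
    phi <- optimize_modes(obj, V0, cbasis = cbasis, config = cfg$optimizer)
    mode_sets[[i]] <- phi
    records[[i]] <- simulate_counts(source_true, phi, budgets[i], seed = seeds[i],
                                    nq = cfg$nq)
    pts[[i]] <- records[[i]]$pt
    recon <- nnls_reconstruct(experiment_log(records), weighting = cfg$weighting)
    c_hist <- rbind(c_hist, recon$c_est)
  }

  fim_acc <- accumulated_fisher(recon$c_est, pts, budgets, c_floor = cfg$c_floor)
  structure(list(c_est = recon$c_est, c_history = c_hist, modes = mode_sets,
                 log = experiment_log(records, source = source_true),
                 fim_acc = fim_acc, budgets = budgets, cfg = cfg),
            class = "mospade_adaptive")
}

#' @export
print.mospade_adaptive <- function(x, ...) {
  cat(sprintf("Adaptive imaging run: %d periods, total <N> = %g, K = %d\n",
              length(x$budgets), sum(x$budgets), length(x$c_est)))
  invisible(x)
}

#' Prior-knowledge mode-optimized Monte-Carlo baseline
#'
#' Characterizes the maximum attainable improvement: modes are optimized once
#' at the true coefficients, then `trials` independent measurements of budget
#' `N` are reconstructed by NNLS.
#'
#' @param source_true The scene.
#' @param cbasis A [computation_basis()].
#' @param J Number of imaging modes.
#' @param N Photon budget per trial.
#' @param trials Number of Monte-Carlo trials.
#' @param seed Base seed (trial `t` uses `seed + t`).
#' @param config Optimizer settings.
#' @param nq Quadrature nodes per bin.
#' @param weighting NNLS weighting.
#' @return A `mospade_mse` report with the optimized `modes` attached as an
#'   attribute.
#' @export
run_known_source <- function(source_true, cbasis, J, N, trials = 25, seed = 1L,
                             config = optimizer_config(), nq = 12,
                             weighting = "none") {
  phi <- optimal_modes(source_true, cbasis, J, nq = nq, config = config)
  pt <- probability_tensor(source_true$basis, phi, nq = nq)
  recs <- lapply(seq_len(trials), function(t)
    nnls_reconstruct(simulate_counts(source_true, phi, N, seed = seed + t, pt = pt),
                     weighting = weighting))
  out <- mse_report(recs, source_true$c)
  attr(out, "modes") <- phi
  out
}

#' Direct-imaging Monte-Carlo baseline
#'
#' @inheritParams run_known_source
#' @param pixel_width,pixel_extent Pixel grid of the direct measurement.
#' @return A `mospade_mse` report with the pixel modes attached.
#' @export
run_direct <- function(source_true, cbasis, N, trials = 25, seed = 1L,
                       pixel_width = 0.5, pixel_extent = NULL, nq = 12,
                       weighting = "none") {
  if (is.null(pixel_extent))
    pixel_extent <- source_true$basis$extent + 3 * cbasis$sigma
  phi <- direct_imaging_modes(cbasis, pixel_width, pixel_extent)
  pt <- probability_tensor(source_true$basis, phi, nq = nq)
  recs <- lapply(seq_len(trials), function(t)
    nnls_reconstruct(simulate_counts(source_true, phi, N, seed = seed + t, pt = pt),
                     weighting = weighting))
  out <- mse_report(recs, source_true$c)
  attr(out, "modes") <- phi
  out
}
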