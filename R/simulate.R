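#' Simulate one photon-counting measurement period
#'
#' Draws independent Poisson counts `n_j ~ Poisson(N * P_j)` for each imaging
#' mode, where `P_j` are the per-photon detection probabilities of the source
#' through the mode set and `N` is the mean photon number reaching the image
#' plane for the period (no extra efficiency factor). Expected counts beyond
#' 1e12 switch to a rounded Gaussian approximation to stay integer-safe.
#'
#' @param source Source model (used only to form the count means).
#' @param modes A [mode_set()].
#' @param N Mean photon number for the period (> 0).
#' @param seed Integer seed; the record stores it for bit-exact replay. The
#'   global RNG state is left untouched.
#' @param pt Optional precomputed [probability_tensor()] for `source$basis`
#'   and `modes` (avoids recomputation in tight Monte-Carlo loops).
#' @param nq Quadrature nodes per bin when `pt` is computed here.
#' @return A `mospade_record`: list with `counts`, `modes`, `pt`, `budget`,
#'   `seed`, `P`.
#' @export
simulate_counts <- function(source, modes, N, seed = NULL, pt = NULL, nq = 12) {
  stopifnot(N > 0)
  if (is.null(pt)) pt <- probability_tensor(source$basis, modes, nq = nq)
  P <- detection_probs(source, pt)
  mu <- N * P
  rng <- if (!is.null(seed)) local_rng(seed) else NULL
  n <- ifelse(mu > 1e12,
              pmax(0, round(mu + sqrt(mu) * stats::rnorm(length(mu)))),
              stats::rpois(length(mu), mu))
  if (!is.null(rng)) rng$restore()
  structure(list(counts = as.numeric(n), modes = modes, pt = pt,
                 budget = N, seed = seed, P = P),
            class = "mospade_record")
}

#' @export
print.mospade_record <- function(x, ...) {
  cat(sprintf("Measurement record: J = %d modes, budget <N> = %g, total counts %g\n",
              length(x$counts), x$budget, sum(x$counts)))
  invisible(x)
}

#' Bundle measurement records into an experiment log
#'
#' @param ... `mospade_record`s (or a single list of them).
#' @param source Optional reference to the (true) scene, for reporting only.
#' @return A `mospade_log`.
#' @export
experiment_log <- function(..., source = NULL) {
  recs <- list(...)
  if (length(recs) == 1 && !inherits(recs[[1]], "mospade_record")) recs <- recs[[1]]
  stopifnot(all(vapply(recs, inherits, logical(1), "mospade_record")))
  if (length(recs) > 1) {
    sz <- vapply(recs, function(r) r$modes$cbasis$size, numeric(1))
    if (length(unique(sz)) != 1)
      stop("all records must share the same computation basis")
  }
  structure(list(records = recs, source = source), class = "mospade_log")
}
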