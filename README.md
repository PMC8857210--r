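# mospade

Manifold-optimized spatial-mode demultiplexing (MO-SPADE) for far-field
imaging of incoherent sources.

Conventional ("direct") imaging detects photons in the position basis at the
image plane, and its precision for sub-diffraction features falls far short
of what quantum estimation theory allows. Sorting the image-plane field into
a set of orthonormal spatial modes before photon counting can close most of
that gap. This package designs such mode sets for *arbitrary* source
distributions: the source brightness is decomposed over K orthogonal source
modes, `F(R) = Σ_k c_k f_k(R)`, and the imaging modes Φ = {φ_j} are chosen to
minimize the Cramér–Rao bound (CRB) of the coefficient estimates,

    L(Φ) = tr( W · I(c; Φ)⁻¹ ),      I_kl = Σ_j (1/P_j) (∂P_j/∂c_k)(∂P_j/∂c_l),

with `P_j = Σ_k c_k p_jk` the per-photon modal detection probabilities under
a Gaussian PSF of width σ, and W the identity (mean CRB). The minimization
runs over the Stiefel manifold of orthonormal mode matrices by Riemannian
conjugate gradient. The package also computes the quantum CRB via symmetric
logarithmic derivatives (the measurement-independent floor for any detection
scheme), simulates Poisson photon counting, reconstructs sources by
non-negative least squares, and implements the adaptive protocol that
alternates source estimation with mode re-optimization using accumulated
Fisher information — so an unknown source can be imaged at near
quantum-limited resolution with no prior knowledge.

Intended users: researchers in computational imaging, quantum-inspired
super-resolution microscopy, and astronomical photometry who want CRB-driven
measurement design and honest classical-versus-quantum benchmarks.

## Worked example

Five equal point sources spaced 0.3 σ apart — far below the Rayleigh limit
(the Airy radius is ≈ 3 σ):

```r
library(mospade)

psf <- psf_model(sigma = 1)
cb  <- computation_basis(psf, M = 48)
src <- point_comb(5, 0.3)               # amplitudes c = 0.2 each, unit flux

direct <- direct_imaging_modes(cb, pixel_width = 0.25, extent = 5.6)
phi    <- optimal_modes(src, cb, J = 5) # manifold-optimized 5-mode sorter

c(direct = mean_crb(src, direct),
  mospade = mean_crb(src, phi),
  quantum = mean_qcrb(src, cb))
#>     direct    mospade    quantum
#> 15408.1377   400.1605   275.5645
```

Per detected photon, the optimized mode sorter bounds the mean squared error
of the five amplitudes at ≈ 400, a 38-fold improvement over direct imaging
(15408) and within a factor 1.45 of the quantum limit (276). A Monte-Carlo
check that the bounds are actually achieved at ⟨N⟩ = 10⁶ photons:

```r
md <- run_direct(src, cb, N = 1e6, trials = 100, seed = 11, pixel_width = 0.25)
mm <- run_known_source(src, cb, J = 5, N = 1e6, trials = 100, seed = 23)
c(md$mse, mm$mse, md$mse / mm$mse)
#> [1] 1.575364e-02 4.266873e-04 3.692082e+01
```

both estimators sit on their CRB/⟨N⟩ lines and the reconstruction error
drops by an order of magnitude. For a source nobody knows in advance, the
adaptive loop gets almost all of this gain with only 8 imaging modes:

```r
src28 <- extended_source("bump", a = 0.8, extent = 11.2)   # 28 bins
ad <- run_adaptive(src28, computation_basis(psf, 80),
                   adaptive_config(periods = 3, total_photons = 1e7,
                                   J_adaptive = 8, seed = 400))
mean((ad$c_est - src28$c)^2)
#> [1] 3.980211e-06
```

Curve-level comparisons (`crb_vs_separation()`, `crb_vs_binwidth()`,
`resolution_gain()`), the quantum bound machinery (`source_density()`,
`sld_qfim()`, `whitening_transform()`), 2D low-contrast scenes
(`scene_2d()`) and a thin command-line front end (`inst/cli/mospade.R`) are
documented in the help pages; the methods vignette
(`vignettes/mospade-methods.Rmd`) explains the model, the conventions and
the numerics.

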