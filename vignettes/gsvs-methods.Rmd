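---
title: "Methods: shrinkage-based recovery of complex diffusion MRI under general noise models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shrinkage-based recovery of complex diffusion MRI under general noise models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `gsvs`, the conventions
and numerical choices the implementation commits to, what the bundled
synthetic phantom does and does not emulate, and the known limitations.

## The recovery model

DWI volumes reconstructed by a *linear* method carry additive, zero-mean,
circularly symmetric complex Gaussian noise whose covariance is exactly
computable from the scanner channel covariance: magnitude images do not
(their noise becomes Rician, signal-dependent). `gsvs` therefore operates on
complex data throughout. Local spherical patches of M voxels tracked over N
diffusion volumes are arranged as Casorati matrices Y = X + W, with the
signal X assumed approximately low rank (diffusion contrast varies smoothly
over a few-voxel neighbourhood and is heavily oversampled across volumes)
and W Gaussian with patch covariance Λ_Y = Σ_M ⊗ I_N (stationary encodings)
or a per-encoding family Σ_M^a with volume groups (interleaved encodings).

Recovery uses singular value shrinkage: with f(η_W) the limiting spectral
distribution of noise-only matrices, the D-transform

D_f(x) = φ(x)(γ φ(x) + (1 − γ)/x),  φ(x) = ∫ x/(x² − η²) f(η) dη,  γ = M/N,

yields the shrinker η̂_X = −2 D_f(η_Y)/D_f′(η_Y) for observed singular
values above the bulk edge η_W⁺ and 0 otherwise; this asymptotically
minimizes the Frobenius loss among all singular-value maps. The count of
surviving components is the rank estimate, and
L̂ = Σ_r(1/D_f(η_Yr) − η̂²_Xr) estimates the asymptotic Frobenius error of
the patch without ground truth. Assumptions worth keeping in mind: the
guarantees are asymptotic (M, N → ∞ at fixed γ) and treat the signal as
bi-unitarily invariant; at desk-top patch sizes (M, N of a few dozen) the
bulk edge fluctuates by O(M^{-2/3}), so occasional single-component false
detections on pure noise are expected and harmless (they are shrunk to near
zero).

## Noise propagation conventions

* **DFT convention.** All spectral operations use the centered, unitary DFT
  (DC at voxel `floor(n/2)+1`), so Fᴴ = F⁻¹ exactly; spectral filters are
  defined on the centered grid.
* **Sample-referenced noise.** k-space is always indexed on the full
  reconstruction grid and noise lives on the *acquired* samples with
  covariance σ²Λ_z. Under this convention the aliased-set covariance of a
  U-fold undersampled SENSE reconstruction is σ²·U·(S̄_qUᴴS̄_qU)⁻¹ and the
  ratio of undersampled to fully-sampled voxel noise equals the g-factor
  times √U, voxelwise — the classic parallel-imaging SNR identity, which the
  test suite checks against an independent g-factor computation.
* **Partial Fourier.** Only the k-space weighting is modelled: `zero_fill`
  is the indicator of acquired lines; `ramp` is a homodyne-style weight
  rising linearly 0 → 2 across the symmetrically sampled band (1 at DC) and
  2 on the asymmetric-only band. The taps are documented in
  `pf_filter_taps()` and versioned with the package; classical homodyne's
  separate phase-estimation step is intentionally absent (phase is handled
  by the demodulation stage and by the recovery itself).
* **Analytic vs Monte-Carlo.** FULL and UNDER covariances are analytic;
  partial-Fourier covariances are analytic for U = 1 (per-PE-column operator
  G W C WᴴGᴴ) and Monte-Carlo otherwise: noise-only draws are pushed through
  the *actual* reconstruction and patch covariances are sample covariances
  of the draws. The default is 2000 draws; the two paths are required to
  agree on shared cases by the test suite.
* **Demodulation and covariance.** Removing a linear phase ramp along the
  PE axis permutes partial-Fourier noise correlations in principle; like the
  reconstruction it feeds, the implementation treats this effect as
  negligible and does not alter Λ_Y after demodulation.
* **Regularization.** Covariance inversions floor eigenvalues at 1e-8 of
  the largest (with a message); the channel whitener refuses covariances
  that are singular at the 1e-12 level and reports the condition number.

## Phase correction

Per slice and volume, the ramp is the *integer* harmonic at the argmax of
the centered 2D DFT magnitude and the offset is the phase of that
coefficient — a deliberately gross, robust estimate that survives very low
SNR; subpixel refinement is intentionally not attempted. The phase origin is
fixed at the grid center: with no canonical choice between center and
corner, the center makes the ramp/offset decomposition match the DFT
convention exactly. Estimation runs uniformly on all volumes including
b = 0. Integer-harmonic corruption is removed exactly; off-lattice ramps are
reduced to a residual the shrinkage stage absorbs. The corruption generator
can draw on or off the integer lattice precisely so tests can distinguish
the two regimes.

## Patching and assembly

Patches are the M nearest in-FOV voxels to each center (spheres that deform
at boundaries rather than zero-pad), with distance ties broken
lexicographically, M = round(γN). Centers sit on a stride-T lattice (T = 2
for denoising, T = 6 for patch-size estimation — the sparse pass needs only
aggregate risk, not coverage), augmented deterministically until every FOV
voxel is covered when assembly will follow. Overlapping estimates are
combined with per-voxel convex weights: `inverse_variance` (1/L̂ per patch;
the default for simulation studies), `gaussian` (window sd = half the
nominal patch radius (3M/4π)^{1/3} — the width is a package choice, made
once, since no canonical value exists), `uniform`, and a `nearest`
single-patch scheme kept as the no-overlap diagnostic. The patch-size
search is restricted to γ < 1 by default: beyond square matrices the
asymptotic risk estimates degrade noticeably, so candidates above 1 buy
nothing.

## ESD simulation

"Size B(M×N)" is realized as one (BM)×(BN) draw — this preserves γ, gives
B·M spectrum atoms, and after division by √B lives on the M×N
singular-value scale; the i.i.d. bulk-edge oracle (edge/√N → 1+√γ) pins this
reading down in the tests. B = 2 by default: doubling B halves the edge's
sampling error at four times the SVD cost, and B = 2 already keeps the
white-shrinker equivalence within 1%. One ESD is drawn per patch (seeded
order-invariantly from the run seed); an optional cache reuses an ESD across
patches whose covariance spectra agree within 1% relative tolerance, for
speed — the pipeline tests bound its effect. The derivative D_f′ is computed
analytically from the discrete atoms; finite differences near the edge are
numerically fragile. A generalized Marčenko-Pastur fixed-point solver is
deliberately out of scope; only Monte-Carlo simulation and the white-noise
closed form are provided.

## Data-driven estimators

EXP1/EXP2 iterate candidate ranks R and compare the Marčenko-Pastur
bulk-width statistic σ̃²(R) = (λ_{R+1} − λ_p)/(4√β) — β = (M−R)/N for EXP1,
(M−R)/(N−R) for EXP2, the shape correction that matters for near-square
matrices — with the tail expectation Σ_{r>R}λ_r. The reported noise variance
is the tail mean at the selected rank, the statistic whose expectation is
exactly σ² on pure noise; the bulk-width value itself carries an
irreducible O(M^{-2/3}) downward bias at practical patch sizes and is used
only inside the selection criterion. This choice is pinned by the
self-consistency simulations in the test suite (median σ̂ within 2% of
truth on standardized reconstructions). MED divides the median observed
eigenvalue (index p/2 of the decreasingly sorted spectrum for even p) by the
numerically inverted Marčenko-Pastur median. All estimators report σ per
complex entry (real and imaginary parts combined) and are symmetric in
(M, N).

## What the phantom emulates — and what it does not

The generator produces multi-shell single-tensor signal (nested ellipsoids:
isotropic "brain", two orthogonal anisotropic "tracts", a free-diffusion
sphere), smooth complex coil lobes placed around the FOV with an
exponentially correlated channel covariance, circularly symmetric channel
noise injected per acquired sample, undersampling / partial-Fourier /
volumewise-interleaved Cartesian sampling, and per-slice linear phase
corruption whose amplitude scales as √(b/b_max) (stronger diffusion
gradients fluctuate more). Defaults are a reduced-scale version of an adult
multi-shell protocol: 32³ grid, shells b = 0/1/2.5/5 ms/μm² with
6/10/14/18 directions (48 volumes), so suites run in minutes; its SNR is set
by the explicit `noise_sigma` parameter since no external calibration target
exists. It deliberately omits EPI distortion and ghosting, motion between
volumes, nonlinear phase, multiband slice encoding and realistic anatomy —
so passing tests demonstrate the statistical machinery (noise propagation,
edge detection, shrinkage optimality, risk estimation) under the assumed
model, not robustness to the artifacts real scans add on top.

## Problem sizes used by the validation suite

Chosen so each experiment isolates one claim at comfortable Monte-Carlo
precision: noise standardization on a 32³/8-coil/U=2/48-volume dataset with
343 patches at γ = 0.85; a rank-1 spiked model at γ = 0.5, N = 4000;
white-shrinker equivalence at γ ∈ {0.25, 0.5, 0.85}; AMSE fidelity on 100
patches of 128×160 with five strong spikes; rank recovery on 100 seeded
64×80 trials; end-to-end ordering on a 24³ phantom; phase-correction and
interleaved-encoding comparisons on 20³- and 16²×8-scale phantoms over
fixed seed sets.

## Known limitations

* Asymptotic optimality degrades for very small patches (M ≲ 10) and for
  γ ≥ 1; the default search range avoids both.
* The MC patch-covariance path stores one reconstructed noise volume per
  draw; for large grids prefer the analytic paths or reduce `n_draws`.
* The magnitude-input mode exists to demonstrate the Rician bias mechanism,
  not as a recommended operating point.
* Phase correction is global-linear per slice; strongly nonlinear phase
  (e.g. through-plane motion during diffusion encoding) leaves residual
  rank inflation that shows up as higher retained ranks, not as bias.
* INTER covariances require the Monte-Carlo path or per-encoding analytic
  U = 1 partial-Fourier models; general U > 1 partial-Fourier covariances
  are Monte-Carlo only.
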