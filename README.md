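# gsvs — generalized singular value shrinkage for complex diffusion MRI

Diffusion-weighted MRI (DWI) is chronically starved of signal-to-noise
ratio: the water signal decays exponentially with the diffusion weighting
*b*, and accelerated (parallel, partial-Fourier, interleaved) acquisitions
trade further SNR for speed. `gsvs` denoises the **complex-valued** volumes
that come out of a linear SENSE reconstruction, before any magnitude
operation can introduce a Rician noise floor, by treating each local group
of voxels as a low-rank matrix recovery problem under a *general* —
correlated and heteroscedastic — noise model.

The method, for each spherical patch of M voxels observed over N diffusion
volumes arranged as a Casorati matrix Y = X + W:

1. **Noise propagation.** The scanner channel covariance Λ_z is propagated
   through the linear reconstruction to the image-domain covariance Λ_y and
   marginalized onto the patch, Λ_Y = P Λ_y Pᴴ. Fully sampled, undersampled
   (via the g-factor), partial-Fourier (spectral filter G) and
   volumewise-interleaved encodings are supported, analytically or by
   Monte-Carlo propagation of noise-only draws.
2. **ESD modelling.** The asymptotic singular-value spectrum of the noise,
   f(η_W), is simulated by drawing one (BM)×(BN) matrix per patch from
   CN(0, Λ_Y) (or taken from the Marčenko-Pastur closed form for white
   noise); its largest value estimates the bulk edge η_W⁺.
3. **Optimal shrinkage.** With the D-transform
   D_f(x) = φ(x)·(γ φ(x) + (1−γ)/x), φ(x) = ∫ x/(x²−η²) f(η) dη,
   each observed singular value above the edge is shrunk to
   η̂_X = −2 D_f(η_Y)/D_f′(η_Y) — the rule that asymptotically minimizes the
   Frobenius loss ‖X̂ − X‖² — and everything at or below the edge is
   suppressed. The per-patch risk is estimated without ground truth as
   L̂ = Σ_r (1/D_f(η_Yr) − η̂²_Xr).
4. **Patch size selection.** The aspect ratio γ = M/N is chosen by
   minimizing the normalized aggregate risk L̄(γ) = Σ L̂ / Σ‖X̂‖² over a
   candidate grid on a sparse patch subset.
5. **Phase handling.** A per-slice, per-volume linear phase (integer
   harmonic + offset, via the Fourier shift theorem) is removed before
   recovery and restored afterwards, increasing the redundancy (lowering the
   rank) of the patch matrices without biasing magnitudes.

A bundled synthetic phantom (multi-shell tensor signal, smooth complex coil
sensitivities, correlated channel noise, undersampling / partial-Fourier /
interleaved sampling, linear phase corruption) makes the entire chain
testable without scanner data. Data-driven noise estimators (EXP1, EXP2,
MED) and a hard-truncation (MPPCA-style) baseline are included for
comparison studies.

## Worked example

```r
library(gsvs)
spec  <- phantom_spec(grid_shape = c(24, 24, 24))   # 4 shells, 48 volumes
truth <- make_phantom(spec)
coils <- make_coils(spec$grid_shape, L = 8, seed = 1)
scheme <- sampling_scheme("UNDER", U = 2)
kd <- sample_kspace(truth, coils, scheme, noise_sigma = 6, seed = 1)
nm <- propagate_noise(coils, scheme, noise_sigma = 6)
y  <- sense_reconstruct(kd)
cat(sprintf("input PSNR:  %.2f dB\n", psnr(y, truth, phantom_mask(spec))))
cfg <- run_config(gamma_grid = c(0.35, 0.5, 0.65, 0.8), stride_gamma = 4,
                  phase_correct = FALSE, mask = phantom_mask(spec), seed = 1)
res <- denoise(y, nm, cfg, truth = truth)
print(res$report$gamma_curve)
cat(sprintf("denoised PSNR: %.2f dB (SSIM %.3f)\n", res$report$psnr, res$report$ssim))
cat(sprintf("mean inverse RAMSE: %.2f dB\n", res$report$mean_inv_ramse_db))
```

Output:

```
input PSNR:  23.50 dB
  gamma        lbar
1  0.35 0.005153807
2  0.50 0.004175460
3  0.65 0.003824918
4  0.80 0.003513048
denoised PSNR: 37.33 dB (SSIM 0.766)
mean inverse RAMSE: 24.40 dB
```

The `lbar` column is the estimated relative risk per candidate patch size;
the minimizer (γ = 0.8, i.e. M = 38 voxels per patch for N = 48 volumes) is
used for denoising. The ~14 dB PSNR gain comes from shrinking each patch's
singular values against its *propagated* noise spectrum — no noise level is
estimated from the data — and the mean inverse RAMSE is the matching
ground-truth-free estimate of the output SNR.

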