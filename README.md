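# gbm4d — guided 4-D collaborative denoising of dynamic PET sinograms

Dynamic PET splits an acquisition into short time frames so tracer kinetics
can be measured, but each frame is then severely count-starved and Poisson
noise dominates both the reconstructed images and the tissue time-activity
curves (TACs). `gbm4d` implements a projection-domain denoiser for dynamic
PET: the guided block-matching and 4-D transform-domain collaborative
filter (GBM4D), applied to the sinogram *before* reconstruction, where the
Poisson noise model is exact.

The package is aimed at PET methodology researchers who want a fully
reproducible, pure-R reference implementation of the filter together with
the simulation and evaluation apparatus needed to study it: dynamic phantom
generation with two-tissue-compartment kinetics, parallel-beam projection
with count-budgeted Poisson noise, OSEM reconstruction, and SSIM / PSNR /
TAC-RMSE evaluation.

## The method

For counts `z(x,t) ~ Poisson(y(x,t))`, the pipeline is:

1. **Variance stabilization.** Anscombe transform `f(z) = 2√(z + 3/8)`,
   giving approximately `N(0, 1)` noise; the final estimate returns to the
   count domain through the closed-form exact unbiased inverse.
2. **Guided matching.** Blocks are matched once per slice on the *guide
   image* `Z_guide(x) = Σ_t Z_t(x)` — the accumulated stabilized sinogram —
   whose noise level `σ√|T|` is far below each frame's relative to signal,
   using a coarse-prefiltered, DCT-domain block distance
   `d(x_R, x) = ‖Υ′(T Z_guide_{x_R}) − Υ′(T Z_guide_x)‖² / N²` and the rule
   `S_{x_R} = {x : d(x_R, x) ≤ τ_match σ_guide²}`.
3. **Collaborative filtering.** The matched `N × N` blocks from all `|T|`
   frames form an `N × N × |T| × |S|` group, filtered in a separable
   orthonormal 4-D DCT domain — Step 1 by hard thresholding
   (`Υ(υ) = 0` for `|υ| ≤ λ_4D σ`, with `λ_4D = 2.8`), Step 2 by empirical
   Wiener shrinkage `W = |T(basic)|² / (|T(basic)|² + σ²)` with the Step-1
   estimate as pilot and re-matching on its accumulated guide.
4. **Aggregation.** Overlapping filtered blocks are combined by a weighted
   average (group reliability weight × 2-D Kaiser window).
5. **Reconstruction.** 2-D OSEM with a sparse, exactly matched
   projector/adjoint pair (`f_j ← f_j / Σ_{i∈S_b} H_ij · Σ_{i∈S_b} H_ij
   p_i / (Hf)_i`), by default 20 iterations × 8 subsets.

## Worked example

Denoise a dynamic Shepp-Logan sinogram and measure the gain:

```r
library(gbm4d)

ph    <- shepp_logan_phantom(64)                  # 64 x 64 x 1 activity
clean <- forward_project(ph)                      # parallel-beam sinogram
clean <- array(rep(clean * 1e5 / sum(clean), 8), c(64, 64, 1, 8))

sino <- add_poisson_noise(clean, sum(clean), seed = 7)   # 1e5 counts/frame
den  <- gbm4d_denoise_counts(sino)                # stabilize -> filter -> invert

psnr(clean, sino$counts)   # 20.04 dB  (noisy sinogram vs clean)
psnr(clean, den)           # 32.03 dB  (denoised sinogram vs clean)
```

The full benchmark — 8 × 6-min frames, 4 central 128 × 128 slices of the
3-D Shepp-Logan phantom, 1.4M counts per slice, OSEM 20 it × 8 subsets,
metrics against the noiseless-sinogram reconstruction — runs in about two
minutes:

```r
res <- slp_experiment(seed = 1)
subset(res$metrics, method == "gbm4d")
#>    method frame   ssim psnr_db
#>     gbm4d     1 0.9783   29.56
#>     gbm4d     2 0.9785   29.55
#>     ...
#>     gbm4d     8 0.9771   29.18
```

Per-frame global SSIM ≈ 0.98 and PSNR ≈ 29.2–29.6 dB, against
16.2 dB for the un-denoised branch. The kinetic counterpart
(`brain_experiment()`, `brain_tac_study()`) simulates a brain-like phantom
with two-tissue-compartment TACs and reports per-tissue TAC RMSE; gray- and
white-matter TAC errors drop roughly threefold, while the 4 × 4 × 4 tumor
is partially attenuated (see the vignette's limitations section).

A thin command-line front end over the same functions lives at
`inst/cli/gbm4d.R` (`simulate`, `denoise`, `reconstruct`, `evaluate`,
`run-all`, YAML-configured).

## Package layout

- `R/vst.R` — Anscombe transform and exact unbiased inverse
- `R/matching.R` — guide images, prefiltered distances, block matching, stacking
- `R/dct.R`, `R/filtering.R` — orthonormal 4-D DCT, hard-threshold and Wiener
  stages, Kaiser-weighted aggregation, the two-step denoiser
- `R/phantom.R`, `R/kinetics.R` — Shepp-Logan and brain-like phantoms, Feng
  input function, two-tissue-compartment TACs, dynamic activity volumes
- `R/projection.R`, `R/recon.R` — sparse radon system matrix, Poisson count
  simulation, OSEM / MLEM / FBP reconstruction
- `R/evaluation.R` — global SSIM, PSNR, TAC extraction and RMSE
- `R/pipeline.R` — configuration, NIfTI/JSON I/O, end-to-end pipeline and the
  two standard experiments
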