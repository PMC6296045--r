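# geodenoise

Patch-based denoising of cryo-EM micrographs with geodesic block matching.

Single-particle electron cryomicrographs are 2-D projections with very low
signal-to-noise ratio, but they contain many near-identical copies of the
same particle. `geodenoise` exploits this structural redundancy: overlapping
p×p image blocks are grouped by similarity, each group is denoised jointly in
a data-driven orthonormal dictionary, and the estimates are averaged back
into the image. It is aimed at cryo-EM practitioners preprocessing
micrographs before particle picking, and more generally at anyone denoising
grayscale images with strong repeated structure.

## Method

For an observed image y = x + v with i.i.d. Gaussian noise v of known
standard deviation σ (on the 0–255 gray scale):

1. **Block matching under a geodesic dissimilarity.** Blocks are compared
   pixel-by-pixel with

   d(S_A, S_B) = (1/p²) Σᵢ [ ½(value[Aᵢ] − value[Bᵢ])² + ½(t_Aᵢ + t_Bᵢ + tan|α − β|) ],

   where t is the gradient magnitude and α, β are gradient orientations
   quantized to {0, π/4, π/2, 3π/4, π}. Unlike the plain Euclidean distance
   (mean squared gray difference), this accounts for local edge structure.
   N seeded reference blocks are drawn and every candidate block in the
   whole image is assigned to its nearest reference.

2. **Gaussian mixture prior over centered groups.** With group means μ_y
   removed, a K-component GMM is fitted by EM, maximizing
   ln L = Σₙ ln( Σₖ πₖ Πₘ N(ȳ_{n,m} | μₖ, Σₖ) ), one latent component per
   group.

3. **Bayesian dictionary selection.** Each group picks the component
   maximizing Σₘ ln N(ȳₘ | 0, Σₖ); the eigenvectors of that Σₖ (sorted by
   non-increasing eigenvalue λ) form the group dictionary D.

4. **Weighted soft-threshold sparse coding.** Coefficients z = Dᵀȳₘ are
   shrunk by SoftMAP(z, w/2) = sgn(z)(|z| − w/2)₊ with eigenvalue-dependent
   weights wᵢ = c·2√2·σ²/(λᵢ + ε), and the block estimate is
   x̂ₘ = μ_y + D·α̂.

5. **Aggregation and iteration.** Estimates are averaged per pixel and the
   noise level is updated by (σ⁽ᵗ⁾)² = η·(σ² − ‖y − y⁽ᵗ⁻¹⁾‖²) before the
   next pass.

Quality is evaluated with MSE, PSNR = 10·log10(255²/MSE), SNR and SSIM.

## Worked example

```r
library(geodenoise)

ph    <- make_phantom(phantom_spec())              # 640x640, 20 ring "particles"
noisy <- add_gaussian_noise(ph$image, sigma = 25, seed = 2)
psnr(ph$image, noisy)
#> [1] 20.1734

cfg <- denoise_config(sigma = 25, stride = 4, K = 8, em_iters = 15,
                      outer_iters = 2, seed = 1)
res <- denoise_image(noisy, cfg, clean = ph$image)
res$report$psnr_t
#> [1] 29.30172 30.36796
res$report$sigma_t
#> [1] 10.809230  8.574227
ssim(ph$image, res$estimate)
#> [1] 0.6970658
```

The per-iteration PSNR climbs from 20.2 dB (noisy input) to 30.4 dB after
two passes — roughly +10 dB on this phantom — while the internal noise
estimate σ⁽ᵗ⁾ drops from 25 to 8.6, reflecting how much noise energy the
estimate has already explained.

The same pipeline is available from the shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "geodenoise", package = "geodenoise"))')
Rscript "$cli" simulate --size 640 --sigma 25 --seed 1 --out phantom
Rscript "$cli" denoise  --input phantom_noisy.mrc --clean phantom_clean.mrc \
                        --sigma 25 --stride 4 --K 8 --em-iters 15 --iters 2 \
                        --output denoised.mrc --report report.json
Rscript "$cli" metrics  --ref phantom_clean.mrc --test denoised.mrc
```

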