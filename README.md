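# serialreg

Registration of ordered serial histology sections into a coherent 3D stack.

Serial sectioning slices a tissue block into consecutive 2-D sections, each
digitized separately. Before any 3-D analysis — following a glomerulus
through a kidney, reconstructing vasculature, measuring structures across
depth — the sections must be brought into a common coordinate frame.
Sectioning makes this hard: every slice is placed on its slide with an
arbitrary rotation and offset, the tissue stretches and tears, staining and
illumination vary from slide to slide. `serialreg` implements a classical,
training-free pipeline for this problem, aimed at image-analysis
practitioners who want a transparent, fully scriptable tool with a
quantitative evaluation built in.

## Method

Each consecutive pair (fixed section *I_t*, moving section *I_{t+1}*) is
aligned in three stages:

1. **Rotation-aware keypoint matching.** Corner keypoints (Harris) with
   normalized patch descriptors are detected in both sections. Because
   patch descriptors tolerate only small rotations, the moving section is
   rotated through a candidate set (default 0°, 30°, …, 330°) and the
   angle that maximizes RANSAC-consistent matches is kept; the winning
   matches are expressed in the unrotated frame, so no extra resampling
   enters the pipeline. Learned feature extractors can be plugged in behind
   the same backend contract.
2. **Robust affine alignment.** From the matched pairs
   *M = {(p_i, q_i)}*, RANSAC repeatedly fits the affine map
   *x′ = A q + t* (moving → fixed) to minimal 3-pair samples, keeps the
   hypothesis with the most inliers (residual < 3 px by default), and
   re-fits by least squares on the inlier set.
3. **B-spline non-rigid refinement.** Residual local deformation is
   modeled by a free-form deformation
   *T(x) = x + Σ_ij c_ij B_i(u) B_j(v)* on a coarse control grid (cubic
   B-splines, 8×8 cells by default), optimized by gradient descent on
   *L = L_NCC + λ L_reg*, where *L_NCC* is a local normalized
   cross-correlation loss (9×9 windows) — invariant to the gain/offset
   illumination changes typical of serial slides — and *L_reg* is a
   diffusion (squared finite difference) smoothness penalty on the
   displacement field.

Per-pair transforms are composed into the frame of an anchor slice (the
middle slice by default, halving the length of error-propagating chains),
and every slice is resampled **once** through its composed coordinate map
into the registered 3-D stack.

Alignment quality is quantified with the standard landmark suite: per-pair
relative target registration error rTRE = ‖x̂ − x‖ / diagonal, aggregated
as AMrTRE (mean of pair medians), MMrTRE (median of medians), AMean_rTRE,
AMxrTRE (mean of pair maxima), robustness R_avg (fraction of landmarks
whose error decreased vs. the unregistered positions), and the absolute
AMean_D in pixels or physical units.

Because real serial-section datasets with validated landmarks are rarely
shareable, the package ships a synthetic generator that emulates the
degradations above (per-hop rotation/scale/translation, smooth elastic
deformation, illumination jitter, fresh fine-grain noise) while tracking
landmarks and ground-truth transforms exactly; it is the test bed for every
stage.

## Worked example

```r
library(serialreg)

spec  <- synthetic_stack_spec(n_slices = 4, size = c(192L, 192L))
stack <- make_synthetic_stack(spec, seed = 1)

config <- default_config()
config$background <- spec$background

res <- register_stack(stack$sections, config, verbose = TRUE)
#> pair 0->1: angle 330 deg, 51 inliers
#> pair 1->2: angle 0 deg, 61 inliers
#> pair 2->3: angle 0 deg, 60 inliers

ev <- evaluate_sequence(stack$landmarks, res$pairs, dims = spec$size)
print(ev$initial_summary)
#>       AMrTRE     MMrTRE AMean_rTRE  AMxrTRE R_avg  AMean_D n_pairs
#> 1 0.06844245 0.05665504 0.06755829 0.113034     0 18.34403       3
print(ev$summary)
#>         AMrTRE       MMrTRE   AMean_rTRE     AMxrTRE R_avg   AMean_D n_pairs
#> 1 0.0004181094 0.0003944688 0.0008443745 0.004780762     1 0.2292722       3
```

The first pair needed a 330° (= −30°) orientation correction before
matching succeeded. Before registration the landmarks of consecutive
sections disagree by 18.3 px on average (rTRE ≈ 0.068 of the image
diagonal) and no landmark is aligned; after the three-stage registration
the mean disagreement is 0.23 px, every landmark improved (R_avg = 1), and
the registered stack is returned in `res$registered`, ready to write as a
multi-page TIFF with `write_image_stack()`.

A command-line interface wrapping the same functions is installed at
`inst/cli/serialreg.R` (`register`, `evaluate`, `synthesize`,
`--print-config`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default 8-slice synthetic stack from the given seed, runs
the complete pipeline on it from scratch, prints the landmark evaluation
summary before and after registration, and writes the JSON result object
to `--out`.
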