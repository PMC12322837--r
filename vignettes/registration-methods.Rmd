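---
title: "Methods: serial-section registration in serialreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section registration in serialreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `serialreg`, in the spirit of a methods section: what the
pipeline assumes, which knobs matter, and what a passing test does and does
not establish.

## Problem setting and assumptions

The input is an ordered sequence of 2-D section images cut from one tissue
block. The pipeline assumes that consecutive sections show largely the
same anatomy (sections a few micrometres apart), deformed by

* a global rigid/affine placement error — arbitrary rotation, small
  scale change, translation;
* a smooth, moderate elastic deformation from cutting and mounting;
* global intensity changes (staining intensity, illumination), and
* uncorrelated fine-grain content change between sections.

It does **not** model topological damage (tears, folds, missing pieces) or
multi-section slides; such slices fail gracefully (flagged, identity
transform) rather than being repaired.

## Coordinate conventions

All modules share one convention: coordinates are 0-based with `x` the
column index and `y` the row index, origin at the centre of the top-left
pixel. Affine transforms map *moving* coordinates into the *fixed* frame,
`x' = A q + t`. Images are always resampled with backward maps (the output
pixel pulls its value from the input image), so warped images have no
holes. Landmark CSV files use the same 0-based pixel convention; this is
stated explicitly because a silent 1-pixel disagreement between image and
landmark conventions is otherwise invisible and corrupts every metric.

## Stage 1: keypoints and the rotation search

The built-in backend is deliberately classical so the package works with
zero downloads: Harris corner detection (derivative scale ≈ 1, integration
scale 1.5), 3×3 non-maximum suppression, a response threshold relative to
the image maximum (default 0.001), and a cap of 800 keypoints. Descriptors
are 16×16 intensity patches, Gaussian-windowed, zero-mean and
unit-normalized — invariant to affine intensity changes but **not** to
rotation. Matching is mutual-nearest-neighbour with a 0.9 ratio test.

Rotation invariance is provided *explicitly* by the rotation search: the
moving image is rotated through a candidate set (default 30° steps), and
the angle producing the most RANSAC-consistent matches wins, ties going to
the smallest absolute angle. Two design points deserve justification:

* **Upright patches by default.** An orientation-normalized descriptor
  (available via `orient_patches = TRUE`) would make match counts nearly
  equal across candidate angles, so the search could no longer identify
  the true orientation — the angle would collapse to the tie-break. The
  division of labour is therefore: descriptors handle the ≤ ±15° residual
  left by the 30° grid; the search handles everything larger. This mirrors
  the practical reason rotation preprocessing exists at all: fast feature
  matchers tend to be orientation-sensitive.
* **Keypoint density matters more than keypoint quality.** With elastic
  deformation of a few pixels, individual correspondences are noisy;
  reliable affine estimation needs tens of tentative matches so that
  RANSAC can find a consistent subset. The low default response threshold
  and the 800-keypoint cap were chosen (on synthetic stacks) so that a
  256×256 textured section yields several hundred keypoints; sparser
  settings produced occasional 3-inlier fits — formally "successful" but
  wildly wrong. If your sections are much larger or low-texture, scale
  `max_keypoints` with image area.

The trial rotation is never baked into the image: the winning matches are
mapped back to the original moving frame, and the affine stage estimates
one transform in original coordinates. This avoids a second interpolation
of the moving image.

## Stage 2: robust affine estimation

RANSAC samples minimal 3-pair subsets (the exact-fit size for an affine),
counts inliers at a 3 px residual threshold, and runs 2000 iterations by
default (500 during the per-angle search, where only the *count* matters).
The final transform is re-fit by least squares on the winning inlier set.
The estimator is deterministic given the configured seed, and the seed is
perturbed per hop and per candidate angle so repeated draws are
independent but reproducible. Degenerate samples (collinear triples) are
skipped by a determinant test; fewer than three inliers is reported as
failure with an identity transform rather than an exception.

## Stage 3: B-spline free-form refinement

The non-rigid model is a tensor-product B-spline displacement field
`T(x) = x + Σ_ij c_ij B_i(u) B_j(v)` over a uniform grid of spline cells
covering `[0, Nx] × [0, Ny]` (default 8×8 cells, cubic; a degree-k spline
carries k extra control rows/columns of padding so the whole domain,
borders included, lies in the spline support). Basis weights come from the
Cox–de Boor recursion; dense evaluation is two small matrix products,
which also makes the exact gradient with respect to the control points a
pair of matrix products.

### Similarity term

The local NCC loss is computed over all pixels whose `(2r+1)²` window
(default r = 4) lies fully inside the image. Per window the package uses
the *squared* correlation form

    CC(x) = S_num(x)² / (S_den1(x) · S_den2(x) + ε),

which is bounded in [0, 1], equals 1 for locally affine-identical patches,
and needs no square root in the gradient. Two numerical choices:

* **Relative stabilizer.** ε is scaled to the window pixel count and the
  dynamic ranges of both images, `ε = (10⁻⁶ · n · r_F · r_W)²`. An
  absolute ε would make the loss scale-dependent: identical images in
  [0, 1] would score noticeably worse than the same images in [0, 255].
  With the relative form, an image correlates with itself to −1 within
  ~10⁻⁸ at any intensity scale, and the flat-window limit (both variances
  → 0) stays finite.
* **Normalization.** The window sum is divided by the number of valid
  windows, so one `lambda` default works across image sizes. The bare sum
  is available (`normalize_ncc = FALSE`).

### Regularization term

The smoothness penalty is the diffusion form: half the mean squared
forward difference of the displacement field, with the axis scale factors
`s_x = Nx`, `s_y = Ny` applied to displacements expressed as fractions of
the image extent. Inside the optimizer this is evaluated on the
*normalized* displacement field (components divided by `Nx`, `Ny`), which
for square images reduces exactly to the plain squared-difference penalty
in pixel units. The reason is balance: applied literally to pixel-unit
displacements, the `Nx²` scale factor would multiply the penalty by ~10⁴
for a 256² image and any useful deformation would be crushed at λ ≈ 1;
on normalized displacements, λ = 1 weights a deformation of a few pixels
against an NCC improvement of a few percent, which is the intended
trade-off. The standalone `diffusion_reg()` applies the definition
literally to whatever field it is given (the linear field `u_x = x/Nx`
scores exactly 0.5).

### Optimizer

Control points start at zero (identity). The update is a *normalized*
gradient step with backtracking: each accepted iteration moves the largest
control-point component by at most the current step size (`alpha`,
default 1 px), and the step is halved whenever it would increase the loss,
growing back by 25% after accepted steps. Plain fixed-rate gradient
descent was rejected because the raw gradient magnitude depends on image
content, size, and intensity scale, so no single literal learning rate is
meaningful across inputs; the normalized step gives `alpha` pixel units
and makes the default portable. Side effects of this choice: the recorded
loss trace is non-increasing by construction, `alpha = 0` is an exact
no-op that stops at the first tolerance check, and convergence is declared
when the loss improves by less than `tol` (10⁻⁶) or no descent step can be
found. Warped samples that fall outside the moving image take the
configured background value and propagate zero gradient, so the boundary
cannot "suck" the field outward. RGB sections are reduced to luminance
(0.299 R + 0.587 G + 0.114 B) for the loss; the final field warps all
channels. The optimization is single-resolution; a coarse-to-fine pyramid
would extend the capture range but is beyond the present scope.

## Composition and stacking

Hop `t` stores the affine (moving → fixed points) and the B-spline field
(a *backward* image map, fixed grid → affinely-warped moving
coordinates). The point map of a hop is therefore affine followed by the
field's inverse; the field inverse is computed by fixed-point iteration
(`x ← y − u(x)`, 10 iterations or 0.1 px), which converges quickly for
the smooth few-pixel fields this stage estimates. Composites to the
anchor chain these primitives exactly on *coordinates*; images are
resampled once through the full chain, never through intermediate images.
The default anchor is the middle slice: cumulative error grows with chain
length, and anchoring centrally halves the longest chain compared with
anchoring at an end. Outside its domain a field contributes its
nearest-domain displacement (constant extension), so chained coordinates
that leave one slice's canvas remain well-defined.

## The synthetic world

`make_synthetic_stack()` generates the package's test bed. Slice 0 is
multi-scale smoothed noise plus elliptical textured blobs (corner-rich by
construction); each hop applies an affine (rotation up to ±20°, isotropic
scale 0.97–1.03, translation up to ±15 px — magnitudes typical of slide
placement error at working resolution) composed with a sum of Gaussian
bumps rescaled to a 5 px maximum (σ = 40 px), then a global gain/offset
jitter of ±10% and fresh fine-grain noise. Landmarks are sampled ≥ 10% of
the image size from the borders and propagated through the *exact* hop
transforms (numeric inversion to ~10⁻¹² px), so the generator is its own
oracle; self-consistency is asserted in the test suite at 10⁻⁹.

What the generator does **not** emulate: stain-specific colour
distributions, tears/folds (topological change), partial tissue, and the
content drift of widely separated sections. A green end-to-end test
therefore establishes that the pipeline solves the *geometric* problem it
models — not that it survives every pathology of real slide archives.
Two regimes separate the stages in testing: with zero elastic amplitude
the affine stage alone must recover hops to subpixel accuracy; with
positive amplitude the non-rigid stage must reduce the remaining error.

## Degenerate inputs and tie-breaks

* Constant (textureless) images yield an empty keypoint set with a
  warning flag; downstream the pair is flagged and carries identity
  transforms, and the sequence pipeline completes.
* Rotation-search ties go to the smallest absolute angle (on (−180°,
  180°]); below 3 inliers at every angle the search reports failure at 0°.
* RANSAC ties on inlier count go to the smaller mean inlier residual,
  then to the earlier hypothesis — deterministic for a fixed seed.
* Medians of an even number of values are midpoints (R's default);
  robustness uses the *strict* inequality `rTRE < rIRE`, so a tie is not
  an improvement.
* The initial-error reference for robustness is the moving-image landmark
  position itself, normalized by the fixed image's diagonal.

## Limitations

* Pure pairwise chaining: errors still accumulate over long chains (the
  anchor choice only halves the exponent base, so to speak); groupwise
  refinement over all slices simultaneously is future work.
* The built-in backend assumes textured grayscale-representable content;
  very sparse or periodic textures can starve or alias the matcher.
* Single-level FFD: deformations beyond the capture range of the control
  grid and NCC window (~half a cell) require a pyramid or a denser grid.
* Whole-slide pyramid formats are out of scope; downsample externally and
  register at a working resolution.
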