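---
title: "Atlas propagation for mouse-brain volumes: models, parameters and validation"
author: "atlasmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas propagation for mouse-brain volumes: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasmap)
```

# The problem

Brain-wide mapping experiments image whole mouse brains as serial coronal
section stacks and need every labelled cell assigned to a named anatomical
structure. Manual delineation does not scale and is surprisingly
inconsistent even among experts, so the standard approach is *atlas
propagation*: register an annotated average-brain atlas onto each sample
volume and carry the atlas labels through the recovered spatial
transform. `atlasmap` implements this pipeline end to end together with the
validation machinery needed to benchmark it — consensus estimation from
rater panels (STAPLE and shape-based averaging), overlap and distance
metrics, and a synthetic phantom generator that provides ground truth for
every stage without any external data.

# The registration model

The pipeline recovers a mapping $T$ from sample (reference) world
coordinates to atlas (floating) world coordinates in two stages.

**Affine stage.** A symmetric block-matching scheme: the reference volume
is partitioned into non-overlapping cubes (default edge 4 voxels), the
most intensity-variant half is retained, and each retained block is matched
to the integer displacement (default search radius 3 voxels) maximizing
normalized cross-correlation, refined to sub-voxel precision by a per-axis
parabolic fit of the correlation peak. A least-trimmed-squares affine fit
(default keep fraction 0.5) makes the estimate robust to spurious matches.
Matching runs in both directions and the forward update is averaged with
the inverted backward update in the matrix-log domain, giving a symmetric,
deterministic update; the loop iterates over a coarse-to-fine pyramid.

**Free-form stage.** The residual non-linear deformation is modelled as a
displacement field $D(x)$ interpolated by tensor-product cubic B-splines
from a regular control-point lattice (default spacing 10 reference voxels),
composed over the affine: $T(x) = A x + D(x)$. The control displacements
maximize

$$J = (1 - w)\,\mathrm{NMI}(R, F \circ T) - w\,\mathrm{BE}(D),$$

where NMI is normalized mutual information, $(H_R + H_F)/H_{RF}$ in nats,
computed from a joint histogram with first-order (linear) Parzen binning,
and BE is the bending energy — the mean over a dense sampling of the
reference grid of the sum of squared second spatial derivatives of $D$
(mixed terms doubled), zero exactly for globally affine fields. The default
weight is $w = 0.95$. Optimization is conjugate-gradient ascent
(Polak-Ribière+) with a backtracking line search on an analytic gradient,
over a coarse-to-fine pyramid of images and lattices. Intensity assumptions
are mild: NMI only requires a consistent statistical relationship between
the intensity distributions of sample and atlas, which is why a
background-fluorescence sample can be registered to an autofluorescence
average brain.

Labels are then carried by nearest-neighbour pull-back through $T$. Before
transformation the atlas labels are smoothed twice with a 0.5-voxel
Gaussian to suppress the single-voxel border jitter typical of atlases
reconstructed from serial 2D annotations; smoothing acts on per-label
indicator images followed by an argmax (background included), never on the
raw integer ids, so no spurious intermediate labels can appear (the literal
integer-smoothing mode remains available behind a flag for fidelity
experiments).

# Validation machinery

Because no ground truth exists for real brains, segmentation quality is
scored against a consensus estimated from panels of manual raters.

* **STAPLE** is the binary EM algorithm that treats the true mask as
  hidden and alternates between a per-pixel posterior (E-step) and
  per-rater sensitivity/specificity estimates (M-step), all raters
  initialized at the same level (default 0.99). Estimation runs inside an
  analysis region of interest — the bounding box of the panel union
  dilated by 10 px — because specificity over an effectively infinite
  empty background is degenerate; the ROI is configurable and the
  foreground prior defaults to the mean foreground fraction over it.
  Posterior ties at 0.5 threshold to foreground.
* **SBA** (shape-based averaging) averages per-mask signed Euclidean
  distance transforms and keeps pixels with mean signed distance at most
  zero.
* **Metrics**: Dice $2|A\cap B|/(|A|+|B|)$ (two empty masks score 1,
  documented; one empty scores 0), symmetric Hausdorff distance over
  foreground pixel centres in micrometres (computed over all foreground
  pixels rather than boundaries only — the value is identical), pairwise
  z-distance of rater section choices (section step 15 µm by default),
  best-count z-window filtering (ties to the lowest starting section), and
  landmark distances through the composed transform with support for
  omitting named landmarks.
* **3D→2D reduction**: automated segmentations are 3D, raters draw single
  coronal planes. The structure's outline is extracted on each candidate
  section, filled, resampled to the 4 µm scoring grid, and the plane with
  the highest Dice against the consensus is selected (ties to the lowest
  z).

# The phantom generator

`makePhantom()` builds a 64³ volume at 12.5 µm isotropic spacing — the
working resolution of the pipeline — holding an ellipsoidal cortex shell
and four nuclei of graded size (radii roughly 4–10 voxels), emulating a
target set spanning a range of sizes and difficulty. Intensity is composed
of per-structure offsets over a bright interior, a smooth anatomical
texture field (correlation length 1.5 voxels, s.d. 12 intensity units)
that stands in for vasculature and cytoarchitecture and *deforms with the
tissue*, a low-frequency bias field, partial-volume edge softening, and
independent Gaussian acquisition noise (s.d. 5). The texture matters: real
autofluorescence is textured everywhere, and without it block matching has
no purchase on locally linear intensity patches (normalized
cross-correlation is blind to gain and offset).

`makeDeformedPair()` warps a noiseless phantom through a known random
affine (default rotation ±6°, scale 0.95–1.05, translation ±3 voxels)
composed with a known smooth FFD (default control spacing 16 voxels,
maximum displacement 4 voxels — below half the spacing, which guarantees a
fold-free field; the minimum Jacobian determinant is asserted positive at
generation). Labels are carried exactly by nearest neighbour, landmarks by
Newton inversion of the transform (verified to 10⁻⁹), and independent
noise is added to both volumes afterwards, so the pair behaves like two
separately acquired images of the same deformed anatomy.

`simulateRaters()` corrupts a true mask through two composable channels:
smooth boundary jitter (a low-order Fourier perturbation of the contour
applied through the signed distance function, which keeps masks closed and
simply connected) and per-pixel Bernoulli flips at rates $1-p$ and $1-q$ —
exactly the STAPLE generative model, applied over the whole plane. The
drawn per-rater $(p, q)$ are returned so recovery can be tested.

**What passing phantom tests do and do not show.** The phantom exercises
the full numerical machinery under known truth, but its anatomy is convex,
its texture stationary, and its deformations smooth and modest. Real
stacks add tiling artifacts, missing tissue, asymmetric damage, larger
shape differences, and atlas annotation errors; performance there must be
judged by rater-panel validation, not extrapolated from phantom scores.

# Numerical choices

* **Bending-energy convention.** BE is computed with displacements in
  millimetres and derivatives with respect to the control-grid index, the
  convention of the clinical registration toolkits under which penalty
  weights such as 0.95 are conventionally quoted. A dimensionless
  convention would silently change the meaning of the weight.
* **Pyramid depth on small volumes.** The standard schedule (6 levels,
  coarsest 5 computed for the affine stage, coarsest 4 for the free-form
  stage) is defined for full-size brains. Levels whose downsampled minimum
  dimension falls below 16 voxels are skipped, and the computed-level
  count then applies to the coarsest *available* levels; on a 64³ phantom
  all three available levels are optimized. The carried (uncomputed)
  finest levels receive the control lattice by exact dyadic B-spline
  subdivision without further optimization.
* **Histogram bins per level.** The requested bin count (default 128)
  applies at full-data resolutions; at each pyramid level the effective
  count is capped near the cube root of the voxel count (power of two,
  floor 16) so the joint histogram stays populated and the NMI gradient
  informative.
* **Gradients.** The NMI gradient uses the analytic Parzen chain rule with
  the floating-image spatial gradient precomputed by central differences;
  it is optionally smoothed over the lattice (default 1 knot s.d.) before
  the conjugate-gradient step. The line search only ever accepts improving
  steps, so the reported objective trace is non-decreasing by
  construction; convergence is declared at a relative gain below 10⁻⁵ or
  300 iterations per level.
* **Degenerate inputs.** Constant reference volumes abort block matching
  ("no informative blocks"); empty overlap aborts NMI; all-empty panels
  abort STAPLE; empty masks abort SBA and Hausdorff with the offending
  rater named. Boundary handling for all Gaussian filters is half-sample
  reflection, avoiding edge dimming at the brain boundary; out-of-field
  resampling pads with 0, the dark background of fluorescence data.
* **Preprocessing order.** Anisotropic z-smoothing (5 voxel s.d. at native
  resolution) precedes isotropic downsampling to 12.5 µm; in-plane
  anti-aliasing uses a 0.4·(target/source)-voxel Gaussian. Downsampling
  interpolates trilinearly. Phantom experiments feed the phantom in as
  already-preprocessed data (z-smoothing disabled in the experiment
  configuration) since the phantom is generated directly at the working
  resolution, whereas the 5-voxel z-smoothing is defined at the native
  5 µm section step of raw stacks.

# Problem sizes used by the test-suite experiments

The shipped experiments are sized for a desk-scale single-CPU run: affine
recovery uses twenty 64³ phantoms; free-form recovery one 64³ phantom under
the default configuration; regularization behaviour a 32³ pair;
the 18-weight sweep a 24³ pair with a reduced iteration cap; the
end-to-end rater experiment a 32³ phantom with six simulated raters per
structure at the 4 µm scoring grid. These sizes were chosen so each
experiment probes the full algorithm while completing in seconds to a few
minutes.

# Known limitations

* Binary STAPLE only; multi-label consensus, spatially varying performance
  models and MAP priors are out of scope.
* The similarity defaults to NMI; locally normalized cross-correlation is
  accepted as a configuration value for parameter searches but is not the
  validated default.
* The free-form model is not guaranteed diffeomorphic; folding is
  *diagnosed* (negative-Jacobian fraction) rather than prevented, with the
  bending-energy weight as the practical control.
* Registration quality on real data depends on acquisition artifacts the
  phantom does not model; qualitative inspection of overlaid outlines
  remains advisable.

# A worked example

```{r example, eval = FALSE}
pair <- makeDeformedPair(phantomSpec(seed = 5))
cfg <- defaultConfig(preprocess.z_sigma_vox = 0)
run <- runPipeline(pair$moving, pair$fixed, pair$fixedLabels, cfg)
labelDice(run$labels, pair$deformedLabels)
```

See the README for the numbers this prints and
`scripts/acceptance.R` for the full set of recomputed validation
quantities.
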