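# atlasmap

Automated anatomical segmentation of 3D mouse-brain volumes by atlas
propagation, with the complete validation framework needed to benchmark it
against human raters.

Whole-brain microscopy (e.g. serial two-photon tomography) produces
volumes in which every labelled cell must be assigned to a named
anatomical structure. `atlasmap` segments such volumes by registering an
annotated average-brain atlas onto each sample — a symmetric
block-matching **affine** registration followed by a cubic B-spline
**free-form deformation** that maximizes

    J = (1 − w) · NMI(R, F ∘ T) − w · BE(T),      T(x) = A x + D(x)

where NMI is normalized mutual information, (H(R)+H(F))/H(R,F), from a
128-bin Parzen joint histogram, BE is the bending energy (mean squared
second derivatives of the displacement field D) with default weight
w = 0.95, and D is interpolated from a control-point lattice with 10-voxel
spacing. Atlas labels are carried through the recovered transform by
nearest-neighbour pull-back after per-label Gaussian de-jittering
(0.5 voxel s.d., two passes).

Because anatomical "ground truth" does not exist for real brains, the
package also implements the validation side: **STAPLE** (EM estimation of
a consensus segmentation plus per-rater sensitivity/specificity),
**shape-based averaging**, Dice and Hausdorff scoring, z-distance and
z-window analyses of rater section choices, landmark distances, a
bending-energy sweep harness, and a **synthetic phantom generator** with
known deformations, exact labels, analytic landmarks and simulated rater
panels, so every stage is testable with no external data.

Who it is for: labs running atlas-propagation pipelines on high-resolution
rodent imaging who need a validated, scriptable, fully reproducible
implementation — and a way to quantify how well it works.

## Worked example

Segment a synthetic brain whose true deformation is known, then score the
result per structure:

```r
library(atlasmap)

pair <- makeDeformedPair(phantomSpec(seed = 5))
pair$fixedLabels
#> LabelVolume: 64 x 64 x 64 voxels, 5 structures, spacing (12.5, 12.5, 12.5) um
#>    1=CTX, 2=HPC, 3=TH, 4=VPM, 5=ACA

cfg <- defaultConfig(preprocess.z_sigma_vox = 0)  # phantom is pre-downsampled
run <- runPipeline(pair$moving, pair$fixed, pair$fixedLabels, cfg)

round(labelDice(run$labels, pair$deformedLabels), 3)
#>     1     2     3     4     5
#> 0.983 0.992 0.990 0.993 0.969
```

Each number is the 3D Dice overlap between the propagated label and the
ground-truth deformed label of that structure (1 = perfect): the pipeline
recovers the unknown affine + 4-voxel free-form deformation to ~99%
overlap on most structures. The recovered transform also aligns the ten
anatomical landmarks to a mean error of

```r
round(landmarkDistance(pair$deformedLandmarks, pair$fixedLandmarks,
                       run$affine, run$ffd)$meanUm, 2)
#> [1] 2.16
```

micrometres — about a sixth of a voxel. Rater-panel validation works the
same way on simulated panels: `simulateRaters()` → `staple()` / `sba()` →
`scorePanel()`; `runValidationExperiment()` wires the whole loop together
deterministically from one seed.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/atlasmap` (subcommands `phantom`, `affine`, `f3d`,
`segment`, `outline`, `consensus`, `score`, `sweep`; all accept
`--config`).

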