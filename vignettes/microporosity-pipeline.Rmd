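---
title: "Quantifying cortical bone microporosity from micro-CT: methods and design notes"
author: "PoroCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical bone microporosity from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoroCT)
```

## The measurement problem

Osteocytes live in ellipsoidal cavities (lacunae, roughly 100–1500 µm³)
connected by sub-micron canaliculi, and cortical bone is additionally
perforated by vascular canals (> 1500 µm³). Changes in this intracortical
pore network — lacunar shrinkage, canal dilation, infilling — accompany
estrogen deficiency and other bone diseases, but they sit at the
resolution limit of laboratory micro-CT (≈ 2 µm isotropic voxels).
PoroCT implements the full quantification chain for such data: density
calibration, region-of-interest definition, segmentation, pore
classification, porosity and morphometry statistics, mineral density
distribution analysis, matching 2D electron-microscopy section
measurements, and group statistics. Because studies of this kind rarely
deposit raw scans, the package also ships a phantom generator whose
analytic ground truth lets every stage be validated by parameter
recovery rather than by comparison with inaccessible data.

## Pipeline model

1. **Calibration** (`readStack`): grey levels map linearly to tissue
   mineral density (TMD), `density = grey·slope + intercept`, in
   mg HA/ccm. DICOM rescale tags are honored when present; TIFF stacks
   use a YAML sidecar. The in-memory convention is fixed once: axis
   order (slice, row, column), 0-based indices, half-open crop ranges.
2. **Region of interest** (`interpolateContours`, `middleThirdMask`):
   the user outlines the trabecular network or cortical band on sparse
   keyframe slices; intervening slices are interpolated. We blend the
   *signed distance fields* of the bracketing polygons linearly in the
   slice coordinate and threshold at zero. SDF blending is the standard
   shape-morphing construction: it is exact for nested level sets,
   varies the area monotonically for nested convex contours, and
   handles shape change smoothly. The distance fields are sampled from
   the continuous polygons (point-to-edge distances), so interpolated
   boundaries carry sub-voxel positions; at keyframes the mask is the
   rasterized polygon itself (voxel center inside, even-odd rule).
   Whether the original scanner software interpolates linearly or with
   splines is not documented anywhere we could find; linear blending is
   the simplest defensible choice and is stated here once.
   The "middle third" of a cortical band is defined by geodesic
   arc-length between two anchor landmarks: each band voxel gets
   `t = d1/(d1 + d2)` from within-band chamfer distances to the two
   anchors, and `1/3 ≤ t < 2/3` is retained.
3. **Segmentation** (`gaussianFilter`, `thresholdBone`): a separable
   Gaussian (σ = 0.8 voxels, truncated at ±1 voxel and renormalized —
   the Scanco-style sigma/support parameterization) with mirrored
   boundaries, then a global TMD threshold of 780 mg HA/ccm.
   The comparison is inclusive (≥), the lower-bound convention of
   scanner thresholds. The filter runs on the full volume before
   masking so ROI edges are not darkened.
4. **Microporosity** (`extractPores`, `labelPores`,
   `microporosityMetrics`): pores are the ROI-restricted complement of
   bone. Components are found under 26-connectivity — the natural dual
   of face-connected bone; anything weaker fragments thin connections —
   and classified by *physical* volume so the thresholds stay
   resolution-independent: < 100 µm³ noise, 100–1500 µm³ (closed
   interval) lacuna, > 1500 µm³ canal. Pores touching the ROI border
   are kept but flagged, and metrics can be computed with or without
   them, since any censoring rule biases canal statistics. Reported
   metrics: Lc.V/TV (%), N.Lc/mm³, Ca.V/TV (%), N.Ca/mm³ and Ca.Dm
   (µm).
5. **Morphometry** (`bvTv`, `localThickness`, `morphometryMetrics`):
   BV/TV by voxel counting; Tb.Th and Tb.Sp by the model-independent
   (Hildebrand–Rüegsegger) local thickness — the volume-weighted mean
   diameter of the largest inscribed sphere through each voxel,
   computed from the exact Euclidean distance transform with
   containment-exact ridge pruning. Tb.N uses the plate-model estimate
   (BV/TV)/Tb.Th: the scanner's mid-axis Tb.N algorithm is
   unpublished, and the plate model keeps the four metrics internally
   consistent; this substitution is flagged in the documentation.
6. **BMDD** (`peelSurface`, `bmddHistogram`, `findFwhm`): two one-voxel
   erosions with the 6-connected (face) structuring element strip
   exactly 4 µm from every surface at 2 µm voxels — the arithmetic that
   motivates the face-connected choice — before histogramming TMD.
   Summary statistics are the weighted mean and the full width at half
   maximum about the global peak, with linearly interpolated half-max
   crossings.
7. **2D sections** (`percentPoreArea`, `lacunaAxes`,
   `corticalThickness2d`, `canalicularDiameter`): backscattered
   electron images are colour-thresholded by a user-supplied grey level
   (no automatic threshold is claimed); pore components split into
   lacunar vs vascular by section area; lacuna axes come from the
   moment-equivalent ellipse (whether the microscope vendor tool
   measures moment or Feret axes is unknown; moment ellipses are
   rotation-invariant and standard); cortical thickness is twice the
   EDT averaged along the band's medial ridge; canalicular diameter is
   the sub-pixel width of a below-threshold run in a line profile.
8. **Statistics** (`aggregatePerAnimal`, `studentsT`,
   `boxplotSummary`): repeated measurements collapse to one value per
   animal; groups are compared with the equal-variance (pooled SD)
   two-tailed Student's t-test — not Welch — at α = 0.05, with
   five-number boxplot summaries (interpolated quartiles, whiskers at
   the extremes). No multiple-testing correction is applied, mirroring
   common practice in this literature; treat marginal p-values
   accordingly.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| voxel size | 2 | µm | resolution of the emulated scans |
| Gaussian σ / support | 0.8 / 1 | voxels | standard scanner denoising setting |
| bone threshold | 780 | mg HA/ccm | global TMD threshold separating bone |
| noise / lacuna / canal bounds | 100, 1500 | µm³ | established lacunar volume limits |
| peel layers | 2 | voxels | removes 4 µm of partial-volume surface |
| BMDD bin width | 5 | mg HA/ccm | FWHM interpolation error ≪ biological group differences |
| 2D lacuna/vascular area split | 80 | µm² | section area of a mid-range lacuna; exposed as config |

## The phantom generator

`generateCorticalPhantom` emulates a cortical band of mineralized
matrix, `N(1200, 60)` mg HA/ccm clipped at zero, containing prolate
ellipsoidal lacunae and cylindrical canals carved to density 0, then a
Gaussian point-spread blur (σ = 0.8 voxels) followed by additive
detector noise (SD 25 mg HA/ccm) — blur before noise, since the scanner
blurs structure and the detector adds noise afterwards. Lacunar volumes
default to a log-uniform draw on 100–600 µm³ (the span reported for
healthy lacunae; the in-vivo distribution shape is not documented, so
uniform and log-normal draws are also available) with a fixed 2.9:1
long:short axis ratio, matching measured long/short axis diameters of
roughly 9.5/3.3 µm. Placement is rejection-sampled with a 2-voxel
minimum surface gap so no two pores merge; canals run the full slice
extent and are therefore border-flagged. Every phantom carries an
analytic truth ledger (per-pore geometry, exact porosities, density
parameters) that is internally consistent to 1e-12.

`generateTrabecularPhantom` provides plate stacks (exact
`BV/TV = t/(t+g)`, plates phased to stay clear of the volume edge) and
orthogonal rod lattices with inclusion-exclusion analytic bone
fraction. `renderSection` maps any slice linearly onto a [0, 255]
greyscale section for the 2D module.

What the phantoms do **not** emulate: beam hardening, ring artefacts,
partial-volume anisotropy, the canalicular network (below micro-CT
resolution), spatially correlated noise, and real lacunar shape
variation beyond a fixed aspect ratio. Recovery tests therefore
demonstrate correctness of the measurement chain, not robustness to
every scanner artefact.

## Numerical conventions and edge cases

- **Distance and thickness.** The EDT measures to the nearest
  background voxel *center*. This makes even-thickness plates exact
  (a 6-voxel plate reads 12 µm at 2 µm voxels) at the cost of a
  half-voxel convention elsewhere: odd plates read one voxel thick
  fat, and a single voxel reads `2·voxel_size`. Digitized cylinders
  and spheres recover their diameters within one voxel when
  voxel-centered. Sphere coverage during thickness assignment is
  inclusive at the radius, and only containment-non-redundant spheres
  are drawn (a sphere whose 26-neighbor's sphere contains it can never
  contribute), which is an exact pruning, not an approximation.
- **Histogram bins** are centered on multiples of the bin width, so
  round TMD values fall on bin centers and two-valued histograms have
  exact means. One empty bin is padded on each flank so FWHM
  interpolation always has a crossing; a single populated bin yields
  one bin width by this convention.
- **Erosion at the array edge** treats outside-volume as background, so
  surfaces at the volume boundary recede like any other — BMDD peeling
  must not retain partial-volume voxels merely because the scan was
  cropped there.
- **Degenerate statistics**: zero pooled variance with equal means
  gives t = 0, p = 1; rasterized polygons require ≥ 3 vertices; empty
  masks and ROIs raise errors rather than returning silent zeros.
- **Determinism**: all phantom randomness flows from the integer seed
  in `PhantomSpec`; the analysis chain itself is RNG-free, so the full
  pipeline is bit-reproducible (asserted down to CSV bytes in the
  tests).

## Validation scale

The test suite validates against analytic truths at sizes chosen to
keep the full run near a minute on one CPU: oracle equivalence for
connected components on one hundred 32³ masks, EDT against brute force
on 10³ grids, and phantom recovery at 160³–200³. One acceptance-grade
recovery runs at 400³ voxels (50 lacunae of 150–600 µm³, three 15 µm
canals): lacuna count is recovered exactly and porosities within a few
percent of analytic truth under digitization alone, which is why the
recovery phantoms disable blur and noise — the stated ±15 % band
covers voxelization loss, and blur-induced bias at a 780 threshold is
a property of the imaging model, not of the measurement chain being
validated.

## Known limitations

- Tb.N is a plate-model estimate, not the scanner's mid-axis method;
  absolute values are comparable within this package only.
- The 26/6 connectivity pair and the border-pore policy are documented
  choices where the underlying scanner scripts are unpublished;
  `labelPores` exposes the border flag so both censoring conventions
  remain available.
- BSE grey levels are treated as given; no grey-to-calcium (qBEI)
  calibration is attempted.
- Lacunae below the voxel-volume noise floor (100 µm³ ≈ 12.5 voxels at
  2 µm) are invisible by construction; resolution-driven undercounting
  relative to synchrotron studies is expected and affects both groups
  of a comparison equally.
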