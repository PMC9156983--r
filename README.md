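# PoroCT

Cortical bone microporosity, trabecular morphometry and mineral density
analysis for micro-CT, in R.

Laboratory micro-CT at ~2 µm isotropic resolution can resolve the two
dominant intracortical pore populations — osteocyte lacunae and vascular
canals — but turning a calibrated image stack into defensible numbers
requires a long chain of conventions: density calibration, semi-automated
region definition, filtering and thresholding, connected-component
classification, thickness estimation, partial-volume handling and group
statistics. PoroCT implements that chain end to end for researchers
studying bone microstructure (e.g. estrogen-deficiency models of
osteoporosis), and ships a synthetic phantom generator with analytic
ground truth so every stage is verifiable by parameter recovery without
access to raw scans.

## What it computes

- **Microporosity** — pores are the complement of bone inside the
  cortical ROI, labelled under 26-connectivity and classified by
  physical volume: < 100 µm³ noise, 100–1500 µm³ osteocyte lacunae,
  > 1500 µm³ vascular canals. Reported as lacunar porosity
  Lc.V/TV (%), lacunar density N.Lc (mm⁻³), canal porosity Ca.V/TV (%),
  canal density N.Ca (mm⁻³) and canal diameter Ca.Dm (µm,
  volume-weighted mean local thickness).
- **Trabecular morphometry** — BV/TV by voxel counting; Tb.Th and Tb.Sp
  by model-independent local thickness (largest inscribed spheres over
  the exact Euclidean distance transform); plate-model
  Tb.N = (BV/TV)/Tb.Th.
- **BMDD** — bone mineral density distribution after peeling two
  surface-voxel layers (4 µm at 2 µm voxels) to suppress partial-volume
  bias: weighted mean TMD ("mean mineral density") and full width at
  half maximum ("mineral heterogeneity"), both in mg HA/ccm.
- **2D BSEM measurements** — percent lacunar/vascular pore area by
  colour thresholding, moment-ellipse lacuna axes, medial-ridge
  cortical thickness, sub-pixel canalicular diameter from line
  profiles.
- **Group statistics** — per-animal aggregation, pooled-variance
  two-tailed Student's t-tests, boxplot five-number summaries.
- **Phantoms** — seeded cortical and trabecular volumes (ellipsoidal
  lacunae, cylindrical canals, Gaussian PSF, detector noise) with an
  analytic ground-truth ledger.

Segmentation defaults follow standard cortical-bone practice: Gaussian
filter σ = 0.8 voxels with support 1, global threshold 780 mg HA/ccm.

## Worked example

Generate a realistic phantom (2 µm voxels, matrix 1200 ± 60 mg HA/ccm,
40 lacunae, 2 canals, PSF blur and detector noise), run the full
cortical pipeline, and print the metrics:

```r
library(PoroCT)

spec <- phantomSpec(dim = c(160L, 160L, 160L), nLacunae = 40L,
                    nCanals = 2L, corticalThickness = 200, seed = 7L)
ph    <- generateCorticalPhantom(spec)
bone  <- segmentBone(ph$volume, ph$roi)          # filter + threshold 780
pores <- labelPores(extractPores(bone, ph$roi),
                    voxelSize(ph$volume), roi = ph$roi)
microporosityMetrics(pores, ph$roi, voxelSize(ph$volume))
#> Cortical microporosity metrics
#>   Lc.V/TV: 0.0303 %   N.Lc: 1025.4 /mm^3
#>   Ca.V/TV: 2.3747 %   N.Ca: 97.7 /mm^3   Ca.Dm: 30.34 um
#>   TV: 0.0205 mm^3

bmddHistogram(ph$volume, peelSurface(bone, 2))
#> Bone mineral density distribution
#>   mean TMD: 1199.8 mg HA/ccm   FWHM: 66.1 mg HA/ccm   n = 2241560 voxels
```

The canal diameter (30.3 µm vs the true 30 µm) and porosities recover
the ground truth in `ph$truth`; under these blurred, noisy conditions
only 21 of the 40 lacunae survive the 100 µm³ noise floor
(`table(pores$pore_class)` shows the rest demoted), the same
resolution-driven undercounting reported for real 2 µm scans — the
digitization-only recovery tests in `tests/testthat/` disable blur and
noise and recover the lacunar count exactly. Real scans enter the same
pipeline through `readStack()` (DICOM series or multi-page TIFF plus a
YAML calibration sidecar) and `interpolateContours()`/`middleThirdMask()`
for keyframe-based ROI definition.

See `vignettes/microporosity-pipeline.Rmd` for the full account of the
model, parameter choices and numerical conventions.

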