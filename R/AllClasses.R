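#' @import methods
NULL

#' Calibrated micro-CT volume
#'
#' The canonical in-memory representation of a micro-CT scan: a 3D grid of
#' tissue mineral density values in mg HA/ccm on an isotropic voxel grid.
#' The axis order is fixed as (slice, row, column), with the slice index
#' increasing distal to proximal; indices are 0-based in all coordinate
#' interfaces and crop ranges are half-open.
#'
#' Densities may be negative after calibration (air), but bone thresholding
#' never selects such voxels.
#'
#' @slot data 3D numeric array of tissue mineral density (mg HA/ccm),
#'   dimensions (slice, row, column).
#' @slot voxelSize isotropic voxel edge length in micrometers.
#' @slot provenance free-form list of metadata (source files, calibration
#'   slope/intercept, processing notes).
#'
#' @seealso [readStack()], [gaussianFilter()], [thresholdBone()]
#' @export
setClass("CalibratedVolume",
  representation(data = "array", voxelSize = "numeric", provenance = "list"),
  prototype(data = array(0, dim = c(1, 1, 1)), voxelSize = 2,
            provenance = list())
)

setValidity("CalibratedVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array (slice, row, column)")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number (um)")
  if (!all(is.finite(object@data)))
    return("density values must be finite")
  TRUE
})

#' Linear grey-to-density calibration
#'
#' Maps raw scanner grey levels to tissue mineral density:
#' `density = grey * slope + intercept` (mg HA/ccm).
#'
#' @slot slope (mg HA/ccm) per grey level; must be non-zero.
#' @slot intercept mg HA/ccm.
#'
#' @export
setClass("CalibrationMap",
  representation(slope = "numeric", intercept = "numeric"),
  prototype(slope = 1, intercept = 0)
)

setValidity("CalibrationMap", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope == 0)
    return("slope must be a single non-zero number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  TRUE
})

#' Boolean voxel masks
#'
#' `VoxelMask` is the common parent of the package's 3D boolean grids.
#' `RoiMask` marks the analysis region (trabecular compartment or medial
#' cortical third) built from per-slice contours; `BoneMask` marks
#' segmented bone and records the segmentation parameters used.
#'
#' @slot mask 3D logical array congruent with a [CalibratedVolume-class].
#'
#' @aliases RoiMask-class BoneMask-class
#' @export
setClass("VoxelMask",
  representation(mask = "array"),
  prototype(mask = array(FALSE, dim = c(1, 1, 1)))
)

setValidity("VoxelMask", function(object) {
  if (length(dim(object@mask)) != 3L)
    return("mask must be a 3D array")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (anyNA(object@mask))
    return("mask must not contain NA")
  TRUE
})

#' @slot label region label, one of `"trabecular"`,
#'   `"cortical_medial_third"` or `"full"`.
#' @rdname VoxelMask-class
#' @export
setClass("RoiMask",
  contains = "VoxelMask",
  representation(label = "character"),
  prototype(label = "trabecular")
)

setValidity("RoiMask", function(object) {
  ok <- c("trabecular", "cortical_medial_third", "full")
  if (length(object@label) != 1L || !object@label %in% ok)
    return(sprintf("label must be one of: %s", paste(ok, collapse = ", ")))
  TRUE
})

#' @slot params list of segmentation parameters (`gauss_sigma`,
#'   `gauss_support`, `threshold_mgHAccm`) or peeling provenance.
#' @rdname VoxelMask-class
#' @export
setClass("BoneMask",
  contains = "VoxelMask",
  representation(params = "list"),
  prototype(params = list())
)

#' Segmentation parameters
#'
#' Defaults follow standard cortical-bone micro-CT practice: a truncated
#' Gaussian filter with sigma 0.8 voxels and support (truncation radius)
#' 1 voxel, and a global bone threshold of 780 mg HA/ccm.
#'
#' @slot gaussSigma Gaussian sigma, voxel units, `>= 0`.
#' @slot gaussSupport kernel truncation radius, voxels, integer `>= 1`.
#' @slot threshold bone threshold, mg HA/ccm, `> 0`; comparison is
#'   inclusive (`density >= threshold` is bone).
#'
#' @export
setClass("SegmentationParams",
  representation(gaussSigma = "numeric", gaussSupport = "integer",
                 threshold = "numeric"),
  prototype(gaussSigma = 0.8, gaussSupport = 1L, threshold = 780)
)

setValidity("SegmentationParams", function(object) {
  if (object@gaussSigma < 0) return("gaussSigma must be >= 0")
  if (object@gaussSupport < 1L) return("gaussSupport must be >= 1")
  if (object@threshold <= 0) return("threshold must be > 0")
  TRUE
})

#' Cortical microporosity metrics
#'
#' Summary metrics of the intracortical pore network: lacunar porosity
#' Lc.V/TV (%), lacunar density N.Lc (1/mm^3), vascular canal porosity
#' Ca.V/TV (%), canal density N.Ca (1/mm^3), canal diameter Ca.Dm (um,
#' canal-volume-weighted mean local thickness) and the total analysed
#' volume TV (mm^3). `caDiameter` is `NA` when no canals are present.
#'
#' @slot lcPorosity Lc.V/TV, percent.
#' @slot lcDensity N.Lc per mm^3.
#' @slot caPorosity Ca.V/TV, percent.
#' @slot caDensity N.Ca per mm^3.
#' @slot caDiameter Ca.Dm, um.
#' @slot tv total (ROI) volume, mm^3.
#'
#' @seealso [microporosityMetrics()]
#' @export
setClass("MicroporosityMetrics",
  representation(lcPorosity = "numeric", lcDensity = "numeric",
                 caPorosity = "numeric", caDensity = "numeric",
                 caDiameter = "numeric", tv = "numeric")
)

setValidity("MicroporosityMetrics", function(object) {
  if (object@lcPorosity < 0 || object@lcPorosity > 100 ||
      object@caPorosity < 0 || object@caPorosity > 100)
    return("porosities must lie in [0, 100] percent")
  if (object@lcDensity < 0 || object@caDensity < 0)
    return("densities must be >= 0")
  if (object@tv <= 0) return("tv must be > 0")
  TRUE
})

#' Trabecular morphometry metrics
#'
#' @slot bvTv bone volume fraction BV/TV, dimensionless in `[0, 1]`.
#' @slot tbTh trabecular thickness Tb.Th, mm.
#' @slot tbN trabecular number Tb.N, 1/mm (plate model).
#' @slot tbSp trabecular separation Tb.Sp, mm.
#'
#' @seealso [morphometryMetrics()]
#' @export
setClass("MorphometryMetrics",
  representation(bvTv = "numeric", tbTh = "numeric", tbN = "numeric",
                 tbSp = "numeric")
)

setValidity("MorphometryMetrics", function(object) {
  if (object@bvTv < 0 || object@bvTv > 1) return("bvTv must be in [0, 1]")
  if (object@tbTh < 0 || object@tbSp < 0 || object@tbN < 0)
    return("tbTh, tbSp and tbN must be >= 0")
  TRUE
})

#' Bone mineral density distribution result
#'
#' Histogram of tissue mineral density over peeled bone voxels together
#' with its weighted mean (mean mineral density) and full width at half
#' maximum (mineral heterogeneity), both in mg HA/ccm.
#'
#' @slot binCenters histogram bin centers, mg HA/ccm (centers lie on
#'   multiples of the bin width).
#' @slot counts voxels per bin.
#' @slot meanDensity weighted mean tissue mineral density, mg HA/ccm.
#' @slot fwhm full width at half maximum, mg HA/ccm.
#' @slot nVoxels number of voxels after peeling (equals `sum(counts)`).
#'
#' @seealso [bmddHistogram()], [findFwhm()]
#' @export
setClass("BmddResult",
  representation(binCenters = "numeric", counts = "numeric",
                 meanDensity = "numeric", fwhm = "numeric",
                 nVoxels = "numeric")
)

setValidity("BmddResult", function(object) {
  if (length(object@binCenters) != length(object@counts))
    return("binCenters and counts must have equal length")
  if (abs(sum(object@counts) - object@nVoxels) > 1e-6)
    return("counts must sum to nVoxels")
  if (object@fwhm < 0) return("fwhm must be >= 0")
  rng <- range(object@binCenters)
  if (object@meanDensity < rng[1] - 1e-9 || object@meanDensity > rng[2] + 1e-9)
    return("meanDensity must lie within the bin center range")
  TRUE
})

#' 2D greyscale section image
#'
#' A backscattered-electron-style section: a greyscale pixel grid with a
#' physical pixel size.
#'
#' @slot pixels 2D numeric matrix of grey values.
#' @slot pixelSize micrometers per pixel, `> 0`.
#'
#' @seealso [renderSection()], [percentPoreArea()], [lacunaAxes()]
#' @export
setClass("SectionImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixels = matrix(0, 1, 1), pixelSize = 1)
)

setValidity("SectionImage", function(object) {
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um)")
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  TRUE
})

#' Synthetic bone phantom specification
#'
#' Parameters of the seeded phantom generator. Defaults emulate healthy
#' rat cortical bone scanned at 2 um: a mineralized matrix at
#' 1200 +/- 60 mg HA/ccm containing prolate ellipsoidal osteocyte lacunae
#' (volumes 100-600 um^3, long:short axis ratio 2.9) and cylindrical
#' vascular canals (radius 15 um), blurred by a Gaussian point-spread
#' function (sigma 0.8 voxels) with additive detector noise
#' (SD 25 mg HA/ccm). Set `psfSigma = 0` and `noiseSd = 0` for
#' digitization-only phantoms used in analytic recovery checks.
#'
#' @slot dim volume dimensions, voxels, (slice, row, column).
#' @slot voxelSize um per voxel.
#' @slot corticalThickness cortical band thickness, um.
#' @slot rodRadius trabecular rod radius, um.
#' @slot rodPitch trabecular lattice pitch, um.
#' @slot nLacunae number of lacunae to place.
#' @slot lacunaVolumeRange min/max lacunar volume, um^3.
#' @slot lacunaAspect long:short semi-axis ratio (prolate, two equal
#'   short axes).
#' @slot lacunaVolumeDist `"loguniform"`, `"uniform"` or `"lognormal"`.
#' @slot canalRadius vascular canal radius, um.
#' @slot nCanals number of canals (axis-parallel, full slice extent).
#' @slot densityMean mean matrix density, mg HA/ccm.
#' @slot densitySd matrix density SD, mg HA/ccm.
#' @slot psfSigma Gaussian PSF sigma, voxels.
#' @slot noiseSd additive noise SD, mg HA/ccm.
#' @slot seed integer RNG seed; generation is bit-reproducible.
#'
#' @seealso [phantomSpec()], [generateCorticalPhantom()],
#'   [generateTrabecularPhantom()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric",
                 corticalThickness = "numeric",
                 rodRadius = "numeric", rodPitch = "numeric",
                 nLacunae = "integer", lacunaVolumeRange = "numeric",
                 lacunaAspect = "numeric", lacunaVolumeDist = "character",
                 canalRadius = "numeric", nCanals = "integer",
                 densityMean = "numeric", densitySd = "numeric",
                 psfSigma = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  prototype(dim = c(160L, 160L, 160L), voxelSize = 2,
            corticalThickness = 200,
            rodRadius = 30, rodPitch = 160,
            nLacunae = 50L, lacunaVolumeRange = c(100, 600),
            lacunaAspect = 2.9, lacunaVolumeDist = "loguniform",
            canalRadius = 15, nCanals = 3L,
            densityMean = 1200, densitySd = 60,
            psfSigma = 0.8, noiseSd = 25,
            seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three positive integers")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (object@corticalThickness <= 0 || object@rodRadius <= 0 ||
      object@rodPitch <= 0 || object@canalRadius <= 0)
    return("all geometric dimensions must be > 0")
  if (object@nLacunae < 0L || object@nCanals < 0L)
    return("counts must be >= 0")
  if (length(object@lacunaVolumeRange) != 2L ||
      any(object@lacunaVolumeRange <= 0) ||
      diff(object@lacunaVolumeRange) < 0)
    return("lacunaVolumeRange must be an increasing positive pair (um^3)")
  if (object@lacunaAspect < 1) return("lacunaAspect must be >= 1")
  if (!object@lacunaVolumeDist %in% c("loguniform", "uniform", "lognormal"))
    return("lacunaVolumeDist must be loguniform, uniform or lognormal")
  if (object@densitySd < 0 || object@psfSigma < 0 || object@noiseSd < 0)
    return("densitySd, psfSigma and noiseSd must be >= 0")
  TRUE
})
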