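#' Accessors for PoroCT objects
#'
#' `densities()` returns the 3D density array of a
#' [CalibratedVolume-class]; `voxelSize()` its voxel edge length in um;
#' `maskArray()` the logical array of a [VoxelMask-class]; `roiLabel()`
#' the region label of a [RoiMask-class].
#'
#' @param x a PoroCT object.
#' @return the slot value.
#' @name accessors
#' @aliases densities voxelSize maskArray roiLabel
NULL

#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' Write a metrics record to a flat CSV file
#'
#' Serializes a result object (microporosity, morphometry or BMDD
#' metrics) to a one-row CSV with unit-suffixed column names; a list of
#' records of the same class becomes one row per record. Numeric fields
#' round-trip through [readMetrics()] to better than 1e-9 relative.
#'
#' @param x a [MicroporosityMetrics-class], [MorphometryMetrics-class] or
#'   [BmddResult-class] object, or a list of objects of one such class.
#' @param path output file path.
#' @param id optional specimen/ROI identifier(s), written as an `id`
#'   column.
#' @return invisibly, the data frame written.
#' @seealso [readMetrics()]
#' @export
setGeneric("writeMetrics", function(x, path, id = NULL)
  standardGeneric("writeMetrics"))

#' @rdname accessors
#' @export
setMethod("densities", "CalibratedVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "CalibratedVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "SectionImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomSpec", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("maskArray", "VoxelMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("roiLabel", "RoiMask", function(x) x@label)

#' @describeIn CalibratedVolume-class dimensions of the density grid.
#' @param x a `CalibratedVolume`.
#' @export
setMethod("dim", "CalibratedVolume", function(x) dim(x@data))

#' @describeIn VoxelMask-class dimensions of the mask grid.
#' @param x a `VoxelMask`.
#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@mask))

setMethod("show", "CalibratedVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "CalibratedVolume: %d x %d x %d voxels (slice x row x col) @ %g um\n",
    d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  density range: %.1f .. %.1f mg HA/ccm\n",
              min(object@data), max(object@data)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("%s: %d x %d x %d voxels, %d set (%.2f%%)\n",
              class(object), d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
  if (is(object, "RoiMask")) cat("  label:", object@label, "\n")
})

setMethod("show", "MicroporosityMetrics", function(object) {
  cat("Cortical microporosity metrics\n")
  cat(sprintf("  Lc.V/TV: %.4f %%   N.Lc: %.1f /mm^3\n",
              object@lcPorosity, object@lcDensity))
  cat(sprintf("  Ca.V/TV: %.4f %%   N.Ca: %.1f /mm^3   Ca.Dm: %s um\n",
              object@caPorosity, object@caDensity,
              ifelse(is.na(object@caDiameter), "NA",
                     sprintf("%.2f", object@caDiameter))))
  cat(sprintf("  TV: %.4f mm^3\n", object@tv))
})

setMethod("show", "MorphometryMetrics", function(object) {
  cat("Trabecular morphometry\n")
  cat(sprintf("  BV/TV: %.4f   Tb.Th: %.4f mm   Tb.N: %.3f /mm   Tb.Sp: %.4f mm\n",
              object@bvTv, object@tbTh, object@tbN, object@tbSp))
})

setMethod("show", "BmddResult", function(object) {
  cat("Bone mineral density distribution\n")
  cat(sprintf("  mean TMD: %.1f mg HA/ccm   FWHM: %.1f mg HA/ccm   n = %d voxels\n",
              object@meanDensity, object@fwhm, as.integer(object@nVoxels)))
})

setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage: %d x %d px @ %g um/px, grey %.1f .. %.1f\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %g um, seed %d\n",
              paste(object@dim, collapse = " x "), object@voxelSize,
              object@seed))
  cat(sprintf("  %d lacunae (%g-%g um^3, aspect %g), %d canals (r = %g um)\n",
              object@nLacunae, object@lacunaVolumeRange[1],
              object@lacunaVolumeRange[2], object@lacunaAspect,
              object@nCanals, object@canalRadius))
  cat(sprintf("  matrix %g +/- %g mg HA/ccm, PSF sigma %g vox, noise SD %g\n",
              object@densityMean, object@densitySd, object@psfSigma,
              object@noiseSd))
})
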