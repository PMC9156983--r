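#' Create segmentation parameters
#'
#' @param gaussSigma Gaussian sigma in voxels (default 0.8).
#' @param gaussSupport kernel truncation radius in voxels (default 1).
#' @param threshold global bone threshold, mg HA/ccm (default 780).
#' @return a [SegmentationParams-class].
#' @export
segmentationParams <- function(gaussSigma = 0.8, gaussSupport = 1L,
                               threshold = 780) {
  new("SegmentationParams", gaussSigma = as.numeric(gaussSigma),
      gaussSupport = as.integer(gaussSupport),
      threshold = as.numeric(threshold))
}

#' Read segmentation parameters from a YAML config
#'
#' Reads the `segmentation:` section (keys `sigma`, `support`,
#' `threshold`); missing keys fall back to the defaults of
#' [segmentationParams()].
#'
#' @param path YAML config path.
#' @return a [SegmentationParams-class].
#' @export
readSegmentationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$segmentation
  if (is.null(s)) s <- list()
  segmentationParams(
    gaussSigma = if (is.null(s$sigma)) 0.8 else s$sigma,
    gaussSupport = if (is.null(s$support)) 1L else s$support,
    threshold = if (is.null(s$threshold)) 780 else s$threshold)
}

#' Gaussian noise filter
#'
#' Separable discrete Gaussian, truncated at +/- `support` voxels and
#' renormalized to unit sum, applied along all three axes with mirrored
#' boundaries. `sigma = 0` is the identity; constant volumes are
#' unchanged.
#'
#' @param volume a [CalibratedVolume-class].
#' @param sigma Gaussian sigma, voxels, `>= 0`.
#' @param support truncation radius, voxels, integer `>= 1`.
#' @return the filtered [CalibratedVolume-class].
#' @examples
#' v <- new("CalibratedVolume", data = array(1000, c(8, 8, 8)),
#'          voxelSize = 2)
#' f <- gaussianFilter(v)          # constant volume is unchanged
#' stopifnot(all(abs(densities(f) - 1000) < 1e-9))
#' @export
gaussianFilter <- function(volume, sigma = 0.8, support = 1L) {
  stopifnot(is(volume, "CalibratedVolume"))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  d <- dim(volume@data)
  out <- cpp_gaussian_blur(as.numeric(volume@data), as.integer(d),
                           as.numeric(sigma), as.integer(support))
  new("CalibratedVolume", data = array(out, dim = d),
      voxelSize = volume@voxelSize,
      provenance = c(volume@provenance,
                     list(gauss_sigma = sigma, gauss_support = support)))
}

#' Global density threshold segmentation of bone
#'
#' A voxel is bone when its density is at least `threshold` (inclusive
#' comparison, lower-bound convention) and it lies inside the ROI.
#'
#' @param volume a [CalibratedVolume-class], typically after
#'   [gaussianFilter()].
#' @param roi a [RoiMask-class] (or 3D logical array) congruent with
#'   `volume`; `NULL` means the whole volume.
#' @param threshold mg HA/ccm, `> 0` (default 780).
#' @return a [BoneMask-class].
#' @export
thresholdBone <- function(volume, roi = NULL, threshold = 780) {
  stopifnot(is(volume, "CalibratedVolume"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  m <- volume@data >= threshold
  if (!is.null(roi)) {
    r <- asMaskArray(roi)
    stopCongruent(volume@data, r, "volume and roi")
    m <- m & r
  }
  new("BoneMask", mask = m,
      params = list(threshold_mgHAccm = threshold))
}

#' Filter and threshold in one step
#'
#' Convenience wrapper: [gaussianFilter()] on the full volume followed by
#' [thresholdBone()] within the ROI.
#'
#' @param volume a [CalibratedVolume-class].
#' @param roi a [RoiMask-class] or `NULL`.
#' @param params a [SegmentationParams-class].
#' @return a [BoneMask-class] carrying the parameters used.
#' @export
segmentBone <- function(volume, roi = NULL, params = segmentationParams()) {
  filt <- gaussianFilter(volume, params@gaussSigma, params@gaussSupport)
  bone <- thresholdBone(filt, roi, params@threshold)
  bone@params <- list(gauss_sigma = params@gaussSigma,
                      gauss_support = params@gaussSupport,
                      threshold_mgHAccm = params@threshold)
  bone
}
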