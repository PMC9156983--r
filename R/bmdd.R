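#' Peel surface voxel layers from a bone mask
#'
#' Removes `nLayers` one-voxel layers by iterated erosion with the
#' 6-connected (face) structuring element, so every segmented surface —
#' endosteal, periosteal, pore and trabecular, including surfaces at the
#' array edge — recedes by exactly `nLayers` voxels. With the default two
#' layers at 2 um voxels this strips 4 um of surface, excluding
#' partial-volume voxels from density statistics.
#'
#' @param bone a [BoneMask-class] (or 3D logical array).
#' @param nLayers integer `>= 0` (default 2).
#' @return a [BoneMask-class] of the peeled bone.
#' @examples
#' cube <- array(FALSE, c(14, 14, 14))
#' cube[3:12, 3:12, 3:12] <- TRUE
#' sum(maskArray(peelSurface(cube, 2)))  # 6^3 = 216
#' @export
peelSurface <- function(bone, nLayers = 2L) {
  if (nLayers < 0) stop("nLayers must be >= 0", call. = FALSE)
  m <- asMaskArray(bone)
  d <- dim(m)
  out <- array(cpp_erode6(as.logical(m), as.integer(d),
                          as.integer(nLayers)), dim = d)
  params <- if (is(bone, "BoneMask")) bone@params else list()
  new("BoneMask", mask = out,
      params = c(params, list(peel_layers = as.integer(nLayers))))
}

#' Bone mineral density distribution
#'
#' Histograms the tissue mineral density of the peeled bone voxels into
#' bins of width `binWidth` whose centers lie on multiples of the bin
#' width, and summarizes the distribution by its weighted mean (mean
#' mineral density) and full width at half maximum (mineral
#' heterogeneity), both in mg HA/ccm.
#'
#' @param volume a [CalibratedVolume-class].
#' @param peeled a [BoneMask-class] (or 3D logical array) after
#'   [peelSurface()]; must be nonempty and congruent with `volume`.
#' @param binWidth bin width in mg HA/ccm, `> 0` (default 5).
#' @return a [BmddResult-class].
#' @examples
#' v <- new("CalibratedVolume", data = array(1200, c(6, 6, 6)),
#'          voxelSize = 2)
#' m <- array(TRUE, c(6, 6, 6))
#' res <- bmddHistogram(v, m)
#' res@meanDensity  # 1200
#' @export
bmddHistogram <- function(volume, peeled, binWidth = 5) {
  stopifnot(is(volume, "CalibratedVolume"))
  if (binWidth <= 0) stop("binWidth must be > 0", call. = FALSE)
  m <- asMaskArray(peeled)
  stopCongruent(volume@data, m, "volume and peeled mask")
  if (!any(m)) stop("peeled mask is empty", call. = FALSE)
  vals <- volume@data[m]
  k <- floor(vals / binWidth + 0.5)  # bin centers at k * binWidth
  kr <- range(k)
  # pad one empty bin on each side so FWHM interpolation always has a
  # flank (single populated bin then yields one bin width)
  counts <- c(0, tabulate(k - kr[1] + 1L, nbins = kr[2] - kr[1] + 1L), 0)
  centers <- ((kr[1] - 1L):(kr[2] + 1L)) * binWidth
  meanD <- sum(centers * counts) / sum(counts)
  new("BmddResult", binCenters = centers, counts = as.numeric(counts),
      meanDensity = meanD, fwhm = findFwhm(centers, counts),
      nVoxels = sum(counts))
}

#' Full width at half maximum of a histogram
#'
#' Half maximum is half the global peak count; the two crossings are
#' located by linear interpolation between adjacent bins, walking outward
#' from the peak on each side. If the counts never fall below the half
#' maximum on a side (including the single-bin case) the corresponding
#' half-bin edge is used, so a single populated bin yields one bin width.
#' Multimodal histograms are summarized about the highest peak.
#'
#' @param binCenters increasing, equally spaced bin centers.
#' @param counts non-negative counts, at least one nonzero.
#' @return FWHM in the units of `binCenters`.
#' @examples
#' findFwhm(c(-1, 0, 1), c(0, 10, 0))  # triangle peak: one bin spacing
#' @export
findFwhm <- function(binCenters, counts) {
  if (length(binCenters) != length(counts))
    stop("binCenters and counts must have equal length", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  n <- length(counts)
  bw <- if (n > 1) binCenters[2] - binCenters[1] else NA_real_
  p <- which.max(counts)
  half <- counts[p] / 2

  left <- if (p == 1 || all(counts[1:(p - 1)] >= half)) {
    binCenters[1] - (if (is.na(bw)) 0 else bw / 2)
  } else {
    i <- max(which(counts[1:(p - 1)] < half))
    binCenters[i] + (half - counts[i]) / (counts[i + 1] - counts[i]) *
      (binCenters[i + 1] - binCenters[i])
  }
  right <- if (p == n || all(counts[(p + 1):n] >= half)) {
    binCenters[n] + (if (is.na(bw)) 0 else bw / 2)
  } else {
    j <- p + min(which(counts[(p + 1):n] < half))
    binCenters[j] - (half - counts[j]) / (counts[j - 1] - counts[j]) *
      (binCenters[j] - binCenters[j - 1])
  }
  right - left
}
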