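#' Bone volume fraction
#'
#' @param bone a [BoneMask-class] (or 3D logical array).
#' @param roi a [RoiMask-class] (or 3D logical array), nonempty,
#'   congruent with `bone`.
#' @return BV/TV, the fraction of ROI voxels that are bone.
#' @export
bvTv <- function(bone, roi) {
  b <- asMaskArray(bone)
  r <- asMaskArray(roi)
  stopCongruent(b, r, "bone and roi")
  n <- sum(r)
  if (n == 0) stop("empty ROI", call. = FALSE)
  sum(b & r) / n
}

#' Model-independent local thickness
#'
#' Direct 3D thickness in the sense of Hildebrand and Ruegsegger: each
#' foreground voxel is assigned the diameter of the largest sphere that
#' contains it and fits entirely within the structure, and the
#' volume-weighted mean over all foreground voxels is returned. Applied
#' to bone for Tb.Th and to the background within the ROI for Tb.Sp.
#'
#' @param mask 3D logical array (or [VoxelMask-class]), nonempty.
#' @param voxelSize um per voxel.
#' @param map if `TRUE`, also return the per-voxel thickness map.
#' @return mean thickness in um, or (with `map = TRUE`) a list
#'   `list(mean, map)` where `map` is in um.
#' @examples
#' m <- array(FALSE, c(20, 16, 16))
#' m[8:13, , ] <- TRUE            # 6-voxel plate = 12 um at 2 um
#' localThickness(m, voxelSize = 2)
#' @export
localThickness <- function(mask, voxelSize, map = FALSE) {
  m <- asMaskArray(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  th <- cpp_local_thickness(as.logical(m), as.integer(dim(m)))
  mn <- mean(th[m]) * voxelSize
  if (!map) return(mn)
  list(mean = mn, map = array(th * voxelSize, dim = dim(m)))
}

#' Plate-model trabecular number
#'
#' Tb.N estimated from the plate model as `(BV/TV) / Tb.Th`.
#'
#' @param bvTv bone volume fraction, in `[0, 1]`.
#' @param tbTh trabecular thickness in mm, `> 0`.
#' @return Tb.N in 1/mm.
#' @export
tbN <- function(bvTv, tbTh) {
  if (tbTh <= 0) stop("tbTh must be > 0", call. = FALSE)
  bvTv / tbTh
}

#' Full trabecular morphometry
#'
#' BV/TV by voxel counting, Tb.Th as the local thickness of bone within
#' the ROI, Tb.Sp as the local thickness of the non-bone space within the
#' ROI, and plate-model Tb.N.
#'
#' @param bone a [BoneMask-class] (or 3D logical array).
#' @param roi a [RoiMask-class] (or 3D logical array).
#' @param voxelSize um per voxel.
#' @return a [MorphometryMetrics-class] (thicknesses in mm).
#' @export
morphometryMetrics <- function(bone, roi, voxelSize) {
  b <- asMaskArray(bone)
  r <- asMaskArray(roi)
  stopCongruent(b, r, "bone and roi")
  frac <- bvTv(b, r)
  th_mm <- if (any(b & r)) localThickness(b & r, voxelSize) * 1e-3 else 0
  sp_mm <- if (any(r & !b)) localThickness(r & !b, voxelSize) * 1e-3 else 0
  n <- if (th_mm > 0) tbN(frac, th_mm) else 0
  new("MorphometryMetrics", bvTv = frac, tbTh = th_mm, tbN = n,
      tbSp = sp_mm)
}
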