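#' Extract intracortical pores by image inversion
#'
#' Pores (osteocyte lacunae and vascular canals) are everything inside
#' the cortical ROI that is not bone. Pores touching the ROI border are
#' retained; [labelPores()] flags them so metrics can be computed with or
#' without them.
#'
#' @param bone a [BoneMask-class] (or 3D logical array).
#' @param roi a [RoiMask-class] (or 3D logical array), the cortical
#'   analysis region, congruent with `bone`.
#' @return 3D logical pore mask (`roi & !bone`).
#' @export
extractPores <- function(bone, roi) {
  b <- asMaskArray(bone)
  r <- asMaskArray(roi)
  stopCongruent(b, r, "bone and roi")
  r & !b
}

#' Label pores and classify them by physical volume
#'
#' Connected components are found under 26-connectivity (the complement
#' of face-connected bone), measured in physical volume
#' (`voxels * voxelSize^3`) and classified: below 100 um^3 is noise,
#' 100-1500 um^3 (closed interval) is an osteocyte lacuna, above
#' 1500 um^3 is a vascular canal. Thresholds compare physical volumes so
#' classification is resolution independent.
#'
#' For every non-noise pore a local-thickness diameter is computed on its
#' cropped bounding box (volume-weighted mean inscribed-sphere diameter,
#' um); noise pores get `NA`.
#'
#' @param poreMask 3D logical array from [extractPores()].
#' @param voxelSize um per voxel, `> 0`.
#' @param roi optional [RoiMask-class] (or 3D logical array); when given,
#'   pores touching the outermost ROI voxel layer (or the array edge) are
#'   flagged `border_touching`.
#' @param noiseMax,lacunaMax class boundaries in um^3 (defaults 100 and
#'   1500).
#' @return a `PoreTable` data frame with columns `label`, `voxel_count`,
#'   `volume_um3`, `pore_class`, `centroid_s`, `centroid_r`, `centroid_c`
#'   (0-based voxel coordinates), `diameter_um`, `border_touching`.
#' @examples
#' m <- array(FALSE, c(12, 12, 12))
#' m[3:6, 3:6, 3:6] <- TRUE   # 64 voxels = 512 um^3 at 2 um
#' labelPores(m, voxelSize = 2)$pore_class
#' @export
labelPores <- function(poreMask, voxelSize, roi = NULL,
                       noiseMax = 100, lacunaMax = 1500) {
  if (voxelSize <= 0) stop("voxelSize must be > 0", call. = FALSE)
  d <- dim(poreMask)
  labels <- labelComponents(poreMask, 26L)
  idx <- which(poreMask)
  if (!length(idx)) {
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), pore_class = character(0),
                      centroid_s = numeric(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), diameter_um = numeric(0),
                      border_touching = logical(0)))
  }
  lab <- labels[idx]
  nlab <- max(lab)
  counts <- tabulate(lab, nbins = nlab)
  coords <- indexToCoord(idx, d)
  cen <- rowsum(coords, lab) / counts

  vol <- counts * voxelSize^3
  cls <- ifelse(vol < noiseMax, "noise",
                ifelse(vol <= lacunaMax, "lacuna", "canal"))

  border <- rep(FALSE, nlab)
  shell <- NULL
  if (!is.null(roi)) {
    r <- asMaskArray(roi)
    stopCongruent(poreMask, r, "pore mask and roi")
    shell <- r & !array(cpp_erode6(as.logical(r), as.integer(d), 1L),
                        dim = d)
  }
  edge <- coords[, 1] == 0 | coords[, 1] == d[1] - 1 |
          coords[, 2] == 0 | coords[, 2] == d[2] - 1 |
          coords[, 3] == 0 | coords[, 3] == d[3] - 1
  on_border <- edge
  if (!is.null(shell)) on_border <- on_border | shell[idx]
  if (any(on_border))
    border[unique(lab[on_border])] <- TRUE

  diam <- rep(NA_real_, nlab)
  for (l in which(cls != "noise"))
    diam[l] <- componentThickness(labels, l, d, voxelSize)

  data.frame(label = seq_len(nlab), voxel_count = counts,
             volume_um3 = vol, pore_class = cls,
             centroid_s = cen[, 1], centroid_r = cen[, 2],
             centroid_c = cen[, 3], diameter_um = diam,
             border_touching = border)
}

# volume-weighted mean local-thickness diameter (um) of one labelled
# component, computed on its padded bounding box
componentThickness <- function(labels, l, d, voxelSize) {
  idx <- which(labels == l)
  co <- indexToCoord(idx, d) + 1  # 1-based
  lo <- pmax(apply(co, 2, min) - 1, 1)
  hi <- pmin(apply(co, 2, max) + 1, d)
  sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == l
  dim(sub) <- hi - lo + 1
  th <- cpp_local_thickness(as.logical(sub), as.integer(dim(sub)))
  mean(th[sub]) * voxelSize
}

#' Local-thickness diameter of a single canal
#'
#' Volume-weighted mean of twice the Euclidean
#' distance-transform-derived local thickness (diameter of the largest
#' inscribed sphere through each voxel), in um.
#'
#' @param canalMask 3D logical array containing one connected component.
#' @param voxelSize um per voxel.
#' @return diameter in um.
#' @export
canalDiameter <- function(canalMask, voxelSize) {
  if (!any(canalMask)) stop("empty canal mask", call. = FALSE)
  th <- cpp_local_thickness(as.logical(canalMask),
                            as.integer(dim(canalMask)))
  mean(th[canalMask]) * voxelSize
}

#' Microporosity metrics from a pore table
#'
#' Computes lacunar porosity Lc.V/TV (%), lacunar density N.Lc (1/mm^3),
#' canal porosity Ca.V/TV (%), canal density N.Ca (1/mm^3) and canal
#' diameter Ca.Dm (canal-volume-weighted mean of per-canal diameters,
#' um) over the total ROI volume TV. Noise-class pores never enter any
#' numerator. Ca.Dm is `NA` when there are no canals.
#'
#' @param pores a `PoreTable` from [labelPores()], derived from `roi`.
#' @param roi the [RoiMask-class] (or 3D logical array) the pores were
#'   extracted from.
#' @param voxelSize um per voxel.
#' @param includeBorderTouching keep pores flagged `border_touching`
#'   (default `TRUE`); set `FALSE` for the border-censored variant.
#' @return a [MicroporosityMetrics-class].
#' @export
microporosityMetrics <- function(pores, roi, voxelSize,
                                 includeBorderTouching = TRUE) {
  r <- asMaskArray(roi)
  nroi <- sum(r)
  if (nroi == 0) stop("empty ROI", call. = FALSE)
  tv_mm3 <- nroi * (voxelSize * 1e-3)^3
  if (!includeBorderTouching)
    pores <- pores[!pores$border_touching, , drop = FALSE]
  lac <- pores[pores$pore_class == "lacuna", , drop = FALSE]
  can <- pores[pores$pore_class == "canal", , drop = FALSE]
  tv_um3 <- nroi * voxelSize^3
  caDm <- if (nrow(can)) {
    stats::weighted.mean(can$diameter_um, can$volume_um3)
  } else NA_real_
  new("MicroporosityMetrics",
      lcPorosity = 100 * sum(lac$volume_um3) / tv_um3,
      lcDensity = nrow(lac) / tv_mm3,
      caPorosity = 100 * sum(can$volume_um3) / tv_um3,
      caDensity = nrow(can) / tv_mm3,
      caDiameter = caDm,
      tv = tv_mm3)
}

#' Write a pore table to CSV
#'
#' @param pores a `PoreTable` data frame from [labelPores()].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
writePoreTable <- function(pores, path) {
  utils::write.csv(pores, path, row.names = FALSE)
  invisible(path)
}
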