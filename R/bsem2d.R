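#' Create a 2D section image
#'
#' @param pixels 2D numeric matrix of grey values.
#' @param pixelSize um per pixel.
#' @return a [SectionImage-class].
#' @export
sectionImage <- function(pixels, pixelSize) {
  new("SectionImage", pixels = as.matrix(pixels),
      pixelSize = as.numeric(pixelSize))
}

#' Percent pore area of a thresholded section
#'
#' Pixels darker than `threshold` are pores; they are grouped by
#' 8-connectivity and the components partitioned by physical area into
#' lacunae (area at most `areaSplit`) and vascular pores (larger), the 2D
#' analog of the 3D volume classes. Each class is reported as a
#' percentage of the total tissue area. Components below `minArea` are
#' discarded as noise. The two pore percentages and the solid percentage
#' sum to 100 (up to discarded noise).
#'
#' @param image a [SectionImage-class].
#' @param threshold grey level; the manual colour-threshold choice is a
#'   required input.
#' @param areaSplit lacuna/vascular boundary in um^2 (default 80, the
#'   section area of a mid-range lacuna).
#' @param minArea noise floor in um^2 (default 0).
#' @param tissueMask optional logical matrix restricting the tissue area.
#' @return list with `lacunarAreaPct`, `vascularAreaPct`, `solidPct` and
#'   the labelled component matrix `labels`.
#' @export
percentPoreArea <- function(image, threshold, areaSplit = 80, minArea = 0,
                            tissueMask = NULL) {
  stopifnot(is(image, "SectionImage"))
  px <- image@pixels
  tissue <- if (is.null(tissueMask)) {
    matrix(TRUE, nrow(px), ncol(px))
  } else tissueMask
  areaTot <- sum(tissue)
  if (areaTot == 0) stop("tissue area is zero", call. = FALSE)
  pores <- px < threshold & tissue
  labels <- labelComponents(pores)
  pxArea <- image@pixelSize^2
  lacPx <- 0L; vascPx <- 0L
  if (any(pores)) {
    counts <- tabulate(labels[labels > 0])
    areas <- counts * pxArea
    keep <- areas >= minArea
    lacPx <- sum(counts[keep & areas <= areaSplit])
    vascPx <- sum(counts[keep & areas > areaSplit])
  }
  list(lacunarAreaPct = 100 * lacPx / areaTot,
       vascularAreaPct = 100 * vascPx / areaTot,
       solidPct = 100 * sum(!pores & tissue) / areaTot,
       labels = labels)
}

#' Moment-ellipse axes of a lacuna section
#'
#' Fits the ellipse with the same second central moments as the
#' component; axis lengths are `4 * sqrt(eigenvalue)` of the pixel
#' coordinate covariance, converted to um. Estimates are rotation and
#' translation invariant (within digitization).
#'
#' @param componentMask 2D logical matrix with one connected component of
#'   at least 5 pixels.
#' @param pixelSize um per pixel.
#' @return list with `majorAxis` and `minorAxis` (full lengths, um),
#'   `area` (um^2) and `eccentricity`.
#' @export
lacunaAxes <- function(componentMask, pixelSize) {
  idx <- which(componentMask, arr.ind = TRUE)
  if (nrow(idx) < 5L)
    stop("component too small for moment-ellipse fit (need >= 5 pixels)",
         call. = FALSE)
  xy <- sweep(idx, 2, colMeans(idx))
  cv <- crossprod(xy) / nrow(idx)
  ev <- eigen(cv, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]) * pixelSize
  minor <- 4 * sqrt(ev[2]) * pixelSize
  list(majorAxis = major, minorAxis = minor,
       area = nrow(idx) * pixelSize^2,
       eccentricity = if (major > 0) sqrt(1 - (minor / major)^2) else 0)
}

#' Mean cortical thickness of a 2D band
#'
#' Twice the Euclidean distance-transform value averaged along the
#' band's medial axis (ridge): pixels whose distance value is maximal in
#' their 3x3 neighborhood.
#'
#' @param cortexMask 2D logical matrix, nonempty.
#' @param pixelSize um per pixel.
#' @return mean thickness in um.
#' @export
corticalThickness2d <- function(cortexMask, pixelSize) {
  if (!any(cortexMask)) stop("empty cortex mask", call. = FALSE)
  dmap <- sqrt(edtSq(cortexMask))
  nr <- nrow(dmap); nc <- ncol(dmap)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dmap
  nbrMax <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbrMax <- pmax(nbrMax, pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc])
  }
  ridge <- cortexMask & dmap >= nbrMax & dmap > 0
  mean(2 * dmap[ridge]) * pixelSize
}

#' Sub-pixel canalicular diameter from a line profile
#'
#' The profile must cross exactly one dark band; the width of the
#' below-threshold run is measured with the two threshold crossings
#' located by linear interpolation.
#'
#' @param profile 1D numeric grey values sampled across the canaliculus.
#' @param pixelSize um per sample.
#' @param threshold grey level separating canal from matrix.
#' @return diameter in um (report in nm by multiplying by 1000).
#' @examples
#' canalicularDiameter(c(1, 1, 0, 0, 0, 1, 1), 0.05, 0.5) * 1000  # nm
#' @export
canalicularDiameter <- function(profile, pixelSize, threshold) {
  below <- profile < threshold
  if (!any(below) || below[1] || below[length(below)])
    stop("profile must cross exactly one interior dark band",
         call. = FALSE)
  runs <- rle(below)
  if (sum(runs$values) != 1L)
    stop("profile must cross exactly one interior dark band",
         call. = FALSE)
  i <- min(which(below))   # first below-threshold sample
  j <- max(which(below))   # last below-threshold sample
  xl <- (i - 1) + (profile[i - 1] - threshold) /
    (profile[i - 1] - profile[i])
  xr <- j + (threshold - profile[j]) /
    (profile[j + 1] - profile[j])
  (xr - xl) * pixelSize
}
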