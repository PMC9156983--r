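#' Rasterize a polygon onto a voxel grid
#'
#' A voxel belongs to the polygon if its center lies inside it (even-odd
#' rule). Vertices are (row, column) coordinates in voxel units, 0-based.
#'
#' @param polygon numeric matrix with columns (row, column), at least 3
#'   simple (non-self-intersecting) vertices.
#' @param nrow,ncol grid size.
#' @return logical matrix.
#' @export
rasterizePolygon <- function(polygon, nrow, ncol) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop("polygon needs at least 3 vertices", call. = FALSE)
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])  # close the loop
  pts <- cbind(rep(seq_len(nrow) - 1, times = ncol),
               rep(seq_len(ncol) - 1, each = nrow))
  inside <- mgcv::in.out(bnd, pts)
  matrix(inside, nrow, ncol)
}

#' Read keyframe contours from JSON
#'
#' Expected format: `[{"slice": int, "polygon": [[r, c], ...]}, ...]`,
#' 0-based voxel coordinates.
#'
#' @param path JSON file path.
#' @return list of keyframes, each `list(slice =, polygon =)`.
#' @export
readKeyframes <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lapply(raw, function(k) {
    list(slice = as.integer(k$slice),
         polygon = do.call(rbind, lapply(k$polygon, as.numeric)))
  })
}

#' Interpolate keyframe contours into a 3D region-of-interest mask
#'
#' Reproduces semi-automated region definition: the user outlines the
#' region on a sparse set of keyframe slices and the contour is morphed
#' across intervening slices. Interpolation blends the signed distance
#' fields of the bracketing rasterized keyframe polygons linearly in the
#' slice coordinate and thresholds at zero, a standard shape-morphing
#' construction that varies the region smoothly between keyframes. At a
#' keyframe slice the mask equals the rasterized polygon; slices outside
#' the keyframe span are empty.
#'
#' @param keyframes list of keyframes, each `list(slice = integer,
#'   polygon = matrix of (row, col))`; at least two, strictly increasing
#'   slice indices (0-based).
#' @param dim target volume dimensions (slice, row, column).
#' @param label region label for the resulting [RoiMask-class].
#' @return a [RoiMask-class].
#' @examples
#' sq <- function(lo, hi) rbind(c(lo, lo), c(lo, hi), c(hi, hi), c(hi, lo))
#' roi <- interpolateContours(
#'   list(list(slice = 0L, polygon = sq(1.5, 8.5)),
#'        list(slice = 4L, polygon = sq(1.5, 8.5))),
#'   dim = c(5L, 12L, 12L))
#' sum(maskArray(roi)[3, , ])  # 7x7 square on an intervening slice
#' @export
interpolateContours <- function(keyframes, dim,
                                label = c("trabecular",
                                          "cortical_medial_third", "full")) {
  label <- match.arg(label)
  if (length(keyframes) < 2L)
    stop("need at least two keyframes to interpolate", call. = FALSE)
  ks <- vapply(keyframes, function(k) as.integer(k$slice), integer(1))
  if (any(diff(ks) <= 0))
    stop("keyframe slice indices must be strictly increasing",
         call. = FALSE)
  if (any(ks < 0L) || any(ks >= dim[1]))
    stop("keyframe slice index out of volume bounds", call. = FALSE)

  nr <- dim[2]; nc <- dim[3]
  rasters <- lapply(keyframes, function(k)
    rasterizePolygon(k$polygon, nr, nc))
  sdfs <- lapply(keyframes, function(k)
    polygonSdf(k$polygon, nr, nc))

  out <- array(FALSE, dim = dim)
  for (i in seq_along(ks)) out[ks[i] + 1L, , ] <- rasters[[i]]
  for (i in seq_len(length(ks) - 1L)) {
    s0 <- ks[i]; s1 <- ks[i + 1L]
    for (s in seq(s0 + 1L, length.out = max(0L, s1 - s0 - 1L))) {
      t <- (s - s0) / (s1 - s0)
      blend <- (1 - t) * sdfs[[i]] + t * sdfs[[i + 1L]]
      out[s + 1L, , ] <- blend < 0
    }
  }
  new("RoiMask", mask = out, label = label)
}

# signed distance field of a polygon sampled at voxel centers: exact
# point-to-edge distance, negative inside (even-odd rule), so blended
# zero level sets carry sub-voxel boundary positions
polygonSdf <- function(polygon, nr, nc) {
  polygon <- as.matrix(polygon)
  nv <- nrow(polygon)
  pr <- rep(seq_len(nr) - 1, times = nc)
  pc <- rep(seq_len(nc) - 1, each = nr)
  dmin <- rep(Inf, nr * nc)
  for (i in seq_len(nv)) {
    a <- polygon[i, ]
    b <- polygon[if (i == nv) 1L else i + 1L, ]
    er <- b[1] - a[1]; ec <- b[2] - a[2]
    len2 <- er^2 + ec^2
    t <- if (len2 == 0) 0 else
      pmin(pmax(((pr - a[1]) * er + (pc - a[2]) * ec) / len2, 0), 1)
    dmin <- pmin(dmin, sqrt((pr - (a[1] + t * er))^2 +
                            (pc - (a[2] + t * ec))^2))
  }
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(pr, pc))
  matrix(ifelse(inside, -dmin, dmin), nr, nc)
}

#' Restrict a cortical mask to the middle third of the band
#'
#' Each slice's cortical band is parameterized by geodesic arc length
#' between two anchor points (the growth-plate reference points): every
#' cortex voxel gets `t = d1 / (d1 + d2)` where `d1`, `d2` are
#' within-band geodesic distances from the anchors' nearest band voxels,
#' and voxels with `1/3 <= t < 2/3` are retained.
#'
#' @param cortexMask a [RoiMask-class] (or 3D logical array) marking the
#'   full cortical band.
#' @param anchors either a single 2x2 matrix (rows = the two anchor
#'   points, columns = (row, col), 0-based) applied to every slice, or a
#'   list of such matrices, one per slice.
#' @return a [RoiMask-class] labelled `cortical_medial_third`.
#' @export
middleThirdMask <- function(cortexMask, anchors) {
  m <- asMaskArray(cortexMask)
  d <- dim(m)
  if (is.matrix(anchors)) anchors <- rep(list(anchors), d[1])
  if (length(anchors) != d[1])
    stop("need one anchor pair per slice (or a single pair)", call. = FALSE)
  out <- array(FALSE, dim = d)
  for (s in seq_len(d[1])) {
    sl <- m[s, , ]
    if (!any(sl)) next
    a <- as.matrix(anchors[[s]])
    if (nrow(a) != 2L || ncol(a) != 2L)
      stop("each anchor set must be a 2x2 (row, col) matrix", call. = FALSE)
    if (all(a[1, ] == a[2, ]))
      stop("anchors must not coincide", call. = FALSE)
    if (any(a[, 1] < 0) || any(a[, 1] >= d[2]) ||
        any(a[, 2] < 0) || any(a[, 2] >= d[3]))
      stop("anchor out of slice bounds", call. = FALSE)
    seeds <- apply(a, 1, function(p) nearestMaskPixel(sl, p))
    if (all(seeds[, 1] == seeds[, 2]))
      stop("anchors resolve to the same band voxel", call. = FALSE)
    d1 <- cpp_geodesic_2d(sl, seeds[1, 1] - 1L, seeds[2, 1] - 1L)
    d2 <- cpp_geodesic_2d(sl, seeds[1, 2] - 1L, seeds[2, 2] - 1L)
    t <- d1 / (d1 + d2)
    keep <- !is.na(t) & t >= 1 / 3 & t < 2 / 3
    out[s, , ] <- keep
  }
  new("RoiMask", mask = out, label = "cortical_medial_third")
}

# nearest TRUE pixel (1-based (row, col)) to a 0-based point
nearestMaskPixel <- function(mask, point) {
  idx <- which(mask, arr.ind = TRUE)
  dd <- (idx[, 1] - 1 - point[1])^2 + (idx[, 2] - 1 - point[2])^2
  idx[which.min(dd), ]
}
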