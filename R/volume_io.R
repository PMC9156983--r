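#' Create a grey-to-density calibration
#'
#' @param slope (mg HA/ccm) per grey level, non-zero.
#' @param intercept mg HA/ccm.
#' @return a [CalibrationMap-class].
#' @examples
#' calibrationMap(slope = 0.25, intercept = -100)
#' @export
calibrationMap <- function(slope = 1, intercept = 0) {
  new("CalibrationMap", slope = as.numeric(slope),
      intercept = as.numeric(intercept))
}

#' Read a YAML calibration sidecar
#'
#' The sidecar carries the scanner calibration that accompanies TIFF
#' stacks: keys `voxel_size_um`, `slope` and `intercept`.
#'
#' @param path path to the YAML file.
#' @return list with elements `calibration` (a [CalibrationMap-class])
#'   and `voxelSize` (um).
#' @export
readCalibrationSidecar <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("voxel_size_um", "slope", "intercept")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("calibration sidecar is missing keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  list(calibration = calibrationMap(y$slope, y$intercept),
       voxelSize = as.numeric(y$voxel_size_um))
}

#' Read an ordered image stack into a calibrated volume
#'
#' Reads a series of DICOM files (one slice per file) or one or more
#' (multi-page) TIFF files, applies the linear grey-to-density
#' calibration and returns a [CalibratedVolume-class]. Paths must be
#' ordered by slice position. For DICOM input, per-file rescale
#' slope/intercept tags are used when present and take precedence over
#' `calibration`.
#'
#' @param paths character vector of image files, ordered distal to
#'   proximal.
#' @param calibration a [CalibrationMap-class]; required for TIFF input
#'   and for DICOMs without rescale tags.
#' @param voxelSize isotropic voxel size, um.
#' @return a [CalibratedVolume-class] with density =
#'   `grey * slope + intercept`.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' vol <- new("CalibratedVolume",
#'            data = array(800, dim = c(3, 4, 4)), voxelSize = 2)
#' writeStack(vol, tf, calibrationMap(1, 0))
#' v2 <- readStack(tf, calibrationMap(1, 0), voxelSize = 2)
#' stopifnot(all(densities(v2) == 800))
#' @export
readStack <- function(paths, calibration = NULL, voxelSize) {
  if (length(paths) == 0L)
    stop("no input slices given", call. = FALSE)
  ext <- tolower(tools::file_ext(paths[1]))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(calibration))
      stop("TIFF input requires a calibration (see calibrationMap)",
           call. = FALSE)
    slices <- list()
    for (p in paths) {
      pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      slices <- c(slices, pages)
    }
    slices <- lapply(slices, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # collapse grey-written RGB
      m
    })
    greyToVolume(slices, calibration@slope, calibration@intercept,
                 voxelSize, paths)
  } else {
    slices <- lapply(paths, readDicomSlice)
    slope <- vapply(slices, function(s)
      if (is.null(s$slope)) NA_real_ else s$slope, numeric(1))
    intercept <- vapply(slices, function(s)
      if (is.null(s$intercept)) NA_real_ else s$intercept, numeric(1))
    if (anyNA(slope) || anyNA(intercept)) {
      if (is.null(calibration))
        stop("DICOM slices lack rescale tags and no calibration was given",
             call. = FALSE)
      slope[is.na(slope)] <- calibration@slope
      intercept[is.na(intercept)] <- calibration@intercept
    }
    mats <- lapply(seq_along(slices), function(i)
      slices[[i]]$pixels * slope[i] + intercept[i])
    greyToVolume(mats, 1, 0, voxelSize, paths)
  }
}

greyToVolume <- function(slices, slope, intercept, voxelSize, paths) {
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch: slices differ in row/column size",
         call. = FALSE)
  ns <- length(slices)
  arr <- array(0, dim = c(ns, dims[1, 1], dims[2, 1]))
  for (s in seq_len(ns))
    arr[s, , ] <- slices[[s]] * slope + intercept
  new("CalibratedVolume", data = arr, voxelSize = as.numeric(voxelSize),
      provenance = list(source = paths, slope = slope,
                        intercept = intercept))
}

#' Write a calibrated volume as a 16-bit multi-page TIFF
#'
#' Densities are mapped back to grey levels with the inverse calibration,
#' rounded and clipped to 0..65535, so that [readStack()] with the same
#' calibration round-trips densities to within calibration quantization
#' (half a grey step).
#'
#' @param volume a [CalibratedVolume-class].
#' @param path output TIFF path.
#' @param calibration a [CalibrationMap-class].
#' @return invisibly, `path`.
#' @export
writeStack <- function(volume, path, calibration) {
  stopifnot(is(volume, "CalibratedVolume"), is(calibration, "CalibrationMap"))
  grey <- round((volume@data - calibration@intercept) / calibration@slope)
  grey <- pmin(pmax(grey, 0), 65535)
  pages <- lapply(seq_len(dim(grey)[1]),
                  function(s) grey[s, , ] / 65535)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to ", path, call. = FALSE)
  invisible(path)
}

#' Write and read boolean masks as 0/255 multi-page TIFF
#'
#' @param mask a [VoxelMask-class] or 3D logical array.
#' @param path TIFF path.
#' @return `writeMask` invisibly returns `path`; `readMask` returns a 3D
#'   logical array.
#' @export
writeMask <- function(mask, path) {
  m <- asMaskArray(mask)
  pages <- lapply(seq_len(dim(m)[1]), function(s) m[s, , ] * 1.0)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(FALSE, dim = c(length(pages), d[1], d[2]))
  for (s in seq_along(pages)) arr[s, , ] <- pages[[s]] > 0.5
  arr
}

## ---- minimal DICOM support (single-frame, explicit VR little endian) ----

# Reads the tags needed to reconstruct a calibrated slice: Rows, Columns,
# BitsAllocated, PixelRepresentation, RescaleIntercept/Slope, PixelData.
readDicomSlice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L); hdr <- 8L
    } else {
      stop("unsupported DICOM encoding (implicit VR?) in ", path,
           call. = FALSE)
    }
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, body = body)
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags)))
    stop("DICOM file lacks image tags: ", path, call. = FALSE)
  us <- function(key) readBin(tags[[key]]$body, "integer", size = 2,
                              endian = "little", signed = FALSE)
  ds <- function(key) if (key %in% names(tags))
    as.numeric(trimws(rawToChar(tags[[key]]$body))) else NULL
  nr <- us("0028,0010"); nc <- us("0028,0011")
  bits <- if ("0028,0100" %in% names(tags)) us("0028,0100") else 16L
  signed <- "0028,0103" %in% names(tags) && us("0028,0103") == 1L
  if (bits != 16L)
    stop("only 16-bit DICOM pixel data is supported", call. = FALSE)
  px <- readBin(tags[["7fe0,0010"]]$body, "integer", n = nr * nc,
                size = 2, endian = "little", signed = signed)
  if (!signed) px[px < 0] <- px[px < 0] + 65536
  # DICOM pixel data is row-major (top row first)
  pixels <- matrix(px, nrow = nr, ncol = nc, byrow = TRUE)
  list(pixels = pixels, slope = ds("0028,1053"),
       intercept = ds("0028,1052"))
}

# Test/fixture writer: single-frame explicit-VR little-endian DICOM.
writeDicomSlice <- function(pixels, path, slope = NULL, intercept = NULL) {
  pixels <- round(pixels)
  stopifnot(all(pixels >= 0), all(pixels < 65536))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  elem_short <- function(group, el, vr, body) {
    w16(group); w16(el)
    writeChar(vr, con, eos = NULL)
    if (length(body) %% 2 == 1) body <- c(body, as.raw(0x20))
    w16(length(body))
    if (length(body)) writeBin(body, con)
  }
  us_body <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
  ds_body <- function(x) charToRaw(format(x, digits = 15))
  elem_short(0x0028, 0x0010, "US", us_body(nrow(pixels)))
  elem_short(0x0028, 0x0011, "US", us_body(ncol(pixels)))
  elem_short(0x0028, 0x0100, "US", us_body(16L))
  elem_short(0x0028, 0x0103, "US", us_body(0L))
  if (!is.null(intercept))
    elem_short(0x0028, 0x1052, "DS", ds_body(intercept))
  if (!is.null(slope))
    elem_short(0x0028, 0x1053, "DS", ds_body(slope))
  # PixelData, OW with 32-bit length, row-major
  w16(0x7fe0); w16(0x0010)
  writeChar("OW", con, eos = NULL)
  w16(0L)
  writeBin(as.integer(2L * length(pixels)), con, size = 4,
           endian = "little")
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

## ---- metrics serialization ----

#' @describeIn writeMetrics microporosity metrics: columns `lc_v_tv_pct`,
#'   `n_lc_per_mm3`, `ca_v_tv_pct`, `n_ca_per_mm3`, `ca_dm_um`, `tv_mm3`.
#' @export
setMethod("writeMetrics", "MicroporosityMetrics", function(x, path, id = NULL)
  writeMetricsDf(as(x, "data.frame"), path, id))

#' @describeIn writeMetrics morphometry metrics: columns `bv_tv`,
#'   `tb_th_mm`, `tb_n_per_mm`, `tb_sp_mm`.
#' @export
setMethod("writeMetrics", "MorphometryMetrics", function(x, path, id = NULL)
  writeMetricsDf(as(x, "data.frame"), path, id))

#' @describeIn writeMetrics BMDD summary: columns `mean_density_mghaccm`,
#'   `fwhm_mghaccm`, `n_voxels`.
#' @export
setMethod("writeMetrics", "BmddResult", function(x, path, id = NULL)
  writeMetricsDf(as(x, "data.frame"), path, id))

#' @describeIn writeMetrics a list of records of one metrics class, one
#'   row each.
#' @export
setMethod("writeMetrics", "list", function(x, path, id = NULL) {
  if (!length(x)) stop("empty record list", call. = FALSE)
  cls <- vapply(x, class, character(1))
  ok <- c("MicroporosityMetrics", "MorphometryMetrics", "BmddResult")
  if (length(unique(cls)) != 1L || !cls[1] %in% ok)
    stop("records must all be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  df <- do.call(rbind, lapply(x, as, "data.frame"))
  writeMetricsDf(df, path, id)
})

setAs("MicroporosityMetrics", "data.frame", function(from)
  data.frame(lc_v_tv_pct = from@lcPorosity, n_lc_per_mm3 = from@lcDensity,
             ca_v_tv_pct = from@caPorosity, n_ca_per_mm3 = from@caDensity,
             ca_dm_um = from@caDiameter, tv_mm3 = from@tv))

setAs("MorphometryMetrics", "data.frame", function(from)
  data.frame(bv_tv = from@bvTv, tb_th_mm = from@tbTh,
             tb_n_per_mm = from@tbN, tb_sp_mm = from@tbSp))

setAs("BmddResult", "data.frame", function(from)
  data.frame(mean_density_mghaccm = from@meanDensity,
             fwhm_mghaccm = from@fwhm, n_voxels = from@nVoxels))

writeMetricsDf <- function(df, path, id = NULL) {
  if (!is.null(id)) df <- cbind(id = id, df)
  ok <- try(utils::write.csv(df, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write metrics to ", path, call. = FALSE)
  invisible(df)
}

#' Read a metrics CSV written by [writeMetrics()]
#'
#' @param path CSV path.
#' @return a data frame, one row per record.
#' @export
readMetrics <- function(path) utils::read.csv(path)
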