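test_that("TIFF stack round-trips through calibration", {
  cal <- calibrationMap(1, 0)
  vol <- constantVolume(100, dim = c(3, 4, 4))
  tf <- withr::local_tempfile(fileext = ".tif")
  writeStack(vol, tf, cal)
  back <- readStack(tf, cal, voxelSize = 2)
  expect_equal(dim(back), c(3L, 4L, 4L))
  expect_true(all(densities(back) == 100))

  # affine calibration: grey 50, slope 2, intercept -10 -> 90
  grey <- constantVolume(50, dim = c(2, 3, 3))
  tf2 <- withr::local_tempfile(fileext = ".tif")
  writeStack(grey, tf2, calibrationMap(1, 0))
  v2 <- readStack(tf2, calibrationMap(2, -10), voxelSize = 2)
  expect_true(all(densities(v2) == 90))

  # quantization-bounded round trip with a non-unit slope
  set.seed(1)
  dens <- array(runif(4 * 5 * 5, 600, 1400), dim = c(4, 5, 5))
  cal3 <- calibrationMap(0.25, 200)
  tf3 <- withr::local_tempfile(fileext = ".tif")
  writeStack(makeVolume(dens), tf3, cal3)
  v3 <- readStack(tf3, cal3, voxelSize = 2)
  expect_lt(max(abs(densities(v3) - dens)), 0.25 / 2 + 1e-9)
})

test_that("stack reading enforces its contracts", {
  expect_error(readStack(character(0)), "no input")
  cal <- calibrationMap(1, 0)
  t1 <- withr::local_tempfile(fileext = ".tif")
  t2 <- withr::local_tempfile(fileext = ".tif")
  writeStack(constantVolume(100, dim = c(1, 4, 4)), t1, cal)
  writeStack(constantVolume(100, dim = c(1, 5, 5)), t2, cal)
  expect_error(readStack(c(t1, t2), cal, voxelSize = 2),
               "dimension mismatch")
})

test_that("DICOM slices round-trip with embedded rescale tags", {
  px <- matrix(sample.int(4096, 20 * 16, replace = TRUE), 20, 16)
  d1 <- withr::local_tempfile(fileext = ".dcm")
  d2 <- withr::local_tempfile(fileext = ".dcm")
  PoroCT:::writeDicomSlice(px, d1, slope = 0.5, intercept = -100)
  PoroCT:::writeDicomSlice(px + 1, d2, slope = 0.5, intercept = -100)
  vol <- readStack(c(d1, d2), voxelSize = 2)
  expect_equal(dim(vol), c(2L, 20L, 16L))
  expect_equal(vol@data[1, , ], px * 0.5 - 100)
  expect_equal(vol@data[2, , ], (px + 1) * 0.5 - 100)

  # without tags, the explicit calibration takes over
  d3 <- withr::local_tempfile(fileext = ".dcm")
  PoroCT:::writeDicomSlice(px, d3)
  expect_error(readStack(d3, voxelSize = 2), "rescale")
  v3 <- readStack(d3, calibrationMap(2, 10), voxelSize = 2)
  expect_equal(v3@data[1, , ], px * 2 + 10)
})

test_that("YAML calibration sidecar is read", {
  sf <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("voxel_size_um: 2", "slope: 0.25", "intercept: -50"), sf)
  sc <- readCalibrationSidecar(sf)
  expect_equal(sc$voxelSize, 2)
  expect_equal(sc$calibration@slope, 0.25)
  expect_equal(sc$calibration@intercept, -50)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("slope: 1", bad)
  expect_error(readCalibrationSidecar(bad), "missing keys")
})

test_that("metrics records serialize losslessly and reject bad input", {
  m <- new("MicroporosityMetrics", lcPorosity = 0.0123456789,
           lcDensity = 1234.56789, caPorosity = 1.5, caDensity = 12.5,
           caDiameter = 28.123456789, tv = 0.128)
  cf <- withr::local_tempfile(fileext = ".csv")
  writeMetrics(m, cf, id = "rat1")
  back <- readMetrics(cf)
  expect_equal(names(back),
               c("id", "lc_v_tv_pct", "n_lc_per_mm3", "ca_v_tv_pct",
                 "n_ca_per_mm3", "ca_dm_um", "tv_mm3"))
  expect_equal(back$lc_v_tv_pct, m@lcPorosity, tolerance = 1e-9)
  expect_equal(back$ca_dm_um, m@caDiameter, tolerance = 1e-9)

  mm <- new("MorphometryMetrics", bvTv = 1 / 3, tbTh = 0.0123456789,
            tbN = 5.5, tbSp = 0.1)
  writeMetrics(list(mm, mm), cf)
  b2 <- readMetrics(cf)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$tb_th_mm, rep(mm@tbTh, 2), tolerance = 1e-9)

  expect_error(writeMetrics(list(list(bad = 1)), cf), "must all be one of")
  expect_error(writeMetrics(list(), cf), "empty")
})

test_that("mask TIFF export round-trips", {
  m <- cubeMask(c(4, 6, 6), c(1, 1, 1), c(3, 5, 5))
  tf <- withr::local_tempfile(fileext = ".tif")
  writeMask(m, tf)
  expect_identical(readMask(tf), m)
})
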