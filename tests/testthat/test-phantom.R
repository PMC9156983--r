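test_that("a solid control phantom yields zero porosity", {
  ph <- generateCorticalPhantom(phantomSpec(
    dim = c(40L, 40L, 40L), nLacunae = 0L, nCanals = 0L,
    corticalThickness = 60, psfSigma = 0, noiseSd = 0, seed = 2L))
  bone <- thresholdBone(ph$volume, ph$roi, 780)
  pt <- labelPores(extractPores(bone, ph$roi), 2, roi = ph$roi)
  met <- microporosityMetrics(pt, ph$roi, 2)
  expect_equal(met@lcPorosity, 0)
  expect_equal(met@caPorosity, 0)
  expect_equal(ph$truth$lcPorosityPct, 0)
})

test_that("lacunar population recovers from a digitization-only phantom", {
  ph <- generateCorticalPhantom(phantomSpec(
    dim = c(160L, 160L, 160L), nLacunae = 25L,
    lacunaVolumeRange = c(150, 600), nCanals = 1L,
    corticalThickness = 200, psfSigma = 0, noiseSd = 0, seed = 31L))
  bone <- thresholdBone(ph$volume, ph$roi, 780)
  pt <- labelPores(extractPores(bone, ph$roi), 2, roi = ph$roi)
  met <- microporosityMetrics(pt, ph$roi, 2)
  expect_equal(sum(pt$pore_class == "lacuna"), 25)
  expect_lt(abs(met@lcPorosity - ph$truth$lcPorosityPct) /
              ph$truth$lcPorosityPct, 0.15)
  expect_lt(abs(met@caPorosity - ph$truth$caPorosityPct) /
              ph$truth$caPorosityPct, 0.15)
  expect_lt(abs(met@caDiameter - ph$truth$caDiameterUm), 4)
})

test_that("phantom generation is seed-deterministic", {
  spec <- phantomSpec(dim = c(50L, 50L, 50L), nLacunae = 5L,
                      nCanals = 1L, corticalThickness = 80, seed = 9L)
  a <- generateCorticalPhantom(spec)
  b <- generateCorticalPhantom(spec)
  expect_identical(densities(a$volume), densities(b$volume))
  expect_identical(a$truth, b$truth)
  c <- generateCorticalPhantom(phantomSpec(dim = c(50L, 50L, 50L),
                                           nLacunae = 5L, nCanals = 1L,
                                           corticalThickness = 80,
                                           seed = 10L))
  expect_false(identical(densities(a$volume), densities(c$volume)))
})

test_that("truth ledger is internally consistent", {
  ph <- generateCorticalPhantom(phantomSpec(
    dim = c(80L, 80L, 80L), nLacunae = 12L, nCanals = 2L,
    corticalThickness = 120, psfSigma = 0, noiseSd = 0, seed = 5L))
  tr <- ph$truth
  tv_um3 <- tr$tvMm3 * 1e9
  expect_equal(tr$lcPorosityPct,
               100 * sum(tr$lacunae$volume_um3) / tv_um3,
               tolerance = 1e-12)
  expect_equal(tr$caPorosityPct,
               100 * sum(tr$canals$volume_um3) / tv_um3,
               tolerance = 1e-12)
  # ellipsoid volumes match 4/3 pi a b^2
  expect_equal(tr$lacunae$volume_um3,
               4 / 3 * pi * tr$lacunae$semi_a_um * tr$lacunae$semi_b_um^2,
               tolerance = 1e-12)
  expect_equal(sum(maskArray(ph$roi)) * 8e-9, tr$tvMm3, tolerance = 1e-12)
})

test_that("trabecular plate phantom has exact analytic truth", {
  ph <- generateTrabecularPhantom(
    phantomSpec(dim = c(90L, 48L, 48L), psfSigma = 0, noiseSd = 0,
                seed = 3L),
    geometry = "plates", plateThickness = 60, gap = 120)
  bone <- thresholdBone(ph$volume, ph$roi, 780)
  expect_equal(bvTv(bone, ph$roi), ph$truth$bvTv)  # t / (t + g) exact
  expect_equal(ph$truth$bvTv, 60 / 180)
  expect_lt(abs(localThickness(maskArray(bone), 2) - ph$truth$tbThUm),
            2 + 1e-9)
})

test_that("rod lattice phantom matches its analytic bone fraction", {
  spec <- phantomSpec(dim = c(80L, 80L, 80L), rodRadius = 16,
                      rodPitch = 160, psfSigma = 0, noiseSd = 0,
                      seed = 4L)
  ph <- generateTrabecularPhantom(spec, geometry = "rods")
  bone <- thresholdBone(ph$volume, ph$roi, 780)
  measured <- bvTv(bone, ph$roi)
  expect_lt(abs(measured - ph$truth$bvTv) / ph$truth$bvTv, 0.10)
  expect_error(
    generateTrabecularPhantom(phantomSpec(rodRadius = 90, rodPitch = 160),
                              geometry = "rods"),
    "pitch")
})

test_that("rendered sections carry the analytic ellipse intersection", {
  # one lacuna, no blur: slice through its center shows the cross-section
  ph <- generateCorticalPhantom(phantomSpec(
    dim = c(60L, 60L, 60L), nLacunae = 1L,
    lacunaVolumeRange = c(500, 600), nCanals = 0L,
    corticalThickness = 100, psfSigma = 0, noiseSd = 0, seed = 21L))
  lac <- ph$truth$lacunae
  sl <- round(lac$slice)
  img <- renderSection(ph$volume, sl)
  expect_equal(voxelSize(img), 2)
  expect_gte(min(img@pixels), 0)
  expect_equal(max(img@pixels), 255)  # mapping spans the grey range

  dark <- img@pixels < 100
  expect_gt(sum(dark), 0)
  # constant slice renders flat
  solid <- generateCorticalPhantom(phantomSpec(
    dim = c(20L, 20L, 20L), nLacunae = 0L, nCanals = 0L,
    corticalThickness = 200, densitySd = 0, psfSigma = 0, noiseSd = 0,
    seed = 1L))
  flat <- renderSection(solid$volume, 5)
  expect_equal(diff(range(flat@pixels)), 0)
  expect_error(renderSection(ph$volume, 999), "out of range")
})
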