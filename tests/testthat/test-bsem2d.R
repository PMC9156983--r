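test_that("percent pore area is exact for constructed sections", {
  blank <- sectionImage(matrix(200, 100, 100), 1)
  res <- percentPoreArea(blank, threshold = 100)
  expect_equal(res$lacunarAreaPct + res$vascularAreaPct, 0)
  expect_equal(res$solidPct, 100)

  # one dark disk of known pixel area
  px <- matrix(200, 200, 200)
  disk <- renderEllipse(200, 200, c(99.5, 99.5), c(10, 10))
  px[disk] <- 20
  img <- sectionImage(px, 1)
  res2 <- percentPoreArea(img, threshold = 100, areaSplit = 1e6)
  expect_equal(res2$lacunarAreaPct, 100 * sum(disk) / length(disk))
  expect_equal(res2$lacunarAreaPct + res2$vascularAreaPct + res2$solidPct,
               100, tolerance = 1e-9)
  expect_error(percentPoreArea(img, 100,
                               tissueMask = matrix(FALSE, 200, 200)),
               "tissue area")
})

test_that("rendered lacunar sections recover the drawn percent area", {
  # many small elliptical lacunae totalling ~1.5% of the tissue area
  set.seed(3)
  px <- matrix(200, 400, 400)
  drawn <- matrix(FALSE, 400, 400)
  for (i in 1:12) {
    ctr <- runif(2, 40, 360)
    e <- renderEllipse(400, 400, ctr, c(9, 3.2),
                       thetaRad = runif(1, 0, pi))
    drawn <- drawn | e
  }
  px[drawn] <- 30
  truthPct <- 100 * sum(drawn) / length(drawn)
  res <- percentPoreArea(sectionImage(px, 0.5), threshold = 100)
  expect_lt(abs(res$lacunarAreaPct + res$vascularAreaPct - truthPct), 0.2)
})

test_that("moment-ellipse axes recover drawn lacunae at BSEM scale", {
  # semi-axes 4.75 and 1.65 um at 0.1 um/px
  e <- renderEllipse(160, 160, c(79.5, 79.5), c(47.5, 16.5),
                     thetaRad = 0.4)
  ax <- lacunaAxes(e, pixelSize = 0.1)
  expect_lt(abs(ax$majorAxis - 9.5), 0.3)
  expect_lt(abs(ax$minorAxis - 3.3), 0.3)
  expect_gt(ax$eccentricity, 0.9)

  circ <- renderEllipse(80, 80, c(39.5, 39.5), c(20, 20))
  cx <- lacunaAxes(circ, pixelSize = 0.1)
  expect_lt(abs(cx$majorAxis - 4), 0.1)   # 2r with r = 2 um
  expect_lt(abs(cx$majorAxis - cx$minorAxis), 0.1)

  expect_error(lacunaAxes(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), 0.1),
               "too small")
})

test_that("ellipse axes are rotation and translation invariant", {
  base <- lacunaAxes(renderEllipse(200, 200, c(99.5, 99.5),
                                   c(47.5, 16.5)), 0.1)
  for (th in c(pi / 6, pi / 3, 1.1)) {
    rot <- lacunaAxes(renderEllipse(200, 200, c(89.5, 109.5),
                                    c(47.5, 16.5), thetaRad = th), 0.1)
    expect_lt(abs(rot$majorAxis - base$majorAxis) / base$majorAxis, 0.02)
    expect_lt(abs(rot$minorAxis - base$minorAxis) / base$minorAxis, 0.02)
  }
})

test_that("2D cortical thickness matches analytic bands and annuli", {
  band <- matrix(FALSE, 120, 80)
  band[31:80, ] <- TRUE  # 50 px thick at 2 um/px
  expect_lt(abs(corticalThickness2d(band, 2) - 100), 2 + 1e-9)

  n <- 161
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  rad <- sqrt((g$r - 80)^2 + (g$c - 80)^2)
  annulus <- matrix(rad >= 40 & rad <= 70, n, n)
  expect_lt(abs(corticalThickness2d(annulus, 2) - 60), 2 + 1e-9)
  expect_error(corticalThickness2d(matrix(FALSE, 4, 4), 2), "empty")
})

test_that("canalicular diameter is sub-pixel exact on line profiles", {
  # box dip 3 px wide at 0.05 um/px: 150 nm
  expect_equal(canalicularDiameter(c(1, 1, 0, 0, 0, 1, 1), 0.05, 0.5),
               0.15)
  # Gaussian dip measured at half depth equals its FWHM
  x <- seq(-30, 30)
  prof <- 1 - exp(-x^2 / (2 * 6^2))
  w <- canalicularDiameter(prof, 0.05, 0.5)
  expect_lt(abs(w - 2 * sqrt(2 * log(2)) * 6 * 0.05) / w, 0.05)
  expect_error(canalicularDiameter(seq(1, 0, length.out = 10), 0.05, 0.5),
               "dark band")
  expect_error(canalicularDiameter(c(1, 1, 1), 0.05, 0.5), "dark band")
})
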