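test_that("identical keyframes interpolate to a constant region", {
  kf <- list(list(slice = 0L, polygon = squarePolygon(1.5, 8.5)),
             list(slice = 4L, polygon = squarePolygon(1.5, 8.5)))
  roi <- interpolateContours(kf, dim = c(5L, 12L, 12L))
  ref <- maskArray(roi)[1, , ]
  expect_equal(sum(ref), 49)  # voxel centers 2..8
  for (s in 2:5) expect_identical(maskArray(roi)[s, , ], ref)
})

test_that("interpolated region size passes midway between keyframes", {
  kf <- list(list(slice = 0L, polygon = squarePolygon(9.7, 19.7)),
             list(slice = 10L, polygon = squarePolygon(4.7, 24.7)))
  roi <- interpolateContours(kf, dim = c(11L, 40L, 40L))
  expect_equal(sum(maskArray(roi)[1, , ]), 100)    # side 10
  expect_equal(sum(maskArray(roi)[11, , ]), 400)   # side 20
  mid <- sum(maskArray(roi)[6, , ])
  expect_lt(abs(mid - 225), 0.1 * 225)             # side ~15

  # monotone growth for nested convex keyframes
  areas <- vapply(1:11, function(s) sum(maskArray(roi)[s, , ]),
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("slices outside the keyframe span stay empty", {
  kf <- list(list(slice = 3L, polygon = squarePolygon(2.5, 10.5)),
             list(slice = 7L, polygon = squarePolygon(2.5, 10.5)))
  roi <- interpolateContours(kf, dim = c(20L, 16L, 16L))
  m <- maskArray(roi)
  for (s in c(1:3, 9:20)) expect_equal(sum(m[s, , ]), 0)
  for (s in 4:8) expect_gt(sum(m[s, , ]), 0)
})

test_that("contour interpolation enforces its contracts", {
  kf1 <- list(list(slice = 0L, polygon = squarePolygon(1.5, 5.5)))
  expect_error(interpolateContours(kf1, dim = c(5L, 8L, 8L)),
               "at least two")
  kf2 <- c(kf1, list(list(slice = 9L, polygon = squarePolygon(1.5, 5.5))))
  expect_error(interpolateContours(kf2, dim = c(5L, 8L, 8L)), "bounds")
  expect_error(rasterizePolygon(rbind(c(0, 0), c(1, 1)), 4, 4),
               "at least 3")
})

test_that("keyframes load from JSON", {
  jf <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('[{"slice": 0, "polygon": [[1.5,1.5],[1.5,8.5],',
                    '[8.5,8.5],[8.5,1.5]]},',
                    '{"slice": 4, "polygon": [[2,2],[2,7],[7,7],[7,2]]}]'),
             jf)
  kf <- readKeyframes(jf)
  expect_length(kf, 2)
  expect_equal(kf[[2]]$slice, 4L)
  expect_equal(dim(kf[[1]]$polygon), c(4L, 2L))
  roi <- interpolateContours(kf, dim = c(5L, 12L, 12L))
  expect_gt(sum(maskArray(roi)), 0)
})

test_that("middle third of a straight strip keeps the central columns", {
  strip <- array(FALSE, c(1, 30, 90))
  strip[1, 12:14, ] <- TRUE
  mt <- middleThirdMask(strip, rbind(c(12, 0), c(12, 89)))
  kept <- maskArray(mt)[1, , ]
  cols <- which(apply(kept, 2, any)) - 1
  expect_equal(range(cols), c(30, 59))
  # retained fraction close to one third
  expect_lt(abs(sum(kept) / sum(strip) - 1 / 3), 0.05)
})

test_that("middle third of a semicircular annulus spans ~60 of 180 deg", {
  n <- 101
  ctr <- 50
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  rad <- sqrt((g$r - ctr)^2 + (g$c - ctr)^2)
  ang <- atan2(ctr - g$r, g$c - ctr)  # 0 at +col axis, pi at -col
  band <- rad >= 20 & rad <= 30 & ang >= 0 & ang <= pi
  ann <- array(FALSE, c(1, n, n))
  ann[1, , ] <- matrix(band, n, n)
  mt <- middleThirdMask(ann, rbind(c(50, 75), c(50, 25)))
  frac <- sum(maskArray(mt)) / sum(ann)
  expect_lt(abs(frac - 1 / 3), 0.05)
  # retained pixels cluster around the top of the arc (90 deg)
  kept <- which(maskArray(mt)[1, , ], arr.ind = TRUE)
  angs <- atan2(ctr - (kept[, 1] - 1), (kept[, 2] - 1) - ctr) * 180 / pi
  expect_gt(min(angs), 45)
  expect_lt(max(angs), 135)
})

test_that("middle third rejects degenerate anchors", {
  strip <- array(FALSE, c(1, 10, 30))
  strip[1, 4:6, ] <- TRUE
  expect_error(middleThirdMask(strip, rbind(c(5, 3), c(5, 3))),
               "coincide")
  expect_error(middleThirdMask(strip, rbind(c(5, 0), c(99, 0))),
               "bounds")
})
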