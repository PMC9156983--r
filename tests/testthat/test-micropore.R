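test_that("pore extraction is the ROI-restricted complement of bone", {
  d <- c(12, 12, 12)
  roi <- cubeMask(d, c(1, 1, 1), c(11, 11, 11))
  solid <- roi
  expect_equal(sum(extractPores(solid, roi)), 0)

  bone <- solid
  bone[4:8, 4:8, 4:8] <- FALSE  # 5x5x5 cavity
  expect_equal(sum(extractPores(bone, roi)), 125)

  none <- array(FALSE, d)
  expect_identical(extractPores(none, roi), roi)
  expect_error(extractPores(array(FALSE, c(6, 6, 6)), roi),
               "dimension mismatch")
})

test_that("pores are classified by physical volume at 100 and 1500 um^3", {
  d <- c(24, 24, 24)
  m <- array(FALSE, d)
  m[2, 2, 2] <- TRUE               # 8 um^3 at 2 um
  m[2, 2, 8] <- TRUE               # second isolated voxel
  m[6:9, 6:9, 6:9] <- TRUE         # 4^3 = 512 um^3
  m[14:20, 14:20, 14:20] <- TRUE   # 7^3 = 2744 um^3
  pt <- labelPores(m, voxelSize = 2)
  expect_equal(nrow(pt), 4)
  counts <- table(factor(pt$pore_class,
                         levels = c("noise", "lacuna", "canal")))
  expect_equal(as.vector(counts), c(2L, 1L, 1L))
  expect_equal(pt$volume_um3[pt$pore_class == "lacuna"], 512)
  expect_equal(pt$volume_um3[pt$pore_class == "canal"], 2744)

  # boundaries are inclusive into the lacuna class: 100 and 1500 um^3
  # exactly (12.5 and 187.5 voxels do not exist at 2 um; use 1 um voxels)
  m2 <- array(FALSE, c(16, 16, 16))
  m2[2:6, 2:6, 2:5] <- TRUE        # 100 voxels = 100 um^3 at 1 um
  pt2 <- labelPores(m2, voxelSize = 1)
  expect_equal(pt2$pore_class, "lacuna")
  m3 <- array(FALSE, c(20, 20, 20))
  m3[2:16, 2:11, 2:11] <- TRUE     # 1500 voxels
  expect_equal(labelPores(m3, voxelSize = 1)$pore_class, "lacuna")
  m3[17, 2, 2] <- TRUE             # 1501 voxels, still one 26-component?
  # (17,2,2) is face-adjacent to (16,2,2)
  expect_equal(labelPores(m3, voxelSize = 1)$pore_class, "canal")
})

test_that("diagonal voxels join under 26-connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE
  pt <- labelPores(m, voxelSize = 2)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$voxel_count, 2)
})

test_that("component labeling matches the propagation oracle", {
  set.seed(11)
  for (p in c(0.2, 0.4)) {
    m <- array(runif(14^3) < p, dim = c(14, 14, 14))
    ours <- PoroCT:::labelComponents(m, 26L)
    oracle <- oracleLabel26(m)
    expect_equal(max(ours), max(oracle))
    # identical partitions: label images agree up to renaming
    expect_equal(length(unique(paste(ours[m], oracle[m]))), max(ours))
    expect_equal(sort(tabulate(ours[m])), sort(tabulate(oracle[m])))
  }
})

test_that("EDT matches the brute-force oracle", {
  set.seed(5)
  m <- array(runif(10^3) < 0.7, dim = c(10, 10, 10))
  expect_equal(PoroCT:::edtSq(m), oracleEdtSq(m))
})

test_that("canal diameter recovers analytic cylinders and spheres", {
  # radius 10 um = 5 voxels at 2 um, voxel-centered, 200 um long
  cyl <- cylinderMask(5, 15, 100, center = c(7, 7))
  expect_lt(abs(canalDiameter(cyl, 2) - 20), 4)  # +/- 2 voxel widths

  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_lt(abs(canalDiameter(single, 2) - 2), 2 + 1e-9)  # +/- 1 voxel

  # sphere diameter converges to 2r with refinement (off-center digitized)
  errs <- vapply(c(2, 1, 0.5), function(vs) {
    rv <- 8 / vs                      # 8 um radius
    n <- as.integer(ceiling(4 * rv))
    m <- sphereMask(rv, n, center = rep((n - 1) / 2 + 0.3, 3))
    abs(canalDiameter(m, vs) - 16)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1)
  expect_error(canalDiameter(array(FALSE, c(3, 3, 3)), 2), "empty")
})

test_that("microporosity metrics follow their defining ratios", {
  # hand arithmetic: TV = 0.001 mm^3, ten lacunae totalling 4e-7 mm^3
  pt <- data.frame(label = 1:10, voxel_count = 5,
                   volume_um3 = 40, pore_class = "lacuna",
                   centroid_s = 0, centroid_r = 0, centroid_c = 0,
                   diameter_um = 5, border_touching = FALSE)
  roi <- array(TRUE, c(50, 50, 50))  # 125000 voxels * 8 um^3 = 0.001 mm^3
  met <- microporosityMetrics(pt, roi, voxelSize = 2)
  expect_equal(met@lcPorosity, 0.04)
  expect_equal(met@lcDensity, 10000)
  expect_equal(met@caPorosity, 0)
  expect_true(is.na(met@caDiameter))

  # single canal occupies v of TV exactly
  pt2 <- data.frame(label = 1, voxel_count = 250, volume_um3 = 2000,
                    pore_class = "canal", centroid_s = 0, centroid_r = 0,
                    centroid_c = 0, diameter_um = 12,
                    border_touching = FALSE)
  met2 <- microporosityMetrics(pt2, roi, voxelSize = 2)
  expect_equal(met2@caPorosity, 100 * 2000 / 1e6)
  expect_equal(met2@caDiameter, 12)
  expect_error(microporosityMetrics(pt, array(FALSE, c(5, 5, 5)), 2),
               "empty ROI")
})

test_that("pore classes partition the pore voxels and porosity is monotone", {
  set.seed(23)
  d <- c(30, 30, 30)
  m <- array(runif(prod(d)) < 0.08, dim = d)
  pt <- labelPores(m, voxelSize = 2)
  expect_equal(sum(pt$voxel_count), sum(m))
  expect_setequal(unique(pt$pore_class),
                  intersect(c("noise", "lacuna", "canal"),
                            unique(pt$pore_class)))

  roi <- array(TRUE, d)
  base <- microporosityMetrics(pt, roi, 2)
  m2 <- m
  m2[15:18, 15:18, 15:18] <- TRUE  # add a lacuna-sized pore
  pt2 <- labelPores(m2, voxelSize = 2)
  grown <- microporosityMetrics(pt2, roi, 2)
  expect_gte(grown@lcPorosity + grown@caPorosity,
             base@lcPorosity + base@caPorosity)
})

test_that("border-touching pores are flagged and can be excluded", {
  d <- c(20, 20, 20)
  roi <- array(TRUE, d)
  m <- array(FALSE, d)
  m[1:4, 1:4, 1:4] <- TRUE      # touches the ROI border
  m[10:13, 10:13, 10:13] <- TRUE  # interior
  pt <- labelPores(m, voxelSize = 2, roi = roi)
  expect_equal(sort(pt$border_touching), c(FALSE, TRUE))
  incl <- microporosityMetrics(pt, roi, 2)
  excl <- microporosityMetrics(pt, roi, 2, includeBorderTouching = FALSE)
  expect_gt(incl@lcPorosity, excl@lcPorosity)
  expect_equal(excl@lcDensity * incl@tv, 1)  # one interior lacuna left
})
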