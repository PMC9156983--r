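#' Construct a phantom specification
#'
#' See [PhantomSpec-class] for slot meanings, units and defaults. The
#' defaults emulate healthy rat cortical bone at a 2 um isotropic voxel
#' size: matrix density 1200 +/- 60 mg HA/ccm, lacunar volumes drawn
#' log-uniformly on 100-600 um^3 with a 2.9:1 prolate aspect ratio, and
#' 15 um-radius vascular canals.
#'
#' @param dim volume dimensions (slice, row, column), voxels.
#' @param voxelSize um per voxel.
#' @param corticalThickness cortical band thickness, um.
#' @param rodRadius,rodPitch trabecular lattice geometry, um.
#' @param nLacunae,lacunaVolumeRange,lacunaAspect,lacunaVolumeDist
#'   lacunar population parameters (count, um^3 range, long:short ratio,
#'   distribution shape).
#' @param canalRadius,nCanals vascular canal parameters.
#' @param densityMean,densitySd matrix mineral density, mg HA/ccm.
#' @param psfSigma scanner point-spread sigma, voxels; 0 disables blur.
#' @param noiseSd additive detector noise SD, mg HA/ccm; 0 disables.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(160L, 160L, 160L), voxelSize = 2,
                        corticalThickness = 200,
                        rodRadius = 30, rodPitch = 160,
                        nLacunae = 50L, lacunaVolumeRange = c(100, 600),
                        lacunaAspect = 2.9,
                        lacunaVolumeDist = "loguniform",
                        canalRadius = 15, nCanals = 3L,
                        densityMean = 1200, densitySd = 60,
                        psfSigma = 0.8, noiseSd = 25, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize,
      corticalThickness = corticalThickness,
      rodRadius = rodRadius, rodPitch = rodPitch,
      nLacunae = as.integer(nLacunae),
      lacunaVolumeRange = lacunaVolumeRange,
      lacunaAspect = lacunaAspect, lacunaVolumeDist = lacunaVolumeDist,
      canalRadius = canalRadius, nCanals = as.integer(nCanals),
      densityMean = densityMean, densitySd = densitySd,
      psfSigma = psfSigma, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Generate a cortical bone phantom with analytic ground truth
#'
#' Builds a solid cortical band of mineralized matrix (density
#' `N(densityMean, densitySd)`, clipped at zero), carves non-overlapping
#' randomly oriented prolate ellipsoidal lacunae and slice-axis-parallel
#' cylindrical vascular canals down to background density 0, applies a
#' Gaussian point-spread blur and additive noise, and returns the volume
#' together with the cortical ROI and a ground-truth ledger of analytic
#' lacunar/canal geometry and porosity values.
#'
#' Lacunae are placed fully interior to the band (2-voxel minimum gap
#' from each other, the canals and the band surfaces) by rejection
#' sampling; placement failure after 10^4 attempts per lacuna raises an
#' error naming the constraint. Canals span the full slice extent, so
#' they touch the ROI border at the end slices and are flagged
#' accordingly by [labelPores()].
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([CalibratedVolume-class]), `roi`
#'   ([RoiMask-class], label `cortical_medial_third`) and `truth` (list:
#'   per-lacuna centers/semi-axes/volumes, per-canal axes/radii/volumes,
#'   `lcPorosityPct`, `caPorosityPct`, `nLcPerMm3`, `nCaPerMm3`,
#'   `caDiameterUm`, `tvMm3`, `densityMean`, `densitySd`).
#' @examples
#' ph <- generateCorticalPhantom(phantomSpec(
#'   dim = c(60L, 60L, 60L), nLacunae = 5L, nCanals = 1L,
#'   corticalThickness = 80, psfSigma = 0, noiseSd = 0, seed = 7L))
#' ph$truth$lcPorosityPct
#' @export
generateCorticalPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  d <- spec@dim
  vs <- spec@voxelSize

  # cortical band: central slab of rows, full slice/column extent
  bandVox <- min(d[2], max(3L, round(spec@corticalThickness / vs)))
  r0 <- (d[2] - bandVox) %/% 2L            # 0-based first band row
  band_rows <- r0 + seq_len(bandVox) - 1L
  roi <- array(FALSE, dim = d)
  roi[, band_rows + 1L, ] <- TRUE

  dens <- array(0, dim = d)
  nband <- d[1] * bandVox * d[3]
  dens[, band_rows + 1L, ] <- pmax(
    stats::rnorm(nband, spec@densityMean, spec@densitySd), 0)

  gap <- 2 * vs  # minimum surface separation, um

  # canals: parallel to the slice axis, spanning the full slice extent
  canals <- NULL
  if (spec@nCanals > 0L) {
    cr <- spec@canalRadius
    margin <- (cr + gap) / vs
    if (2 * margin >= bandVox)
      stop("phantom generation failed: canal radius does not fit in the ",
           "cortical band", call. = FALSE)
    centers <- matrix(NA_real_, 0, 2)  # (row, col) voxel coords, 0-based
    for (i in seq_len(spec@nCanals)) {
      placed <- FALSE
      for (att in seq_len(10000L)) {
        rr <- stats::runif(1, r0 + margin, r0 + bandVox - 1 - margin)
        cc <- stats::runif(1, margin, d[3] - 1 - margin)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - rr)^2 + (centers[, 2] - cc)^2) * vs >=
                2 * cr + gap)) {
          centers <- rbind(centers, c(rr, cc))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("phantom generation failed: could not place canal ", i,
             " with the required separation", call. = FALSE)
    }
    canals <- data.frame(row = centers[, 1], col = centers[, 2],
                         radius_um = spec@canalRadius,
                         length_um = d[1] * vs,
                         volume_um3 = pi * spec@canalRadius^2 * d[1] * vs)
  }

  # lacunae: prolate ellipsoids, aspect a : a/q : a/q with q = aspect
  lacunae <- NULL
  if (spec@nLacunae > 0L) {
    q <- spec@lacunaAspect
    vols <- drawLacunaVolumes(spec)
    a <- (3 * vols * q^2 / (4 * pi))^(1 / 3)  # long semi-axis, um
    b <- a / q
    centers <- matrix(NA_real_, 0, 3)
    axes <- matrix(NA_real_, 0, 3)  # unit long-axis direction
    for (i in seq_len(spec@nLacunae)) {
      ai <- a[i]
      marg <- (ai + gap) / vs
      if (2 * marg >= bandVox)
        stop("phantom generation failed: lacuna ", i,
             " does not fit in the cortical band", call. = FALSE)
      placed <- FALSE
      for (att in seq_len(10000L)) {
        ctr <- c(stats::runif(1, marg, d[1] - 1 - marg),
                 stats::runif(1, r0 + marg, r0 + bandVox - 1 - marg),
                 stats::runif(1, marg, d[3] - 1 - marg))
        ok <- TRUE
        if (nrow(centers) > 0) {
          dd <- sqrt(colSums((t(centers) - ctr)^2)) * vs
          ok <- all(dd >= a[seq_len(nrow(centers))] + ai + gap)
        }
        if (ok && !is.null(canals)) {
          dc <- sqrt((canals$row - ctr[2])^2 + (canals$col - ctr[3])^2) * vs
          ok <- all(dc >= spec@canalRadius + ai + gap)
        }
        if (ok) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          centers <- rbind(centers, ctr)
          axes <- rbind(axes, u)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("phantom generation failed: could not place lacuna ", i,
             " without overlap (min gap ", gap, " um)", call. = FALSE)
    }
    lacunae <- data.frame(
      slice = centers[, 1], row = centers[, 2], col = centers[, 3],
      u_s = axes[, 1], u_r = axes[, 2], u_c = axes[, 3],
      semi_a_um = a, semi_b_um = b,
      volume_um3 = 4 / 3 * pi * a * b^2)
  }

  # carve canals
  if (!is.null(canals)) {
    rv <- spec@canalRadius / vs
    for (i in seq_len(nrow(canals))) {
      rr <- canals$row[i]; cc <- canals$col[i]
      ri <- max(0, floor(rr - rv)):min(d[2] - 1, ceiling(rr + rv))
      ci <- max(0, floor(cc - rv)):min(d[3] - 1, ceiling(cc + rv))
      sub <- expand.grid(r = ri, c = ci)
      inside <- (sub$r - rr)^2 + (sub$c - cc)^2 <= rv^2
      sel <- sub[inside, ]
      for (j in seq_len(nrow(sel)))
        dens[, sel$r[j] + 1L, sel$c[j] + 1L] <- 0
    }
  }

  # carve lacunae
  if (!is.null(lacunae)) {
    for (i in seq_len(nrow(lacunae))) {
      ctr <- c(lacunae$slice[i], lacunae$row[i], lacunae$col[i])
      av <- lacunae$semi_a_um[i] / vs
      bv <- lacunae$semi_b_um[i] / vs
      u <- c(lacunae$u_s[i], lacunae$u_r[i], lacunae$u_c[i])
      lo <- pmax(0, floor(ctr - av))
      hi <- pmin(d - 1, ceiling(ctr + av))
      g <- expand.grid(s = lo[1]:hi[1], r = lo[2]:hi[2], c = lo[3]:hi[3])
      ds <- g$s - ctr[1]; dr <- g$r - ctr[2]; dc <- g$c - ctr[3]
      along <- ds * u[1] + dr * u[2] + dc * u[3]
      perp2 <- ds^2 + dr^2 + dc^2 - along^2
      inside <- (along / av)^2 + perp2 / bv^2 <= 1
      sel <- g[inside, ]
      dens[cbind(sel$s + 1L, sel$r + 1L, sel$c + 1L)] <- 0
    }
  }

  if (spec@psfSigma > 0) {
    dens <- array(
      cpp_gaussian_blur(as.numeric(dens), as.integer(d), spec@psfSigma,
                        max(1L, as.integer(ceiling(3 * spec@psfSigma)))),
      dim = d)
  }
  if (spec@noiseSd > 0)
    dens <- dens + stats::rnorm(length(dens), 0, spec@noiseSd)

  tv_um3 <- sum(roi) * vs^3
  tv_mm3 <- tv_um3 * 1e-9
  lcV <- if (is.null(lacunae)) 0 else sum(lacunae$volume_um3)
  caV <- if (is.null(canals)) 0 else sum(canals$volume_um3)
  truth <- list(
    lacunae = lacunae, canals = canals,
    lcPorosityPct = 100 * lcV / tv_um3,
    caPorosityPct = 100 * caV / tv_um3,
    nLcPerMm3 = (if (is.null(lacunae)) 0 else nrow(lacunae)) / tv_mm3,
    nCaPerMm3 = (if (is.null(canals)) 0 else nrow(canals)) / tv_mm3,
    caDiameterUm = if (is.null(canals)) NA_real_ else 2 * spec@canalRadius,
    tvMm3 = tv_mm3,
    densityMean = spec@densityMean, densitySd = spec@densitySd)

  list(volume = new("CalibratedVolume", data = dens, voxelSize = vs,
                    provenance = list(phantom = "cortical",
                                      seed = spec@seed)),
       roi = new("RoiMask", mask = roi, label = "cortical_medial_third"),
       truth = truth)
}

drawLacunaVolumes <- function(spec) {
  rng <- spec@lacunaVolumeRange
  n <- spec@nLacunae
  switch(spec@lacunaVolumeDist,
    loguniform = exp(stats::runif(n, log(rng[1]), log(rng[2]))),
    uniform = stats::runif(n, rng[1], rng[2]),
    lognormal = {
      # lognormal matched to the range: median at the geometric middle,
      # +/-2 SD spanning the range, truncated by rejection
      mu <- mean(log(rng)); sdl <- diff(log(rng)) / 4
      v <- stats::rlnorm(n, mu, sdl)
      while (any(bad <- v < rng[1] | v > rng[2]))
        v[bad] <- stats::rlnorm(sum(bad), mu, sdl)
      v
    })
}

#' Generate a trabecular phantom with analytic ground truth
#'
#' Two geometries: `"plates"` — parallel slabs of thickness
#' `plateThickness` separated by `gap` (stacked along the slice axis),
#' with exact `BV/TV = t / (t + g)` and `Tb.Th = t`; `"rods"` — an
#' orthogonal lattice of cylinders of radius `rodRadius` at pitch
#' `rodPitch` along all three axes, with analytic (inclusion-exclusion)
#' BV/TV and nominal `Tb.Th = 2 * rodRadius`.
#'
#' @param spec a [PhantomSpec-class] (used: `dim`, `voxelSize`,
#'   `rodRadius`, `rodPitch`, `densityMean`, `densitySd`, `psfSigma`,
#'   `noiseSd`, `seed`).
#' @param geometry `"rods"` or `"plates"`.
#' @param plateThickness,gap plate geometry in um (plates only).
#' @return list with `volume`, `roi` (full-volume, label `trabecular`)
#'   and `truth` (`bvTv`, `tbThUm`, geometry parameters).
#' @export
generateTrabecularPhantom <- function(spec, geometry = c("rods", "plates"),
                                      plateThickness = 60, gap = 120) {
  stopifnot(is(spec, "PhantomSpec"))
  geometry <- match.arg(geometry)
  set.seed(spec@seed)
  d <- spec@dim
  vs <- spec@voxelSize

  if (geometry == "plates") {
    tvx <- round(plateThickness / vs)
    gvx <- round(gap / vs)
    period <- tvx + gvx
    # phase plates half a gap in so they never touch the volume edge
    # (local thickness needs background on both plate faces)
    s <- seq_len(d[1]) - 1L
    bone1d <- ((s - gvx %/% 2L) %% period) < tvx
    bone <- array(rep(bone1d, times = d[2] * d[3]), dim = d)
    truth <- list(bvTv = tvx / period, tbThUm = tvx * vs,
                  tbSpUm = gvx * vs, geometry = "plates")
  } else {
    rv <- spec@rodRadius / vs
    pv <- spec@rodPitch / vs
    if (spec@rodRadius >= spec@rodPitch / 2)
      stop("rod radius must be smaller than half the pitch", call. = FALSE)
    ax <- function(n) ((seq_len(n) - 1L) + pv / 2) %% pv - pv / 2
    # distance of each coordinate to the nearest lattice line (centered
    # at pv/2, 3pv/2, ...)
    off <- function(n) {
      x <- seq_len(n) - 1L
      dx <- (x - pv / 2) %% pv
      pmin(dx, pv - dx)
    }
    os <- off(d[1]); or <- off(d[2]); oc <- off(d[3])
    bone <- array(FALSE, dim = d)
    # rods along slices: fixed (row, col) near lattice crossings
    rc <- outer(or^2, oc^2, "+") <= rv^2       # row x col
    sc <- outer(os^2, oc^2, "+") <= rv^2       # slice x col
    sr <- outer(os^2, or^2, "+") <= rv^2       # slice x row
    for (s in seq_len(d[1])) {
      m <- rc                                   # rods along slice axis
      m <- m | matrix(sr[s, ], d[2], d[3])      # rods along col axis
      m <- m | matrix(sc[s, ], d[2], d[3], byrow = TRUE)  # along row axis
      bone[s, , ] <- m
    }
    rho <- spec@rodRadius; p <- spec@rodPitch
    cell <- 3 * pi * rho^2 * p - 3 * (16 / 3) * rho^3 +
      8 * (2 - sqrt(2)) * rho^3
    truth <- list(bvTv = cell / p^3, tbThUm = 2 * rho,
                  geometry = "rods")
  }

  dens <- array(0, dim = d)
  nb <- sum(bone)
  dens[bone] <- pmax(stats::rnorm(nb, spec@densityMean, spec@densitySd), 0)
  if (spec@psfSigma > 0)
    dens <- array(
      cpp_gaussian_blur(as.numeric(dens), as.integer(d), spec@psfSigma,
                        max(1L, as.integer(ceiling(3 * spec@psfSigma)))),
      dim = d)
  if (spec@noiseSd > 0)
    dens <- dens + stats::rnorm(length(dens), 0, spec@noiseSd)

  list(volume = new("CalibratedVolume", data = dens, voxelSize = vs,
                    provenance = list(phantom = "trabecular",
                                      seed = spec@seed)),
       roi = new("RoiMask", mask = array(TRUE, dim = d),
                 label = "trabecular"),
       truth = truth)
}

#' Render a 2D greyscale section from a volume
#'
#' Extracts one slice and maps density linearly onto grey levels
#' spanning [0, 255]; the pixel size equals the voxel size, emulating a
#' backscattered-electron section where grey tracks mineral content.
#'
#' @param volume a [CalibratedVolume-class].
#' @param sliceIndex 0-based slice index.
#' @return a [SectionImage-class].
#' @export
renderSection <- function(volume, sliceIndex) {
  stopifnot(is(volume, "CalibratedVolume"))
  d <- dim(volume@data)
  if (sliceIndex < 0 || sliceIndex >= d[1])
    stop("slice index out of range", call. = FALSE)
  sl <- volume@data[sliceIndex + 1L, , ]
  rng <- range(sl)
  px <- if (rng[2] > rng[1]) {
    (sl - rng[1]) / (rng[2] - rng[1]) * 255
  } else matrix(0, d[2], d[3])
  sectionImage(px, volume@voxelSize)
}
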