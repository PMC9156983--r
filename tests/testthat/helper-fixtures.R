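# fixture builders and independent oracles used across the suite

makeVolume <- function(data, voxelSize = 2) {
  new("CalibratedVolume", data = data, voxelSize = voxelSize)
}

constantVolume <- function(value, dim = c(8, 8, 8), voxelSize = 2) {
  makeVolume(array(value, dim = dim), voxelSize)
}

squarePolygon <- function(lo, hi) {
  rbind(c(lo, lo), c(lo, hi), c(hi, hi), c(hi, lo))
}

# solid cube mask with 0-based half-open extents
cubeMask <- function(dim, lo, hi) {
  m <- array(FALSE, dim = dim)
  m[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- TRUE
  m
}

# axis-aligned solid cylinder along the 3rd axis, voxel-centered
cylinderMask <- function(radiusVox, nAcross, nLong, center = NULL) {
  if (is.null(center)) center <- c((nAcross - 1) / 2, (nAcross - 1) / 2)
  m <- array(FALSE, dim = c(nAcross, nAcross, nLong))
  for (s in seq_len(nAcross)) {
    for (r in seq_len(nAcross)) {
      if ((s - 1 - center[1])^2 + (r - 1 - center[2])^2 <= radiusVox^2)
        m[s, r, ] <- TRUE
    }
  }
  m
}

sphereMask <- function(radiusVox, n, center = NULL) {
  if (is.null(center)) center <- rep((n - 1) / 2, 3)
  g <- expand.grid(s = 0:(n - 1), r = 0:(n - 1), c = 0:(n - 1))
  inside <- (g$s - center[1])^2 + (g$r - center[2])^2 +
    (g$c - center[3])^2 <= radiusVox^2
  array(inside, dim = c(n, n, n))
}

# shift a 3D array by an offset, filling exposed planes
shift3 <- function(a, off, fill = Inf) {
  d <- dim(a)
  out <- array(fill, d)
  idx <- vector("list", 3)
  src <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      idx[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o)
    } else {
      idx[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k]
    }
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# independent flood-fill oracle: breadth-first frontier expansion over
# the 26-neighborhood, vectorized in R (no shared code with the
# package's stack-based labeling)
oracleLabel26 <- function(mask) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0L, d)
  current <- 0L
  todo <- which(mask)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[seed] <- current
    frontier <- PoroCT:::indexToCoord(seed, d)  # 0-based coords
    while (nrow(frontier)) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), ,
             drop = FALSE]
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] &
            nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + d[1] * nb[, 2] + d[1] * d[2] * nb[, 3] + 1)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- current
      frontier <- PoroCT:::indexToCoord(lin, d)
    }
  }
  lab
}

# brute-force squared EDT oracle (small masks only)
oracleEdtSq <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  bg <- which(!mask)
  out <- array(0, d)
  if (!length(fg) || !length(bg)) return(out)
  cf <- PoroCT:::indexToCoord(fg, d)
  cb <- PoroCT:::indexToCoord(bg, d)
  for (i in seq_along(fg)) {
    dd <- (cb[, 1] - cf[i, 1])^2 + (cb[, 2] - cf[i, 2])^2 +
      (cb[, 3] - cf[i, 3])^2
    out[fg[i]] <- min(dd)
  }
  out
}

# rendered filled ellipse on a pixel grid (pixel-center inclusion)
renderEllipse <- function(nr, nc, center, semiAxesPx, thetaRad = 0) {
  r <- matrix(rep(0:(nr - 1), nc), nr, nc)
  cc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  x <- (r - center[1]) * cos(thetaRad) + (cc - center[2]) * sin(thetaRad)
  y <- -(r - center[1]) * sin(thetaRad) + (cc - center[2]) * cos(thetaRad)
  (x / semiAxesPx[1])^2 + (y / semiAxesPx[2])^2 <= 1
}

# explicit truncated-normalized 3x3x3 Gaussian kernel tabulation
oracleKernel3 <- function(sigma) {
  w1 <- exp(-(((-1):1)^2) / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  outer(outer(w1, w1), w1)
}
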