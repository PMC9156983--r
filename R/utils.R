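# internal helpers

stopCongruent <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: %s are not congruent (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

asMaskArray <- function(x) {
  if (is(x, "VoxelMask")) return(x@mask)
  if (is.logical(x) && length(dim(x)) == 3L) return(x)
  stop("expected a VoxelMask or a 3D logical array", call. = FALSE)
}

# squared Euclidean distance transform (voxel units) of a 2D or 3D
# logical array; distance from TRUE voxels to the nearest FALSE voxel
edtSq <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    out <- cpp_edt_sq(as.logical(mask), as.integer(c(d[1], d[2], 1L)))
    return(matrix(out, d[1], d[2]))
  }
  array(cpp_edt_sq(as.logical(mask), as.integer(d)), dim = d)
}

# connected-component labels of a 2D (8-connectivity) or 3D (26 by
# default) logical array
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) == 2L) {
    lab <- cpp_label_components(as.logical(mask),
                                as.integer(c(d[1], d[2], 1L)),
                                as.integer(connectivity))
    return(matrix(lab, d[1], d[2]))
  }
  array(cpp_label_components(as.logical(mask), as.integer(d),
                             as.integer(connectivity)), dim = d)
}

# coordinates (0-based, rows = voxels) of linear indices in a 3D array
indexToCoord <- function(idx, d) {
  idx0 <- idx - 1
  s <- idx0 %% d[1]
  r <- (idx0 %/% d[1]) %% d[2]
  c <- idx0 %/% (d[1] * d[2])
  cbind(s, r, c)
}
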