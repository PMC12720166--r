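#' Construct a brain mask
#'
#' @param inside logical (or binarisable numeric) 3D array; TRUE/nonzero
#'   marks in-mask voxels.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices). Defaults
#'   to the identity (voxel units).
#' @return A \linkS4class{BrainMask}.
#' @export
brainMask <- function(inside, affine = diag(4)) {
  if (is.numeric(inside)) inside <- array(inside != 0, dim = dim(inside))
  if (length(dim(inside)) == 2L)
    inside <- array(inside, dim = c(dim(inside), 1L))
  stopifnot(length(dim(inside)) == 3L)
  new("BrainMask", shape = as.integer(dim(inside)),
      affine = unname(as.matrix(affine)),
      inside = inside, insideIdx = which(as.vector(inside)))
}

#' Read a brain mask from a NIfTI volume
#'
#' Any dtype is accepted; voxels with nonzero values are in-mask. The
#' affine is taken from the NIfTI header (xform), adhering to the usual
#' 0-based voxel-index convention.
#'
#' @param path path to a NIfTI-1 file.
#' @return A \linkS4class{BrainMask}.
#' @export
readBrainMask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  dat <- as.array(img)
  if (length(dim(dat)) > 3L) dat <- dat[, , , 1L]
  brainMask(dat != 0, affine = aff)
}

#' Synthetic brain-like ellipsoidal mask
#'
#' An axis-aligned ellipsoid of in-mask voxels centred on the grid, a
#' synthetic stand-in with roughly brain-like proportions for simulations
#' and examples. It is not derived from any template.
#'
#' @param shape integer(3) grid dimensions.
#' @param semiAxes ellipsoid semi-axes in voxels; default 90% of the
#'   grid half-extent per axis.
#' @param affine voxel-to-mm affine.
#' @return A \linkS4class{BrainMask}.
#' @export
syntheticBrainMask <- function(shape = c(40L, 48L, 40L),
                               semiAxes = (shape - 1) / 2 * 0.9,
                               affine = diag(4)) {
  shape <- as.integer(shape)
  ctr <- (shape - 1) / 2
  ix <- (seq_len(shape[1]) - 1 - ctr[1]) / semiAxes[1]
  iy <- (seq_len(shape[2]) - 1 - ctr[2]) / semiAxes[2]
  iz <- (seq_len(shape[3]) - 1 - ctr[3]) / semiAxes[3]
  r2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  brainMask(r2 <= 1, affine = affine)
}

#' Number of in-mask voxels
#' @param mask A \linkS4class{BrainMask}.
#' @return Integer count N.
#' @export
nInside <- function(mask) length(mask@insideIdx)

#' In-mask voxel indices
#'
#' @param mask A \linkS4class{BrainMask}.
#' @return N x 3 integer matrix of 0-based voxel indices, in the canonical
#'   in-mask ordering used by all model vectors.
#' @export
maskIndices <- function(mask) {
  idx <- arrayInd(mask@insideIdx, mask@shape)
  storage.mode(idx) <- "integer"
  idx - 1L
}

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask: %s grid, %d in-mask voxels (%.1f%%)\n",
              paste(object@shape, collapse = "x"), nInside(object),
              100 * nInside(object) / prod(object@shape)))
  cat("affine:\n"); print(signif(object@affine, 4))
})

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse mask affine and rounds to the nearest voxel (round
#' half away from zero). Indices are 0-based. Coordinates whose nearest
#' voxel falls outside the grid are flagged out-of-grid rather than
#' clipped.
#'
#' @param coordsMm numeric 3-vector or n x 3 matrix of mm coordinates.
#' @param mask A \linkS4class{BrainMask}.
#' @return A list with \code{voxel} (n x 3 integer, NA rows when out of
#'   grid), \code{outOfGrid} (logical n) and \code{inMask} (logical n,
#'   FALSE when out of grid or at a masked-out voxel).
#' @export
mmToVoxel <- function(coordsMm, mask) {
  cm <- if (is.null(dim(coordsMm))) matrix(coordsMm, ncol = 3) else
    as.matrix(coordsMm)
  if (!all(is.finite(cm))) {
    bad <- which(!apply(cm, 1, function(r) all(is.finite(r))))
    stop("non-finite coordinates in rows: ", paste(bad, collapse = ", "))
  }
  inv <- solve(mask@affine)
  v <- cm %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(cm), 3, byrow = TRUE)
  v <- roundHalfAway(v)
  oog <- v[, 1] < 0 | v[, 1] >= mask@shape[1] |
         v[, 2] < 0 | v[, 2] >= mask@shape[2] |
         v[, 3] < 0 | v[, 3] >= mask@shape[3]
  vi <- matrix(NA_integer_, nrow(v), 3)
  vi[!oog, ] <- as.integer(v[!oog, , drop = FALSE])
  inMask <- rep(FALSE, nrow(v))
  if (any(!oog)) {
    lin <- vi[!oog, 1] + mask@shape[1] *
      (vi[!oog, 2] + mask@shape[2] * vi[!oog, 3]) + 1L
    inMask[!oog] <- as.vector(mask@inside)[lin]
  }
  list(voxel = vi, outOfGrid = oog, inMask = inMask)
}

#' Convert voxel indices to mm coordinates (voxel centres)
#'
#' @param voxel n x 3 integer matrix of 0-based voxel indices.
#' @param mask A \linkS4class{BrainMask}.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxelToMm <- function(voxel, mask) {
  v <- if (is.null(dim(voxel))) matrix(voxel, ncol = 3) else as.matrix(voxel)
  v %*% t(mask@affine[1:3, 1:3]) +
    matrix(mask@affine[1:3, 4], nrow(v), 3, byrow = TRUE)
}

# linear (1-based, column-major) index of 0-based voxel triples
voxelLinearIndex <- function(voxel, mask) {
  voxel[, 1] + mask@shape[1] * (voxel[, 2] + mask@shape[2] * voxel[, 3]) + 1L
}

# map linear grid indices to positions in the in-mask ordering (NA outside)
maskPosition <- function(linear, mask) {
  pos <- integer(prod(mask@shape))
  pos[mask@insideIdx] <- seq_along(mask@insideIdx)
  out <- pos[linear]
  out[out == 0L] <- NA_integer_
  out
}
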