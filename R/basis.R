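#' One-dimensional cubic B-spline basis on a voxel axis
#'
#' Uniform cubic B-splines on equally spaced knots spanning
#' \code{[0, nPoints - 1]}, with replicated (clamped) boundary knots so
#' that the basis spans the full grid and retains partition of unity at
#' the edges. The basis is evaluated at the integer grid points. The
#' requested spacing is adjusted to the nearest value giving an integer
#' number of equal knot intervals.
#'
#' A degenerate axis of length 1 (single-slice 2D grids) yields the
#' constant basis.
#'
#' @param nPoints grid length in voxels (>= 2, or 1 for a degenerate
#'   axis).
#' @param knotSpacing knot spacing in voxels (> 0, <= grid extent).
#' @param axis label ("x", "y" or "z").
#' @return An \linkS4class{AxisBasis}.
#' @export
bsplineBasis1d <- function(nPoints, knotSpacing, axis = "x") {
  nPoints <- as.integer(nPoints)
  if (nPoints == 1L)
    return(new("AxisBasis", axis = axis, nPoints = 1L,
               knotSpacing = as.numeric(knotSpacing),
               B = matrix(1, 1, 1), nBasis = 1L, knots = c(0, 0)))
  if (nPoints < 2L) stop("nPoints must be >= 2")
  L <- nPoints - 1L
  if (knotSpacing <= 0) stop("knotSpacing must be > 0")
  if (knotSpacing > L) stop("knotSpacing exceeds grid extent")
  nInt <- max(1L, as.integer(round(L / knotSpacing)))
  inner <- seq(0, L, length.out = nInt + 1)
  knots <- c(rep(0, 3), inner, rep(L, 3))
  B <- splines::splineDesign(knots, x = seq(0, L), ord = 4)
  new("AxisBasis", axis = axis, nPoints = nPoints,
      knotSpacing = as.numeric(knotSpacing), B = unname(B),
      nBasis = ncol(B), knots = knots)
}

setMethod("show", "AxisBasis", function(object) {
  cat(sprintf("AxisBasis[%s]: %d grid points, %d cubic B-spline bases\n",
              object@axis, object@nPoints, object@nBasis))
})

# per-column maximum of a sparse nonnegative matrix
colMaxSparse <- function(X) {
  X <- methods::as(X, "CsparseMatrix")
  p <- X@p
  vapply(seq_len(ncol(X)), function(j) {
    if (p[j + 1] > p[j]) max(X@x[(p[j] + 1):p[j + 1]]) else 0
  }, numeric(1))
}

# compact (start, 4 values) representation of a banded basis matrix
bandRepresentation <- function(B) {
  n <- nrow(B)
  start <- integer(n)
  vals <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    nz <- which(B[i, ] != 0)
    start[i] <- nz[1]
    k <- pmin(length(nz), 4L)
    vals[i, seq_len(k)] <- B[i, nz[seq_len(k)]]
  }
  list(start = start, vals = vals, nBasis = ncol(B))
}

#' Tensor-product spatial design matrix over a mask
#'
#' Forms the N x P design \code{X[v, (px, py, pz)] =
#' Bx[ix, px] * By[iy, py] * Bz[iz, pz]} restricted to in-mask voxels,
#' drops tensor columns whose maximum over the mask does not exceed
#' \code{supportThreshold}, and builds the roughness penalty restricted
#' to the retained columns.
#'
#' @param bx,by,bz \linkS4class{AxisBasis} objects matching the mask
#'   shape.
#' @param mask A \linkS4class{BrainMask}.
#' @param supportThreshold retention rule for tensor columns (default
#'   1e-6).
#' @return A \linkS4class{SpatialDesign}.
#' @export
tensorDesign <- function(bx, by, bz, mask, supportThreshold = 1e-6) {
  if (bx@nPoints != mask@shape[1] || by@nPoints != mask@shape[2] ||
      bz@nPoints != mask@shape[3])
    stop("axis grids must match mask shape")
  vox <- maskIndices(mask)
  N <- nrow(vox)
  rx <- bandRepresentation(bx@B)
  ry <- bandRepresentation(by@B)
  rz <- bandRepresentation(bz@B)
  nx <- rx$nBasis; ny <- ry$nBasis; nz <- rz$nBasis
  sx <- rx$start[vox[, 1] + 1L]
  sy <- ry$start[vox[, 2] + 1L]
  sz <- rz$start[vox[, 3] + 1L]
  nzx <- ncol(rx$vals); nzy <- ncol(ry$vals); nzz <- ncol(rz$vals)
  ii <- jj <- vv <- vector("list", nzx * nzy * nzz)
  k <- 0L
  for (c3 in seq_len(nzz)) {
    vz <- rz$vals[vox[, 3] + 1L, c3]
    for (c2 in seq_len(nzy)) {
      vyz <- ry$vals[vox[, 2] + 1L, c2] * vz
      for (c1 in seq_len(nzx)) {
        val <- rx$vals[vox[, 1] + 1L, c1] * vyz
        keep <- val != 0
        if (!any(keep)) next
        k <- k + 1L
        col <- (sx + c1 - 1L) + nx * (sy + c2 - 2L) +
          nx * ny * (sz + c3 - 2L)
        ii[[k]] <- which(keep)
        jj[[k]] <- col[keep]
        vv[[k]] <- val[keep]
      }
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(ii[seq_len(k)]),
                            j = unlist(jj[seq_len(k)]),
                            x = unlist(vv[seq_len(k)]),
                            dims = c(N, nx * ny * nz))
  retained <- which(colMaxSparse(X) > supportThreshold)
  if (!length(retained)) stop("all tensor columns dropped by the mask")
  Xr <- X[, retained, drop = FALSE]
  Jr <- roughnessPenalty(bx, by, bz, retained)
  pz <- (retained - 1L) %/% (nx * ny)
  py <- ((retained - 1L) %% (nx * ny)) %/% nx
  px <- (retained - 1L) %% nx
  bi <- cbind(px = px + 1L, py = py + 1L, pz = pz + 1L)
  new("SpatialDesign", X = Xr, P = length(retained), basisIndex = bi,
      J = Jr, axes = list(x = bx, y = by, z = bz),
      supportThreshold = supportThreshold,
      gridShape = mask@shape, maskIdx = mask@insideIdx,
      fullIndex = as.integer(retained))
}

setMethod("show", "SpatialDesign", function(object) {
  cat(sprintf(
    "SpatialDesign: %d voxels x %d retained tensor B-spline bases\n",
    nrow(object@X), object@P))
  cat(sprintf("  axis bases: %d x %d x %d; support threshold %.1e\n",
              object@axes$x@nBasis, object@axes$y@nBasis,
              object@axes$z@nBasis, object@supportThreshold))
})

#' Roughness penalty on the tensor B-spline coefficient lattice
#'
#' P-spline construction: second-order difference operators applied
#' along each axis of the coefficient lattice, combined additively
#' (Kronecker-sum structure). On a pruned lattice only difference rows
#' whose full three-point stencil is retained are kept, so boundary
#' coefficients are penalised toward their retained neighbours rather
#' than toward zero. The result is symmetric positive semi-definite and
#' vanishes on coefficient fields that are constant, or linear along an
#' axis, over the retained lattice.
#'
#' @param bx,by,bz \linkS4class{AxisBasis} objects.
#' @param retainedColumns integer indices into the full tensor column
#'   ordering (x fastest); defaults to all columns.
#' @return Sparse symmetric P x P penalty matrix.
#' @export
roughnessPenalty <- function(bx, by, bz, retainedColumns = NULL) {
  nx <- bx@nBasis; ny <- by@nBasis; nz <- bz@nBasis
  nFull <- nx * ny * nz
  if (is.null(retainedColumns)) retainedColumns <- seq_len(nFull)
  P <- length(retainedColumns)
  pos <- integer(nFull)
  pos[retainedColumns] <- seq_len(P)
  lat <- cbind(px = (retainedColumns - 1L) %% nx,
               py = ((retainedColumns - 1L) %/% nx) %% ny,
               pz = (retainedColumns - 1L) %/% (nx * ny))
  J <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(P, P))
  axisRows <- function(n, coord, stride) {
    if (n < 3L) {
      if (n == 2L)
        warning("fewer than 3 bases along an axis; ",
                "no second-difference rows")
      return(NULL)
    }
    base <- retainedColumns[lat[, coord] <= n - 3L]
    if (!length(base)) return(NULL)
    p0 <- pos[base]
    p1 <- pos[base + stride]
    p2 <- pos[base + 2L * stride]
    ok <- p0 > 0L & p1 > 0L & p2 > 0L
    if (!any(ok)) return(NULL)
    m <- sum(ok)
    Matrix::sparseMatrix(i = rep(seq_len(m), 3),
                         j = c(p0[ok], p1[ok], p2[ok]),
                         x = rep(c(1, -2, 1), each = m),
                         dims = c(m, P))
  }
  for (ax in list(list(nx, 1L, 1L), list(ny, 2L, nx),
                  list(nz, 3L, nx * ny))) {
    D <- axisRows(ax[[1]], ax[[2]], ax[[3]])
    if (!is.null(D)) J <- J + Matrix::crossprod(D)
  }
  Matrix::forceSymmetric(J)
}

# ---- sum-factorised tensor products ----------------------------------
#
# X beta and X' v exploit the Kronecker structure of the tensor design:
# three small dense axis multiplications over the full grid instead of a
# 64-nonzeros-per-row sparse product. Hand-built designs (empty axes)
# fall back to the sparse matrix.

tensorContract <- function(A, Bx, By, Bz) {
  .contract3(as.numeric(A), c(ncol(Bx), ncol(By), ncol(Bz)),
             Bx, By, Bz)
}

# eta = X %*% beta restricted to in-mask voxels (beta: P x G)
designApply <- function(design, beta) {
  if (!length(design@gridShape))
    return(as.matrix(design@X %*% beta))
  beta <- as.matrix(beta)
  G <- ncol(beta)
  nb <- vapply(design@axes, function(a) a@nBasis, integer(1))
  out <- matrix(0, length(design@maskIdx), G)
  for (g in seq_len(G)) {
    full <- numeric(prod(nb))
    full[design@fullIndex] <- beta[, g]
    fld <- tensorContract(full, design@axes$x@B, design@axes$y@B,
                          design@axes$z@B)
    out[, g] <- fld[design@maskIdx]
  }
  out
}

# X' v for one or more columns v over in-mask voxels
designApplyT <- function(design, v) {
  if (!length(design@gridShape))
    return(as.matrix(Matrix::crossprod(design@X, v)))
  v <- as.matrix(v)
  G <- ncol(v)
  out <- matrix(0, design@P, G)
  for (g in seq_len(G)) {
    full <- numeric(prod(design@gridShape))
    full[design@maskIdx] <- v[, g]
    coef <- tensorContract(full, t(design@axes$x@B), t(design@axes$y@B),
                           t(design@axes$z@B))
    out[, g] <- coef[design@fullIndex]
  }
  out
}

#' Build the spatial design for a mask at a knot spacing in mm
#'
#' Converts the mm spacing to voxels per axis via the affine's scales and
#' assembles the tensor design and penalty.
#'
#' @param mask A \linkS4class{BrainMask}.
#' @param knotSpacingMm knot spacing in mm (default 10).
#' @param supportThreshold tensor column retention threshold.
#' @return A \linkS4class{SpatialDesign}.
#' @export
buildSpatialDesign <- function(mask, knotSpacingMm = 10,
                               supportThreshold = 1e-6) {
  vs <- sqrt(colSums(mask@affine[1:3, 1:3]^2))
  sp <- knotSpacingMm / vs
  bx <- bsplineBasis1d(mask@shape[1], sp[1], "x")
  by <- bsplineBasis1d(mask@shape[2], sp[2], "y")
  bz <- bsplineBasis1d(mask@shape[3], sp[3], "z")
  tensorDesign(bx, by, bz, mask, supportThreshold)
}
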