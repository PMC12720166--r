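# Shared fixtures and independent oracles, built in code.

fullGridMask <- function(shape, affine = diag(4)) {
  cbmr::brainMask(array(TRUE, dim = shape), affine = affine)
}

smallDesign <- function(mask, spacing = 3) {
  suppressWarnings(cbmr::buildSpatialDesign(mask, spacing))
}

# SufficientStats straight from count tables
statsFromCounts <- function(Yg, Yt, groupOf,
                            groups = paste0("g", seq_len(ncol(Yg)))) {
  colnames(Yg) <- groups
  if (is.null(names(Yt))) names(Yt) <- paste0("s", seq_along(Yt))
  new("SufficientStats", Yg = Yg, Yt = Yt, groups = groups,
      groupOf = as.integer(groupOf))
}

# a design whose X is a single column of ones (intercept-only model)
interceptDesign <- function(N) {
  new("SpatialDesign",
      X = Matrix::sparseMatrix(i = seq_len(N), j = rep(1L, N),
                               x = rep(1, N), dims = c(N, 1L)),
      P = 1L, basisIndex = cbind(px = 1L, py = 1L, pz = 1L),
      J = Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(1L, 1L)),
      axes = list(), supportThreshold = 0)
}

# random toy: per-study per-voxel counts plus matching sufficient stats
randomToy <- function(nVox, studiesPerGroup, seed, withCov = TRUE) {
  set.seed(seed)
  G <- length(studiesPerGroup)
  M <- sum(studiesPerGroup)
  groupOf <- rep(seq_len(G), studiesPerGroup)
  Yij <- matrix(rpois(M * nVox, lambda = 0.8), M, nVox)
  Yg <- matrix(0, nVox, G)
  for (g in seq_len(G))
    Yg[, g] <- colSums(Yij[groupOf == g, , drop = FALSE])
  Z <- if (withCov) matrix(rnorm(M), M, 1) else NULL
  list(Yij = Yij, stats = statsFromCounts(Yg, rowSums(Yij), groupOf),
       Z = Z, groupOf = groupOf, M = M, G = G, nVox = nVox)
}

# naive per-study, per-voxel Poisson negative log-likelihood (data-only
# constants dropped): the factorisation oracle
naivePoissonNLL <- function(Yij, X, beta, Z, gamma, groupOf) {
  M <- nrow(Yij)
  ll <- 0
  for (i in seq_len(M)) {
    eta <- as.vector(X %*% beta[, groupOf[i]])
    if (!is.null(Z) && length(gamma))
      eta <- eta + sum(Z[i, ] * gamma)
    mu <- exp(eta)
    ll <- ll + sum(Yij[i, ] * eta - mu)
  }
  -ll
}

# Cox-de Boor recursion, independent of splines::splineDesign
deBoorBasis <- function(knots, x, ord = 4) {
  nb <- length(knots) - ord
  B <- matrix(0, length(x), nb)
  for (j in seq_len(nb)) {
    for (ix in seq_along(x)) {
      B[ix, j] <- deBoorOne(j, ord, knots, x[ix])
    }
  }
  # right-closed support at the last knot
  last <- max(knots)
  B[x == last, nb] <- 1
  B
}

deBoorOne <- function(j, k, t, x) {
  if (k == 1) return(as.numeric(x >= t[j] & x < t[j + 1]))
  d1 <- t[j + k - 1] - t[j]
  d2 <- t[j + k] - t[j + 1]
  a <- if (d1 > 0) (x - t[j]) / d1 * deBoorOne(j, k - 1, t, x) else 0
  b <- if (d2 > 0) (t[j + k] - x) / d2 * deBoorOne(j + 1, k - 1, t, x)
       else 0
  a + b
}

# MNI152-like 2 mm affine (FSL convention): diag(-2, 2, 2), origin
# (90, -126, -72)
mniAffine <- function() {
  rbind(c(-2, 0, 0, 90), c(0, 2, 0, -126), c(0, 0, 2, -72),
        c(0, 0, 0, 1))
}
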