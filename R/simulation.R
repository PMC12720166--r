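#' Create a simulation scenario
#'
#' The defaults reproduce the simulation study conditions: three groups
#' of 100, 100 and 500 studies with identical underlying intensity
#' functions, a high ("~1000 expected foci per study") or low ("~10")
#' total intensity, homogeneous or two-Gaussian-bump spatial patterns,
#' and one standardised uniform[-1, 1] study-level covariate with a
#' global multiplicative effect.
#'
#' @param grid integer vector of 2 or 3 grid dimensions (a 2D grid is a
#'   single-slice volume); ignored when \code{mask} is given.
#' @param mask optional \linkS4class{BrainMask} for masked-3D scenarios.
#' @param pattern "homogeneous" or "two_gaussian_bumps".
#' @param level "high" (1000 expected foci/study) or "low" (10); or set
#'   \code{targetFoci} directly.
#' @param targetFoci expected total foci per study at covariate 0.
#' @param groupSizes studies per group (default 100, 100, 500).
#' @param gammaTrue true covariate effects (default 0.1).
#' @param nCovariates number of covariates (default 1).
#' @param family generating family.
#' @param alphaTrue per-group dispersion for nb / clustered_nb.
#' @param bumpSd bump standard deviation in voxels (default 5).
#' @param bumpMassFraction fraction of total mass carried by the bumps
#'   (default 0.5).
#' @param bumpOffsetFraction bump centre offset from the grid centre as
#'   a fraction of the first-axis extent (default 0.25).
#' @param voxelSizeMm edge length of a grid voxel in mm (default 2, the
#'   template resolution, so a 10 mm knot spacing is 5 voxels).
#' @param seed integer seed.
#' @return A \linkS4class{SimulationScenario}.
#' @export
simulationScenario <- function(grid = c(100L, 100L), mask = NULL,
                               pattern = "homogeneous",
                               level = c("high", "low"),
                               targetFoci = NULL,
                               groupSizes = c(100L, 100L, 500L),
                               gammaTrue = 0.1, nCovariates = 1L,
                               family = "poisson",
                               alphaTrue = rep(0.05, length(groupSizes)),
                               bumpSd = 5, bumpMassFraction = 0.5,
                               bumpOffsetFraction = 0.25,
                               voxelSizeMm = 2, seed = 1L) {
  level <- match.arg(level)
  if (is.null(targetFoci))
    targetFoci <- if (level == "high") 1000 else 10
  if (is.null(mask))
    mask <- brainMask(array(TRUE, dim = c(grid, rep(1L, 3 - length(grid)))),
                      affine = diag(c(rep(voxelSizeMm, 3), 1)))
  new("SimulationScenario", grid = as.integer(mask@shape), mask = mask,
      pattern = pattern, targetFoci = targetFoci,
      groupSizes = as.integer(groupSizes),
      gammaTrue = rep_len(as.numeric(gammaTrue), nCovariates),
      nCovariates = as.integer(nCovariates), family = family,
      alphaTrue = as.numeric(alphaTrue), bumpSd = bumpSd,
      bumpMassFraction = bumpMassFraction,
      bumpOffsetFraction = bumpOffsetFraction, seed = as.integer(seed))
}

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario: %s grid (%d voxels), %s, %g foci/study, %s\n",
    paste(object@grid, collapse = "x"), nInside(object@mask),
    object@pattern, object@targetFoci, object@family))
  cat("  groups:", paste(object@groupSizes, collapse = ", "),
      " gamma:", paste(object@gammaTrue, collapse = ", "), "\n")
})

#' True intensity field of a scenario
#'
#' Homogeneous: constant \code{c = targetFoci / N}. Two Gaussian bumps:
#' a constant background carrying \code{1 - bumpMassFraction} of the
#' mass plus two isotropic Gaussian bumps (equal mass, centres offset
#' by \code{+-bumpOffsetFraction} of the first-axis extent from the grid
#' centre, sd \code{bumpSd} voxels), normalised on the grid so the field
#' sums exactly to \code{targetFoci}.
#'
#' @param scenario A \linkS4class{SimulationScenario}.
#' @return A \linkS4class{TrueIntensity} over the in-mask voxels.
#' @export
makeTrueIntensity <- function(scenario) {
  mask <- scenario@mask
  N <- nInside(mask)
  target <- scenario@targetFoci
  if (scenario@pattern == "homogeneous")
    return(new("TrueIntensity", values = rep(target / N, N),
               pattern = "homogeneous", params = list(constant = target / N)))
  if (scenario@bumpSd <= 0) stop("bump sd must be > 0")
  vox <- maskIndices(mask)
  ctr <- (mask@shape - 1) / 2
  off <- scenario@bumpOffsetFraction * (mask@shape[1] - 1)
  c1 <- c(ctr[1] - off, ctr[2], ctr[3])
  c2 <- c(ctr[1] + off, ctr[2], ctr[3])
  g1 <- exp(-rowSums(sweep(vox, 2, c1)^2) / (2 * scenario@bumpSd^2))
  g2 <- exp(-rowSums(sweep(vox, 2, c2)^2) / (2 * scenario@bumpSd^2))
  f <- scenario@bumpMassFraction
  vals <- (1 - f) * target / N +
    f * target / 2 * (g1 / sum(g1) + g2 / sum(g2))
  new("TrueIntensity", values = vals, pattern = "two_gaussian_bumps",
      params = list(centres = rbind(c1, c2), sd = scenario@bumpSd,
                    background = (1 - f) * target / N,
                    massFraction = f))
}

#' Simulate a grouped CBMA dataset from a scenario
#'
#' Study-level covariates are drawn uniform[-1, 1] and standardised.
#' Per study i and voxel j, counts are drawn from the scenario family
#' with mean \code{truth[j] * exp(Z_i gammaTrue)} (NB adds voxel-wise
#' independent overdispersion \code{alphaTrue}; Clustered NB draws a
#' study-level Gamma(1/alpha, 1/alpha) factor scaling the whole field).
#' Counts are expanded to foci rows at voxel-centre coordinates. All
#' output is deterministic given the scenario seed.
#'
#' @param scenario A \linkS4class{SimulationScenario}.
#' @param returnFoci also build the foci-level
#'   \linkS4class{GroupedDataset} (default TRUE; disable for large
#'   grids when only the sufficient statistics are needed).
#' @return List with \code{stats} (\linkS4class{SufficientStats}),
#'   \code{truth}, \code{covariates} (\linkS4class{CovariateDesign}),
#'   \code{dataset} (or NULL), \code{mask}.
#' @export
simulateDataset <- function(scenario, returnFoci = TRUE) {
  set.seed(scenario@seed)
  mask <- scenario@mask
  truth <- makeTrueIntensity(scenario)
  N <- nInside(mask)
  G <- length(scenario@groupSizes)
  M <- sum(scenario@groupSizes)
  groupOf <- rep(seq_len(G), scenario@groupSizes)
  groups <- paste0("group", seq_len(G))
  R <- scenario@nCovariates
  Zraw <- matrix(runif(M * R, -1, 1), M, R)
  cov <- standardizeCovariates(Zraw,
                               names = paste0("cov", seq_len(R)))
  ez <- as.vector(exp(cov@Z %*% scenario@gammaTrue))
  mu <- truth@values
  tot <- sum(mu)
  pr <- mu / tot
  Yg <- matrix(0, N, G, dimnames = list(NULL, groups))
  Yt <- numeric(M)
  fociVox <- vector("list", M)
  for (i in seq_len(M)) {
    g <- groupOf[i]
    if (scenario@family == "nb") {
      y <- rnbinom(N, size = 1 / scenario@alphaTrue[g], mu = mu * ez[i])
      Yt[i] <- sum(y)
      Yg[, g] <- Yg[, g] + y
      if (returnFoci) {
        nz <- which(y > 0)
        fociVox[[i]] <- rep(nz, y[nz])
      }
    } else {
      lam <- if (scenario@family == "clustered_nb")
        rgamma(1, shape = 1 / scenario@alphaTrue[g],
               rate = 1 / scenario@alphaTrue[g]) else 1
      n <- rpois(1, lam * tot * ez[i])
      vx <- sample.int(N, n, replace = TRUE, prob = pr)
      Yt[i] <- n
      Yg[, g] <- Yg[, g] + tabulate(vx, nbins = N)
      if (returnFoci) fociVox[[i]] <- vx
    }
  }
  ids <- sprintf("study%04d", seq_len(M))
  names(Yt) <- ids
  stats <- new("SufficientStats", Yg = Yg, Yt = Yt, groups = groups,
               groupOf = as.integer(groupOf))
  dataset <- NULL
  if (returnFoci) {
    vox0 <- maskIndices(mask)
    nFoci <- lengths(fociVox)
    allVox <- unlist(fociVox)
    mm <- voxelToMm(vox0[allVox, , drop = FALSE], mask)
    foci <- data.frame(study_id = rep(ids, nFoci), x = mm[, 1],
                       y = mm[, 2], z = mm[, 3])
    studies <- data.frame(study_id = ids, group = groups[groupOf])
    dataset <- groupedDataset(foci = cbind(foci,
                                           group = rep(groups[groupOf],
                                                       nFoci)),
                              studies = studies, groups = groups,
                              covariates = cov@Z)
  }
  list(stats = stats, truth = truth, covariates = cov, dataset = dataset,
       mask = mask)
}

#' Mean absolute difference between estimated and true intensity
#'
#' The estimation-accuracy metric: the mean over voxels of
#' \code{|estimated - true|}, optionally over a replicate-averaged
#' estimate.
#'
#' @param estimated per-voxel estimated intensity (vector, or matrix of
#'   replicates averaged column-wise when \code{truth} is a vector of
#'   matching rows).
#' @param truth per-voxel true intensity.
#' @return Mean absolute difference.
#' @export
biasMetric <- function(estimated, truth) {
  if (is.matrix(estimated) && length(truth) == nrow(estimated))
    estimated <- rowMeans(estimated)
  if (length(estimated) != length(truth))
    stop("estimated and true intensity differ in shape")
  mean(abs(estimated - truth))
}

#' PP-plot data with pointwise order-statistic bands
#'
#' Sorted observed p-values against uniform quantiles \code{k/(n+1)};
#' the k-th pointwise 95\% band endpoints are the 2.5\% and 97.5\%
#' quantiles of Beta(k, n+1-k), the distribution of the k-th order
#' statistic of n uniforms.
#'
#' @param pValues p-values in [0, 1].
#' @param negLog10 return -log10-transformed values.
#' @return data.frame with \code{expected}, \code{observed},
#'   \code{lower}, \code{upper}.
#' @export
ppPlotData <- function(pValues, negLog10 = FALSE) {
  p <- pValues[!is.na(pValues)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  k <- seq_len(n)
  out <- data.frame(expected = k / (n + 1), observed = sort(p),
                    lower = qbeta(0.025, k, n + 1 - k),
                    upper = qbeta(0.975, k, n + 1 - k))
  if (negLog10)
    out[] <- lapply(out, function(x) -log10(pmax(x, 1e-300)))
  out
}

#' Calibration study of the inference methods on null simulations
#'
#' Runs simulate, fit and test for each replicate and reports voxel-wise
#' p-values, rejection rates at the requested levels, PP-plot data, and
#' a pass/fail flag against the binomial 99\% tolerance band for each
#' level.
#'
#' @param scenario A \linkS4class{SimulationScenario} (a null scenario:
#'   identical truth across groups).
#' @param method "wald" (single-group homogeneity), "chi2" (two-group
#'   comparison), "bootstrap" or "bootstrap_gpd" (bootstrap homogeneity).
#' @param replicates number of simulation replicates.
#' @param spec A \linkS4class{FitSpec}.
#' @param boot A \linkS4class{BootstrapConfig} (bootstrap methods).
#' @param knotSpacingMm knot spacing for the fitted design.
#' @param levels rejection levels (default 0.05, 0.01).
#' @param groups group labels involved (first is tested; first two are
#'   compared).
#' @return List with \code{p} (all voxel-wise p-values),
#'   \code{rejection} (per level), \code{withinBand} (per level),
#'   \code{pp} (PP data frame).
#' @export
calibrationSuite <- function(scenario, method = c("wald", "chi2",
                                                  "bootstrap",
                                                  "bootstrap_gpd"),
                             replicates = 1L, spec = fitSpec("poisson"),
                             boot = bootstrapConfig(B = 200L),
                             knotSpacingMm = 10,
                             levels = c(0.05, 0.01), groups = NULL) {
  method <- match.arg(method)
  design <- buildSpatialDesign(scenario@mask, knotSpacingMm)
  ps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc@seed <- scenario@seed + r - 1L
    sim <- simulateDataset(sc, returnFoci = FALSE)
    if (is.null(groups)) groups <- sim$stats@groups
    if (method %in% c("wald", "chi2")) {
      fit <- fitCBMR(sim$stats, design, sim$covariates@Z, spec)
      cv <- fisherCovariance(fit)
      res <- if (method == "wald")
        waldHomogeneityTest(fit, groups[1], cv)
      else contrastChi2Test(fit, cv, C = matrix(c(1, -1), 1),
                            groups = groups[1:2])
      ps[[r]] <- res@pMap
    } else {
      bt <- boot
      bt@seed <- boot@seed + 1000L * r
      bh <- bootstrapHomogeneity(sim$stats, design, groups[1], spec, bt)
      if (method == "bootstrap_gpd") {
        ps[[r]] <- vapply(seq_along(bh$observed), function(j)
          gpdTailPvalue(bh$null[, j], bh$observed[j],
                        tailFraction = boot@tailFraction,
                        minExceedances = boot@minExceedances)$p,
          numeric(1))
      } else ps[[r]] <- bh$result@pMap
    }
  }
  p <- unlist(ps)
  n <- sum(!is.na(p))
  rejection <- vapply(levels, function(a) mean(p < a, na.rm = TRUE),
                      numeric(1))
  withinBand <- vapply(seq_along(levels), function(k) {
    lo <- stats::qbinom(0.005, n, levels[k]) / n
    hi <- stats::qbinom(0.995, n, levels[k]) / n
    rejection[k] >= lo && rejection[k] <= hi
  }, logical(1))
  names(rejection) <- names(withinBand) <- paste0("alpha",
                                                  sub("0[.]", "",
                                                      levels))
  list(p = p, rejection = rejection, withinBand = withinBand,
       pp = ppPlotData(p))
}
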