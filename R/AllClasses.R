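#' @import methods
#' @useDynLib cbmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix Diagonal crossprod t colSums rowSums
#' @importFrom stats optim rpois rnbinom rgamma rmultinom runif rnorm
#'   pchisq pnorm qbeta p.adjust ks.test dnbinom dpois setNames sd
NULL

#' Brain mask on a regular voxel grid
#'
#' A binary analysis mask with its voxel grid dimensions and the affine
#' transform mapping 0-based voxel indices to world (mm) coordinates.
#' All spatial models in the package are defined over the in-mask voxels,
#' in the fixed order given by \code{maskIndices()}.
#'
#' @slot shape integer(3), voxels along x, y, z.
#' @slot affine 4x4 matrix, voxel index (0-based) to mm.
#' @slot inside logical array of dim \code{shape}; TRUE for in-mask voxels.
#' @slot insideIdx integer vector of linear indices (1-based, column-major)
#'   of the in-mask voxels; fixes the voxel ordering used everywhere.
#' @export
setClass("BrainMask",
  representation(shape = "integer", affine = "matrix",
                 inside = "array", insideIdx = "integer"))

setValidity("BrainMask", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  d <- try(det(object@affine[1:3, 1:3]), silent = TRUE)
  if (inherits(d, "try-error") || !is.finite(d) || abs(d) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (!identical(dim(object@inside), as.integer(object@shape)))
    msg <- c(msg, "inside must have dim == shape")
  if (length(object@insideIdx) != sum(object@inside))
    msg <- c(msg, "insideIdx inconsistent with inside")
  if (length(object@insideIdx) < 1L)
    msg <- c(msg, "mask must contain at least one voxel")
  if (length(msg)) msg else TRUE
})

#' Grouped CBMA dataset
#'
#' Studies with group labels, their reported activation foci (mm
#' coordinates) and optional study-level covariates.  Foci are stored in a
#' long table; studies that lost all foci to mask filtering remain listed
#' in \code{studies} and contribute zero counts.
#'
#' @slot studies data.frame with columns \code{study_id}, \code{group}
#'   (one row per study, in model order).
#' @slot foci data.frame with columns \code{study_id}, \code{x}, \code{y},
#'   \code{z} in mm.
#' @slot groups character, ordered group labels.
#' @slot covariates numeric matrix (M x R) or NULL-equivalent 0-column
#'   matrix; rows aligned with \code{studies}.
#' @export
setClass("GroupedDataset",
  representation(studies = "data.frame", foci = "data.frame",
                 groups = "character", covariates = "matrix"))

setValidity("GroupedDataset", function(object) {
  msg <- character()
  st <- object@studies
  if (!all(c("study_id", "group") %in% names(st)))
    msg <- c(msg, "studies must have study_id and group columns")
  if (anyDuplicated(st$study_id))
    msg <- c(msg, "duplicated study_id")
  if (!all(st$group %in% object@groups))
    msg <- c(msg, "every study's group label must be in groups")
  if (!all(object@groups %in% st$group))
    msg <- c(msg, "every group must contain at least one study")
  if (nrow(object@foci)) {
    if (!all(c("study_id", "x", "y", "z") %in% names(object@foci)))
      msg <- c(msg, "foci must have study_id, x, y, z columns")
    else {
      if (!all(object@foci$study_id %in% st$study_id))
        msg <- c(msg, "foci reference unknown study_id")
      if (!all(is.finite(as.matrix(object@foci[, c("x", "y", "z")]))))
        msg <- c(msg, "non-finite focus coordinates")
    }
  }
  if (ncol(object@covariates) > 0 && nrow(object@covariates) != nrow(st))
    msg <- c(msg, "covariate rows must match number of studies")
  if (length(msg)) msg else TRUE
})

#' Standardised study-level covariate design
#'
#' @slot Z numeric matrix M x R.
#' @slot names character(R).
#' @slot standardized logical.
#' @slot center,scale numeric(R); the transform applied, retained so that
#'   effects can be reported on the original covariate scale.
#' @export
setClass("CovariateDesign",
  representation(Z = "matrix", names = "character", standardized = "logical",
                 center = "numeric", scale = "numeric"))

setValidity("CovariateDesign", function(object) {
  msg <- character()
  if (ncol(object@Z) != length(object@names))
    msg <- c(msg, "names must match columns of Z")
  if (object@standardized && ncol(object@Z) > 0) {
    mu <- colMeans(object@Z)
    s <- apply(object@Z, 2, sd)
    if (any(abs(mu) > 1e-10) || any(abs(s - 1) > 1e-10))
      msg <- c(msg, "standardized covariates must have mean 0, sample sd 1")
  }
  if (length(msg)) msg else TRUE
})

#' Sufficient statistics of the factorised CBMR likelihoods
#'
#' Per-group voxel-wise total foci counts (Yg) and per-study total counts
#' (Yt); after factorisation these are the only data the Poisson, NB and
#' Clustered NB likelihoods consume.
#'
#' @slot Yg numeric matrix N x G; column g is the voxel-wise total over
#'   the studies of group g, on the in-mask voxel ordering.
#' @slot Yt named numeric(M); per-study totals, in study order.
#' @slot groups character(G).
#' @slot groupOf integer(M); group index of each study.
#' @export
setClass("SufficientStats",
  representation(Yg = "matrix", Yt = "numeric", groups = "character",
                 groupOf = "integer"))

setValidity("SufficientStats", function(object) {
  msg <- character()
  if (ncol(object@Yg) != length(object@groups))
    msg <- c(msg, "Yg must have one column per group")
  if (any(object@Yg < 0) || any(object@Yg != round(object@Yg)))
    msg <- c(msg, "Yg entries must be nonnegative integers")
  if (any(object@Yt < 0) || any(object@Yt != round(object@Yt)))
    msg <- c(msg, "Yt entries must be nonnegative integers")
  for (g in seq_along(object@groups)) {
    lhs <- sum(object@Yg[, g])
    rhs <- sum(object@Yt[object@groupOf == g])
    if (lhs != rhs)
      msg <- c(msg, sprintf("count conservation violated for group %s",
                            object@groups[g]))
  }
  if (length(msg)) msg else TRUE
})

#' One-dimensional cubic B-spline basis along a voxel axis
#'
#' @slot axis "x", "y" or "z".
#' @slot nPoints grid length in voxels.
#' @slot knotSpacing requested knot spacing in voxels.
#' @slot B dense nPoints x nBasis coefficient matrix (each row: the basis
#'   functions evaluated at that grid point; at most 4 nonzeros, cubic).
#' @slot nBasis number of basis functions.
#' @slot knots the full (clamped) knot vector used.
#' @export
setClass("AxisBasis",
  representation(axis = "character", nPoints = "integer",
                 knotSpacing = "numeric", B = "matrix", nBasis = "integer",
                 knots = "numeric"))

#' Tensor-product spatial design over a brain mask
#'
#' @slot X sparse N x P design matrix (in-mask voxels x retained tensor
#'   B-spline bases), nonnegative.
#' @slot P retained basis count.
#' @slot basisIndex P x 3 integer matrix mapping columns to per-axis basis
#'   indices (px, py, pz).
#' @slot J sparse P x P symmetric positive semi-definite roughness
#'   penalty (second-order difference penalty on the coefficient lattice,
#'   restricted to retained columns).
#' @slot axes list of the three AxisBasis objects.
#' @slot supportThreshold retention rule: tensor columns whose maximum
#'   over the mask is <= this value are dropped.
#' @slot gridShape,maskIdx,fullIndex tensor bookkeeping enabling
#'   sum-factorised products (grid dimensions; linear indices of the
#'   in-mask voxels; retained column positions on the full coefficient
#'   lattice). Zero-length in hand-built designs, which then fall back
#'   to the sparse matrix.
#' @export
setClass("SpatialDesign",
  representation(X = "Matrix", P = "integer", basisIndex = "matrix",
                 J = "Matrix", axes = "list", supportThreshold = "numeric",
                 gridShape = "integer", maskIdx = "integer",
                 fullIndex = "integer"))

#' Fit specification for CBMR estimation
#'
#' @slot family "poisson", "nb" or "clustered_nb".
#' @slot lambda roughness penalty weight; NA_real_ requests the
#'   scale-aware default (see \code{\link{fitCBMR}}).
#' @slot tolOuter,tolInner absolute log-likelihood change tolerances of
#'   the alternating scheme (default 1e-9).
#' @slot maxIter maximum L-BFGS iterations per inner solve.
#' @slot maxOuter maximum outer alternating rounds.
#' @slot init "homogeneous", "uniform_small" or "warm_start".
#' @slot seed integer seed (used by "uniform_small" initialisation).
#' @export
setClass("FitSpec",
  representation(family = "character", lambda = "numeric",
                 tolOuter = "numeric", tolInner = "numeric",
                 maxIter = "integer", maxOuter = "integer",
                 init = "character", seed = "integer"))

setValidity("FitSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("poisson", "nb", "clustered_nb"))
    msg <- c(msg, "family must be poisson, nb or clustered_nb")
  if (object@tolOuter <= 0 || object@tolInner <= 0)
    msg <- c(msg, "tolerances must be > 0")
  if (!object@init %in% c("homogeneous", "uniform_small", "warm_start"))
    msg <- c(msg, "unknown init")
  if (length(msg)) msg else TRUE
})

#' Fitted CBMR model
#'
#' @slot beta P x G matrix of group spatial coefficients.
#' @slot gamma numeric(R) study-level covariate coefficients.
#' @slot alpha numeric(G) dispersion (zero-length for Poisson).
#' @slot nll final penalised negative log-likelihood.
#' @slot loglikUnpenalised unpenalised log-likelihood (data-only constants
#'   dropped) for model comparison.
#' @slot trace per-round objective values.
#' @slot converged logical.
#' @slot nOuter outer rounds used.
#' @slot lambda penalty weight actually used.
#' @slot spec the FitSpec.
#' @slot design,stats,Z the inputs, retained for downstream inference.
#' @export
setClass("CBMRFit",
  representation(beta = "matrix", gamma = "numeric", alpha = "numeric",
                 nll = "numeric", loglikUnpenalised = "numeric",
                 trace = "numeric", converged = "logical",
                 nOuter = "integer", lambda = "numeric", spec = "FitSpec",
                 design = "SpatialDesign", stats = "SufficientStats",
                 Z = "matrix"))

#' Voxel-wise inference result
#'
#' @slot statMap,pMap,zMap,pCorrected numeric vectors over in-mask voxels
#'   (zMap and pCorrected may be length 0 when not applicable).
#' @slot method "wald", "chi2", "bootstrap" or "bootstrap_gpd".
#' @slot correction "none", "bh_fdr", "bonferroni" or "max_null".
#' @slot df degrees of freedom (chi-square tests).
#' @slot details list of method-specific extras (theta0, sidedness,
#'   dropped resamples, singular-voxel count, ...).
#' @export
setClass("CBMRInference",
  representation(statMap = "numeric", pMap = "numeric", zMap = "numeric",
                 pCorrected = "numeric", method = "character",
                 correction = "character", df = "numeric",
                 details = "list"))

setValidity("CBMRInference", function(object) {
  p <- object@pMap[!is.na(object@pMap)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    "p-values must lie in [0, 1]" else TRUE
})

#' Parametric bootstrap configuration
#'
#' @slot B number of resamples (>= 100 for any p-value claim).
#' @slot seed integer seed.
#' @slot statisticScale "log_intensity" or "intensity".
#' @slot gpdEnabled logical, fit a Generalised Pareto tail.
#' @slot tailFraction upper-tail fraction used for GPD fitting.
#' @slot minExceedances minimum exceedances required for a GPD fit.
#' @export
setClass("BootstrapConfig",
  representation(B = "integer", seed = "integer",
                 statisticScale = "character", gpdEnabled = "logical",
                 tailFraction = "numeric", minExceedances = "integer"))

setValidity("BootstrapConfig", function(object) {
  msg <- character()
  if (object@B < 100L)
    msg <- c(msg, "B must be >= 100 for any p-value claim")
  if (object@gpdEnabled &&
      object@tailFraction * object@B < object@minExceedances)
    msg <- c(msg, "tailFraction * B must be >= minExceedances when GPD enabled")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data simulation scenario
#'
#' Defaults follow the study conditions of the simulation design: three
#' groups of 100, 100 and 500 studies, a high (~1000 expected foci per
#' study) or low (~10) total intensity, a homogeneous or two-Gaussian-bump
#' spatial pattern, and one uniform[-1, 1] standardised covariate.
#'
#' @slot grid integer vector (2D or 3D grid) — ignored when \code{mask}
#'   is supplied.
#' @slot mask BrainMask (or a 0-voxel placeholder when \code{grid} rules).
#' @slot pattern "homogeneous" or "two_gaussian_bumps".
#' @slot targetFoci expected total foci per study at covariate 0.
#' @slot groupSizes integer vector of studies per group.
#' @slot gammaTrue numeric, true covariate effects.
#' @slot nCovariates number of uniform[-1,1] covariates generated.
#' @slot family generating family: "poisson", "nb", "clustered_nb".
#' @slot alphaTrue per-group dispersion for nb / clustered_nb.
#' @slot bumpSd,bumpMassFraction,bumpOffsetFraction bump geometry
#'   (sd in voxels; fraction of total mass in the bumps; centre offset as
#'   a fraction of grid extent from the grid centre).
#' @slot seed integer.
#' @export
setClass("SimulationScenario",
  representation(grid = "integer", mask = "ANY", pattern = "character",
                 targetFoci = "numeric", groupSizes = "integer",
                 gammaTrue = "numeric", nCovariates = "integer",
                 family = "character", alphaTrue = "numeric",
                 bumpSd = "numeric", bumpMassFraction = "numeric",
                 bumpOffsetFraction = "numeric", seed = "integer"))

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (object@targetFoci <= 0)
    msg <- c(msg, "expected per-study foci must be > 0")
  if (any(object@groupSizes < 1L))
    msg <- c(msg, "group sizes must all be >= 1")
  if (!object@pattern %in% c("homogeneous", "two_gaussian_bumps"))
    msg <- c(msg, "unknown pattern")
  if (object@pattern == "two_gaussian_bumps" && object@bumpSd <= 0)
    msg <- c(msg, "bump sd must be > 0")
  if (length(msg)) msg else TRUE
})

#' True voxel-wise intensity field of a simulation scenario
#'
#' @slot values strictly positive per-voxel intensity, summing to the
#'   scenario's expected per-study foci count (at covariate 0).
#' @slot pattern the generating pattern.
#' @slot params list of pattern parameters (bump centres, sd, background).
#' @export
setClass("TrueIntensity",
  representation(values = "numeric", pattern = "character", params = "list"))

setValidity("TrueIntensity", function(object) {
  if (any(object@values <= 0)) "intensity must be strictly positive" else TRUE
})
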