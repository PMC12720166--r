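#' Construct a grouped CBMA dataset
#'
#' @param foci data.frame with columns \code{study_id}, \code{group},
#'   \code{x}, \code{y}, \code{z} (mm), one row per reported focus.
#' @param studies optional data.frame (\code{study_id}, \code{group})
#'   listing every study, including studies without foci; defaults to the
#'   studies present in \code{foci}.
#' @param groups ordered group labels; defaults to order of appearance.
#' @param covariates optional numeric matrix or data.frame of study-level
#'   covariates, rows aligned with \code{studies} (or named rows joined on
#'   \code{study_id}).
#' @return A \linkS4class{GroupedDataset}.
#' @export
groupedDataset <- function(foci, studies = NULL, groups = NULL,
                           covariates = NULL) {
  foci <- as.data.frame(foci)
  if (is.null(studies)) {
    studies <- unique(foci[, c("study_id", "group")])
    rownames(studies) <- NULL
  }
  studies <- as.data.frame(studies)
  studies$study_id <- as.character(studies$study_id)
  studies$group <- as.character(studies$group)
  if (is.null(groups)) groups <- unique(studies$group)
  if (is.null(covariates)) {
    covariates <- matrix(numeric(), nrow(studies), 0)
  } else {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates)) &&
        !identical(rownames(covariates), studies$study_id)) {
      miss <- setdiff(studies$study_id, rownames(covariates))
      if (length(miss))
        stop("covariates missing for studies: ", paste(miss, collapse = ", "))
      covariates <- covariates[studies$study_id, , drop = FALSE]
    }
  }
  fc <- if (nrow(foci)) {
    data.frame(study_id = as.character(foci$study_id),
               x = as.numeric(foci$x), y = as.numeric(foci$y),
               z = as.numeric(foci$z))
  } else data.frame(study_id = character(), x = numeric(), y = numeric(),
                    z = numeric())
  new("GroupedDataset", studies = studies, foci = fc,
      groups = as.character(groups), covariates = covariates)
}

#' @describeIn groupedDataset total number of studies M.
#' @param dataset A \linkS4class{GroupedDataset}.
#' @export
nStudies <- function(dataset) nrow(dataset@studies)

#' @describeIn groupedDataset per-group study counts Mg (named).
#' @export
groupSizes <- function(dataset) {
  vapply(dataset@groups,
         function(g) sum(dataset@studies$group == g), integer(1))
}

#' @describeIn groupedDataset ordered group labels.
#' @export
groupLabels <- function(dataset) dataset@groups

setMethod("show", "GroupedDataset", function(object) {
  cat(sprintf("GroupedDataset: %d studies in %d group(s), %d foci\n",
              nStudies(object), length(object@groups), nrow(object@foci)))
  sz <- groupSizes(object)
  cat("  ", paste(sprintf("%s: %d", names(sz), sz), collapse = ", "), "\n")
  if (ncol(object@covariates))
    cat("  covariates:", paste(colnames(object@covariates), collapse = ", "),
        "\n")
})

#' Remove foci outside a brain mask
#'
#' Foci mapping outside the grid or to masked-out voxels are removed.
#' Studies that lose all foci are retained: they still inform the
#' likelihood through zero counts.
#'
#' @param dataset A \linkS4class{GroupedDataset}.
#' @param mask A \linkS4class{BrainMask}.
#' @return A list with \code{dataset} (filtered), \code{nRemoved}, and
#'   \code{removedPerStudy} (named integer vector).
#' @export
filterToMask <- function(dataset, mask) {
  if (!nrow(dataset@foci))
    return(list(dataset = dataset, nRemoved = 0L,
                removedPerStudy = integer()))
  conv <- mmToVoxel(as.matrix(dataset@foci[, c("x", "y", "z")]), mask)
  keep <- conv$inMask
  removed <- dataset@foci$study_id[!keep]
  out <- dataset
  out@foci <- dataset@foci[keep, , drop = FALSE]
  rownames(out@foci) <- NULL
  list(dataset = out, nRemoved = sum(!keep),
       removedPerStudy = if (length(removed)) table(removed) else integer())
}

#' Compute the factorised model's sufficient statistics
#'
#' Maps foci to in-mask voxels and accumulates the per-group voxel-wise
#' totals Yg and per-study totals Yt. Multiple foci of one study in one
#' voxel accumulate as counts.
#'
#' @param dataset A \linkS4class{GroupedDataset}, already filtered to the
#'   mask (an error is raised otherwise).
#' @param mask A \linkS4class{BrainMask}.
#' @return A \linkS4class{SufficientStats}.
#' @export
computeSufficientStats <- function(dataset, mask) {
  st <- dataset@studies
  if (!all(st$group %in% dataset@groups))
    stop("unknown group label")
  groupOf <- match(st$group, dataset@groups)
  N <- nInside(mask)
  G <- length(dataset@groups)
  Yg <- matrix(0, N, G, dimnames = list(NULL, dataset@groups))
  Yt <- setNames(numeric(nrow(st)), st$study_id)
  if (nrow(dataset@foci)) {
    conv <- mmToVoxel(as.matrix(dataset@foci[, c("x", "y", "z")]), mask)
    if (any(!conv$inMask))
      stop("dataset contains out-of-mask foci; run filterToMask() first")
    pos <- maskPosition(voxelLinearIndex(conv$voxel, mask), mask)
    gidx <- groupOf[match(dataset@foci$study_id, st$study_id)]
    for (g in seq_len(G)) {
      sel <- gidx == g
      if (any(sel))
        Yg[, g] <- tabulate(pos[sel], nbins = N)
    }
    tt <- table(dataset@foci$study_id)
    Yt[names(tt)] <- as.numeric(tt)
  }
  new("SufficientStats", Yg = Yg, Yt = Yt, groups = dataset@groups,
      groupOf = as.integer(groupOf))
}

setMethod("show", "SufficientStats", function(object) {
  cat(sprintf(
    "SufficientStats: N = %d voxels, M = %d studies, G = %d group(s)\n",
    nrow(object@Yg), length(object@Yt), length(object@groups)))
  cat("  total foci per group:",
      paste(sprintf("%s: %d", object@groups, as.integer(colSums(object@Yg))),
            collapse = ", "), "\n")
})

#' Standardise study-level covariates
#'
#' Centres each column to mean 0 and scales to sample standard deviation
#' 1 (denominator M - 1). The transform is retained so covariate effects
#' can be reported on the original scale.
#'
#' @param Z numeric M x R matrix (M >= 2, R >= 1).
#' @param names optional column labels.
#' @return A \linkS4class{CovariateDesign}.
#' @export
standardizeCovariates <- function(Z, names = colnames(Z)) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 1) stop("at least one covariate required")
  if (nrow(Z) < 2) stop("at least two studies required")
  if (is.null(names)) names <- paste0("cov", seq_len(ncol(Z)))
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, sd)
  zero <- which(scl < 1e-12)
  if (length(zero))
    stop("zero-variance covariate column(s): ",
         paste(names[zero], collapse = ", "))
  Zs <- sweep(sweep(Z, 2, ctr), 2, scl, `/`)
  colnames(Zs) <- names
  new("CovariateDesign", Z = Zs, names = names, standardized = TRUE,
      center = ctr, scale = scl)
}
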