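# File formats and the pipeline entry point.

#' Write a voxel-wise map as a NIfTI volume
#'
#' Scatters a vector of per-in-mask-voxel values into the mask geometry;
#' out-of-mask voxels receive \code{fill}. The header affine equals the
#' mask affine.
#'
#' @param values numeric vector of length \code{nInside(mask)}.
#' @param mask A \linkS4class{BrainMask}.
#' @param path output file (.nii or .nii.gz).
#' @param fill value for out-of-mask voxels (default 0; NA available).
#' @return The path, invisibly.
#' @export
writeStatMap <- function(values, mask, path, fill = 0) {
  if (length(values) != nInside(mask))
    stop(sprintf("expected %d values (in-mask voxels), got %d",
                 nInside(mask), length(values)))
  arr <- array(fill, dim = mask@shape)
  arr[mask@insideIdx] <- values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(mask@affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(mask@affine, code = 2L)
  RNifti::sform(img) <- structure(mask@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel-wise map back over a mask
#'
#' @param path NIfTI file.
#' @param mask A \linkS4class{BrainMask} on the same grid.
#' @return Numeric vector over in-mask voxels.
#' @export
readStatMap <- function(path, mask) {
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(dim(arr)[1:3], as.integer(mask@shape)))
    stop("map grid does not match mask")
  as.numeric(arr[mask@insideIdx])
}

#' Read a foci table (and optional covariates) into a GroupedDataset
#'
#' The foci table is tab-separated text with header columns
#' \code{study_id}, \code{group}, \code{x}, \code{y}, \code{z} (mm).
#' The optional covariate table has \code{study_id} plus one column per
#' covariate and is joined on \code{study_id}; a mismatch is an error.
#'
#' @param fociPath path to the foci TSV.
#' @param covariatePath optional path to the covariate TSV.
#' @return A \linkS4class{GroupedDataset}.
#' @export
readFociTable <- function(fociPath, covariatePath = NULL) {
  foci <- utils::read.delim(fociPath, stringsAsFactors = FALSE)
  need <- c("study_id", "group", "x", "y", "z")
  if (!all(need %in% names(foci)))
    stop("foci table must have columns: ", paste(need, collapse = ", "))
  covariates <- NULL
  studies <- unique(foci[, c("study_id", "group")])
  if (!is.null(covariatePath)) {
    cv <- utils::read.delim(covariatePath, stringsAsFactors = FALSE)
    if (!"study_id" %in% names(cv))
      stop("covariate table must have a study_id column")
    miss <- setdiff(studies$study_id, cv$study_id)
    if (length(miss))
      stop("covariates missing for studies: ", paste(miss, collapse = ", "))
    cv <- cv[match(studies$study_id, cv$study_id), , drop = FALSE]
    covariates <- as.matrix(cv[, setdiff(names(cv), "study_id"),
                               drop = FALSE])
    rownames(covariates) <- NULL
  }
  groupedDataset(foci, studies = studies, covariates = covariates)
}

#' Write a GroupedDataset's foci (and covariates) as TSV
#'
#' @param dataset A \linkS4class{GroupedDataset}.
#' @param fociPath output foci TSV path.
#' @param covariatePath optional covariate TSV path.
#' @return \code{fociPath}, invisibly.
#' @export
writeFociTable <- function(dataset, fociPath, covariatePath = NULL) {
  grp <- dataset@studies$group[match(dataset@foci$study_id,
                                     dataset@studies$study_id)]
  out <- data.frame(study_id = dataset@foci$study_id, group = grp,
                    x = dataset@foci$x, y = dataset@foci$y,
                    z = dataset@foci$z)
  utils::write.table(out, fociPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(covariatePath) && ncol(dataset@covariates)) {
    cv <- data.frame(study_id = dataset@studies$study_id,
                     dataset@covariates)
    utils::write.table(cv, covariatePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fociPath)
}

readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

configScenario <- function(cf) {
  simulationScenario(
    grid = if (!is.null(cf$grid)) as.integer(unlist(cf$grid)) else
      c(20L, 20L),
    pattern = cf$pattern %||% "homogeneous",
    level = cf$level %||% "high",
    targetFoci = cf$target_foci,
    groupSizes = as.integer(unlist(cf$group_sizes %||%
                                     c(100L, 100L, 500L))),
    gammaTrue = as.numeric(unlist(cf$gamma_true %||% 0.1)),
    nCovariates = as.integer(cf$n_covariates %||% 1L),
    family = cf$family %||% "poisson",
    alphaTrue = rep_len(as.numeric(unlist(cf$alpha_true %||% 0.05)),
                        length(unlist(cf$group_sizes %||%
                                        c(100, 100, 500)))),
    seed = as.integer(cf$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeRunLog <- function(outDir, command, config) {
  log <- c(sprintf("command: %s", command),
           sprintf("time: %s", format(Sys.time())),
           sprintf("cbmr version: %s",
                   as.character(utils::packageVersion("cbmr"))),
           "config:",
           utils::capture.output(utils::str(config)))
  writeLines(log, file.path(outDir, "run_log.txt"))
}

#' Run the CBMR pipeline
#'
#' A config-driven entry point binding the modules: \code{"simulate"}
#' writes a synthetic foci table, covariates and truth map;
#' \code{"fit"} fits a model to a foci table and writes per-group
#' intensity maps plus the serialised fit; \code{"infer"} computes
#' statistical maps for a contrast from a saved fit; \code{"calibrate"}
#' writes a calibration table and PP data. Every run logs its seeds and
#' configuration; all artefacts are regenerable from the logged config.
#'
#' @param command "fit", "infer", "simulate" or "calibrate".
#' @param config a named list or the path of a YAML file. Common fields:
#'   \code{out} (output directory); simulate: \code{scenario};
#'   fit: \code{foci}, \code{covariates}, \code{mask} (NIfTI path,
#'   optional when \code{grid} is given), \code{model}, \code{spacing},
#'   \code{lambda}, \code{seed}; infer: \code{fit} (dir),
#'   \code{method} ("wald", "chi2", "bootstrap"), \code{contrast}
#'   (numeric matrix/vector), \code{groups}, \code{B}, \code{seed};
#'   calibrate: \code{scenario}, \code{method}, \code{replicates}.
#' @return Invisible named list of artefact paths.
#' @export
cbmrPipeline <- function(command = c("fit", "infer", "simulate",
                                     "calibrate"),
                         config = list()) {
  command <- match.arg(command)
  config <- readRunConfig(config)
  outDir <- config$out %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artefacts <- list()
  if (command == "simulate") {
    sc <- configScenario(config$scenario %||% config)
    sim <- simulateDataset(sc)
    artefacts$foci <- file.path(outDir, "foci.tsv")
    artefacts$covariates <- file.path(outDir, "covariates.tsv")
    writeFociTable(sim$dataset, artefacts$foci, artefacts$covariates)
    artefacts$truth <- file.path(outDir, "truth.nii.gz")
    writeStatMap(sim$truth@values, sim$mask, artefacts$truth)
  } else if (command == "fit") {
    ds <- readFociTable(config$foci, config$covariates)
    mask <- if (!is.null(config$mask)) readBrainMask(config$mask) else
      brainMask(array(TRUE, dim = c(as.integer(unlist(config$grid)),
                                    rep(1L, 3 - length(unlist(config$grid))))))
    flt <- filterToMask(ds, mask)
    stats <- computeSufficientStats(flt$dataset, mask)
    design <- buildSpatialDesign(mask, config$spacing %||% 10)
    Z <- if (ncol(flt$dataset@covariates))
      standardizeCovariates(flt$dataset@covariates)@Z else NULL
    spec <- fitSpec(config$model %||% "poisson",
                    lambda = config$lambda %||% NA_real_,
                    seed = as.integer(config$seed %||% 1L))
    fit <- fitCBMR(stats, design, Z, spec)
    artefacts$fit <- file.path(outDir, "fit.rds")
    saveRDS(list(fit = fit, mask = mask, nRemoved = flt$nRemoved),
            artefacts$fit)
    artefacts$params <- file.path(outDir, "parameters.tsv")
    utils::write.table(
      data.frame(parameter = c(sprintf("beta[%d,%s]",
                                       rep(seq_len(nrow(fit@beta)),
                                           ncol(fit@beta)),
                                       rep(stats@groups,
                                           each = nrow(fit@beta))),
                               if (length(fit@gamma))
                                 sprintf("gamma[%d]",
                                         seq_along(fit@gamma)),
                               if (length(fit@alpha))
                                 sprintf("alpha[%s]", stats@groups)),
                 value = c(as.vector(fit@beta), fit@gamma, fit@alpha)),
      artefacts$params, sep = "\t", quote = FALSE, row.names = FALSE)
    mu <- fittedIntensity(fit)
    for (g in stats@groups) {
      f <- file.path(outDir, sprintf("intensity_%s.nii.gz", g))
      writeStatMap(mu[, g], mask, f)
      artefacts[[paste0("intensity_", g)]] <- f
    }
  } else if (command == "infer") {
    saved <- readRDS(file.path(config$fit, "fit.rds"))
    fit <- saved$fit
    mask <- saved$mask
    method <- config$method %||% "chi2"
    groups <- unlist(config$groups) %||% fit@stats@groups
    if (method %in% c("wald", "chi2")) {
      cv <- fisherCovariance(fit)
      res <- if (method == "wald")
        waldHomogeneityTest(fit, groups[1], cv)
      else {
        C <- config$contrast %||% c(1, -1)
        C <- matrix(as.numeric(unlist(C)), ncol = length(groups),
                    byrow = TRUE)
        if (any(!is.finite(C)))
          stop("malformed contrast matrix in row ",
               which(!apply(is.finite(C), 1, all))[1])
        contrastChi2Test(fit, cv, C, groups = groups)
      }
    } else {
      boot <- bootstrapConfig(B = as.integer(config$B %||% 1000L),
                              seed = as.integer(config$seed %||% 1L))
      res <- bootstrapHomogeneity(fit@stats, fit@design, groups[1],
                                  fit@spec, boot)$result
    }
    corr <- config$correction %||% "bh_fdr"
    pc <- if (corr %in% c("bh_fdr", "bonferroni"))
      correctPvalues(res@pMap, corr) else res@pMap
    artefacts$stat <- file.path(outDir, "stat.nii.gz")
    artefacts$p <- file.path(outDir, "p.nii.gz")
    artefacts$p_corrected <- file.path(outDir, "p_corrected.nii.gz")
    writeStatMap(res@statMap, mask, artefacts$stat)
    writeStatMap(res@pMap, mask, artefacts$p, fill = 1)
    writeStatMap(pc, mask, artefacts$p_corrected, fill = 1)
    if (length(res@zMap)) {
      artefacts$z <- file.path(outDir, "z.nii.gz")
      writeStatMap(res@zMap, mask, artefacts$z)
    }
  } else {
    sc <- configScenario(config$scenario %||% config)
    cal <- calibrationSuite(sc, method = config$method %||% "wald",
                            replicates = as.integer(config$replicates %||%
                                                      1L),
                            spec = fitSpec(config$model %||% "poisson"),
                            knotSpacingMm = config$spacing %||% 10)
    artefacts$calibration <- file.path(outDir, "calibration.tsv")
    utils::write.table(
      data.frame(level = names(cal$rejection),
                 rejection = cal$rejection,
                 within_band = cal$withinBand),
      artefacts$calibration, sep = "\t", quote = FALSE,
      row.names = FALSE)
    artefacts$pp <- file.path(outDir, "pp.tsv")
    utils::write.table(cal$pp, artefacts$pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeRunLog(outDir, command, config)
  artefacts$log <- file.path(outDir, "run_log.txt")
  invisible(artefacts)
}
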