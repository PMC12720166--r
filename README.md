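# cbmr — multi-group coordinate-based meta-regression for neuroimaging foci

Coordinate-based meta-analysis (CBMA) synthesises fMRI studies from
which only peak activation coordinates ("foci") are available. `cbmr`
implements multi-group coordinate-based meta-regression: a generative
GLM for voxel-wise foci counts in which each group of studies has its
own smooth spatial intensity function and all studies share global
study-level covariate effects,

    log mu_ij = x_j' beta_g(i) + Z_i gamma,

with x_j a row of a tensor-product cubic B-spline design over the
brain mask (knot spacing 10 mm by default) and a second-order
roughness penalty lambda * sum_g beta_g' J beta_g stabilising the
spatial coefficients. Counts can be Poisson, Negative Binomial (via
moment matching of the voxel-wise group totals: the matched NB has
mean sum_i mu_ij and variance sum_i mu_ij + alpha_g sum_i mu_ij^2) or
Clustered Negative Binomial (a study-level Gamma factor inducing
within-study covariance alpha_g mu_ij mu_ij'). Estimation is penalised
maximum likelihood by L-BFGS, with an alternating dispersion /
coefficient scheme for the dispersed families warm-started at the
Poisson optimum. Inference covers voxel-wise homogeneity (Wald),
group comparison (chi-square contrasts on the log-intensity scale from
the joint Fisher information), study-level covariate tests, BH-FDR /
Bonferroni / max-null FWER correction, and — for sparse datasets where
the information matrix degrades — a parametric bootstrap with
Generalised Pareto tail fitting for p-values below the bootstrap
floor 1/B.

It is aimed at neuroimaging meta-analysts who want group contrasts
with unbalanced groups, covariate adjustment, and calibrated
voxel-wise inference, with statistical maps written as NIfTI volumes.

## Worked example

Simulate a two-group dataset on a small grid, fit the NB model and
test the two groups against each other:

```r
library(cbmr)

sc <- simulationScenario(grid = c(20L, 20L), level = "high",
                         targetFoci = 100, groupSizes = c(40L, 30L),
                         gammaTrue = 0.1, seed = 1)
sim <- simulateDataset(sc)
design <- buildSpatialDesign(sim$mask, knotSpacingMm = 5)
fit <- fitCBMR(sim$stats, design, sim$covariates@Z, fitSpec("nb"))
fit
#> CBMRFit [nb]: 2 group(s), P = 121, R = 1
#>   penalised nll 16605.3983, unpenalised ll -26786.6240, converged in 2 round(s)
#>   alpha: 2.937e-08, 1e-08
#>   gamma: 0.09921

cv <- fisherCovariance(fit)
cmp <- contrastChi2Test(fit, cv, C = matrix(c(1, -1), 1),
                        groups = c("group1", "group2"))
summary(cmp@pMap)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.007556 0.316168 0.513224 0.518396 0.727414 0.999707

covariateChi2Test(fit, cv, Cgamma = 1)
#> $statistic
#> [1] 66.69223
#> $df
#> [1] 1
#> $p
#> [1] 3.173835e-16
```

The fitted `gamma` of 0.099 recovers the generating covariate effect
0.1 (each unit of the standardised covariate scales every study's
intensity by `exp(0.099) ≈ 1.10`), and the fitted dispersions sit at
the Poisson boundary, as they should for Poisson-generated data. The
covariate test rejects its null decisively, while the group-comparison
p-values are close to uniform — both groups were simulated from the
same truth, so no voxel should (and none does, after multiplicity
correction) show a difference. `fittedIntensity(fit)`
returns the per-group voxel-wise intensity maps, and
`writeStatMap(cmp@pMap, sim$mask, "p.nii.gz", fill = 1)` exports any
voxel-wise map as NIfTI. For sparse data,
`bootstrapHomogeneity()` / `bootstrapGroupComparison()` +
`gpdTailPvalue()` replace the Fisher-information path, and
`cbmrPipeline()` drives simulate/fit/infer/calibrate runs from a
config (see `inst/scripts/cbmr.R` for a shell entry point).

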