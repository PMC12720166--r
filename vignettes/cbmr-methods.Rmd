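---
title: "Coordinate-based meta-regression: models, estimation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-regression: models, estimation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmr)
```

## The problem

A coordinate-based meta-analysis (CBMA) dataset consists of the peak
activation coordinates ("foci", x/y/z mm in a template space) reported
by each of many fMRI studies, usually fewer than ten foci per study.
`cbmr` models the voxel-wise counts of these foci with a generative
log-linear intensity model, estimates a smooth activation intensity
function per *group* of studies (e.g. patients vs. controls, task
variants), adjusts for study-level covariates (sample size, publication
year), and tests spatial homogeneity within a group, intensity equality
between groups, and covariate effects.

## The model

Let $Y_{ij}$ be the focus count of study $i$ at voxel $j$
($j = 1,\dots,N$ in-mask voxels), and let study $i$ belong to group
$g(i)$. The intensity is log-linear,

$$\log \mu_{ij} = x_j^\top \beta_{g(i)} + Z_i \gamma,$$

where $x_j^\top$ is row $j$ of a spatial design matrix $X\ (N \times
P)$, $\beta_g$ is a group-specific spatial coefficient vector, $Z$ is
an $M \times R$ matrix of standardised study-level covariates and
$\gamma$ is shared across groups. Because every covariate column is
centred, $X$ carries the overall level and the model is identifiable.

**Spatial basis.** $X$ is a tensor product of one-dimensional cubic
B-spline bases along x, y and z, with equally spaced knots (default
spacing 10 mm, converted to voxels through the mask affine) and
replicated boundary knots, so the basis spans the full grid and
partitions unity. Tensor columns whose maximum over the mask does not
exceed a support threshold (default `1e-6`) are dropped; the retained
count $P$ therefore depends on the mask and on this retention rule.

**Roughness penalty.** The penalised objective adds $\lambda \sum_g
\beta_g^\top J \beta_g$, where $J$ is assembled from second-order
difference operators along each axis of the coefficient lattice (the
standard P-spline penalty), combined additively across axes. On a
pruned lattice only difference rows whose full three-coefficient
stencil is retained are kept. This detail matters: restricting the
full-lattice penalty to the retained columns would implicitly treat
dropped (outside-mask) coefficients as zeros and drag boundary
coefficients toward log-intensity 0 — i.e. toward intensity 1, orders
of magnitude above typical rates — inflating the fitted field in an
edge band. With the stencil rule the penalty vanishes exactly on
fields that are constant (or linear along an axis) over the retained
lattice, so the overall level and smooth trends are unpenalised.

**Penalty weight.** The method description fixes no $\lambda$, so its
choice is a genuine design decision. Two natural-looking automatic
rules fail. Tying $\lambda$ to the initial likelihood *value* is
ill-posed (the homogeneous initial point is constant in space, so its
penalty is zero for every $\lambda$) and, when normalised to make it
well-defined, scales $\lambda$ with the total data size: at
simulation scale this oversmooths structured truth, and the resulting
systematic misfit is then absorbed by the NB dispersion step, whose
$\hat\alpha$ diverges — smoothing-induced spurious overdispersion.
Tying $\lambda$ to the likelihood *curvature* vanishes exactly in the
sparse-count regime the penalty exists for. The package therefore uses
a fixed default $\lambda = 1$: strong enough to tie weakly-informed
boundary and low-count coefficients to their neighbours (the
instability the penalty is for), negligible relative to the likelihood
as counts grow, and it leaves the NB dispersion estimates at their
generating values in simulation. Where an analyst wants the smoothing
adapted to the data, `selectLambda()` splits each group's voxel counts
by binomial thinning (exact for Poisson) into independent training and
validation halves and picks the weight with the best validation
log-likelihood over a logarithmic grid — spatially featureless data
select heavy smoothing, structured data select light smoothing. The
packaged estimation-accuracy runs select $\lambda$ once per simulated
condition this way; `fitSpec(lambda = NA)` requests the same selection
inside a fit, and bootstrap resampling freezes the observed fit's
weight rather than reselecting per resample.

## Three stochastic models, factorised

All three likelihoods consume only two sufficient statistics: the
voxel-wise total count per group, $Y_{gj} = \sum_{i \in g} Y_{ij}$, and
the per-study total $Y_{t,i} = \sum_j Y_{ij}$. Data size therefore
never enters the per-iteration cost.

**Poisson.** Sums of independent Poissons are Poisson, so the
factorised likelihood is *exactly* the study-by-voxel likelihood:

$$\ell = \sum_g Y_g^\top \log \mu_g^X + Y_t^\top \log \mu^Z
  - \sum_g (\mathbf 1^\top \mu_g^X)(\textstyle\sum_{i\in g} \mu^Z_i),$$

with $\mu_g^X = \exp(X\beta_g)$ and $\mu^Z = \exp(Z\gamma)$. The test
suite verifies this equality against a brute-force per-study oracle to
1e-10.

**Negative Binomial.** Voxel-wise independent overdispersion with
group dispersion $\alpha_g$: each $Y_{ij}$ is Gamma–Poisson with mean
$\mu_{ij}$ and variance $\mu_{ij} + \alpha_g \mu_{ij}^2$. Sums of NBs
are not NB, so the group total at voxel $j$ is *moment matched*: the
approximating NB has mean $\sum_i \mu_{ij}$ and variance $\sum_i
\mu_{ij} + \alpha_g \sum_i \mu_{ij}^2$ — these two identities are the
normative definition, and they pin the matched size
$r'_{gj} = (\sum_i \mu_{ij})^2 / (\alpha_g \sum_i \mu_{ij}^2)$ and
probability $p'_{gj}$. With shared covariates, $r'$ is constant over
voxels within a group, which keeps the likelihood fully vectorised.

The packaged NB likelihood additionally includes the multinomial
log-probability of the per-study totals given the group totals,
$\sum_{i \in g} Y_{t,i} \log(\mu^Z_i / \sum_{i' \in g} \mu^Z_{i'})$.
Without this allocation term the NB model would describe only the
group totals: $\gamma$ would be identified only weakly through the
covariate sums, and the Poisson model (which describes the full data)
would not be nested in it, invalidating the likelihood-ratio test. With
the term, the NB likelihood converges to the exact Poisson likelihood
as $\alpha \to 0$, which the tests check numerically; passing
`includeAllocation = FALSE` recovers the bare group-total form.

**Clustered NB.** A study-level latent factor $\lambda_i \sim
\mathrm{Gamma}(\alpha_g^{-1}, \alpha_g^{-1})$ scales the whole
intensity field of study $i$, inducing within-study covariance
$\mathrm{C}(Y_{ij}, Y_{ij'}) = \alpha_g \mu_{ij} \mu_{ij'}$. The factor
is marginalised analytically (never stored), leaving a likelihood in
$Y_t$, $Y_g$ and the per-study total intensities. A quadrature oracle
(direct numerical integration of the Gamma mixture on a one-study toy)
and a Monte-Carlo covariance check validate the closed form.

The Quasi-Poisson model is out of scope: it is quasi-likelihood-based
and incompatible with the L-BFGS estimation used here.

## Estimation

The Poisson objective is convex in $(\beta, \gamma)$ and fitted by one
L-BFGS-B run (`stats::optim`), with analytic gradients throughout
(finite-difference-verified in the tests). The NB and Clustered NB
objectives are non-convex; they are warm-started at the Poisson
optimum and then alternate, per round, (a) an L-BFGS solve of the
group dispersions on the log scale — box-bounded to
$[10^{-8}, 10^3]$ — holding $(\beta, \gamma)$ fixed, then (b) an
L-BFGS solve of $(\beta, \gamma)$ holding $\alpha$ fixed, until the
outer objective changes by at most `tolOuter` (default 1e-9,
absolute). The alternating inner solves run at `factr = 1` (machine
precision) because the outer criterion monitors absolute
log-likelihood changes; the looser default `factr` would leave
round-to-round jitter above the outer tolerance. `stats::optim`
exposes no step-size cap or Wolfe constants, so the extra caution that
a non-convex objective demands is carried entirely by the warm start
and the alternating scheme. Initialisation options are `homogeneous`
(the exact intercept-only rate) and `uniform_small` (iid
U[−0.01, 0.01]).

Products with the tensor design use sum-factorisation — three small
dense axis multiplications over the full grid instead of a sparse
$N \times P$ product — which makes full-brain fits (N ≈ 233k,
P ≈ 4.3k) run in about a minute per likelihood family on one CPU.

## Inference

**Parametric.** The observed Fisher information $H$ is the Hessian of
the unpenalised negative log-likelihood at the optimum (analytic for
Poisson; central differences of the analytic gradient otherwise),
over $(\beta_1, \dots, \beta_G, \gamma)$ jointly, so cross-group
covariance induced by shared $\gamma$ is retained. The default
covariance is the sandwich $(H + 2\lambda J)^{-1} H (H + 2\lambda
J)^{-1}$ — the sampling covariance of the *penalised* estimator. The
classical $H^{-1}$ is available but overstates the variance of a
penalised estimate whenever the penalty is non-negligible, deflating
the test statistics; the acceptance tests verify that two-group null
p-values pass a uniformity check under the sandwich form at the
high-intensity 100×100 configuration, and that the classical form's
known low-intensity miscalibration is detected rather than hidden.
$(H + 2\lambda J)^{-1}$ is also available and understates the
variance.
Voxel-wise variances of the log-intensity are $x_j^\top
\mathrm{Var}(\hat\beta_g) x_j$. Group contrasts use
$(C\hat\theta_j)^\top (C V_j C^\top)^{-1} (C\hat\theta_j) \sim
\chi^2_m$; with one group this reduces exactly to the squared Wald
statistic. Inference defaults to the log-intensity scale (the GLM
linear response); the intensity scale is available through the delta
method. The homogeneity null value is $\theta_0 = \log(\text{group
total} / (N M_g))$ — the per-study per-voxel rate under uniformly
scattered foci, at covariate 0 — and the homogeneity test is one-sided
(exceedance is the scientific question); group comparisons are
two-sided. Covariate tests use the $\gamma$ block of the joint
covariance. Multiplicity is handled by Benjamini–Hochberg FDR,
Bonferroni, or FWER from the bootstrap null-maximum distribution.
Diagonal "repair" heuristics for a near-singular information matrix
(adding 1e-6, or 1% of the largest diagonal) are implemented as
diagnostics only — they are known to underestimate variance — and a
singular information matrix raises an error that recommends bootstrap
inference; parametric inference is unreliable below roughly 200 foci
per group.

**Parametric bootstrap.** For homogeneity, each study's observed focus
count is redistributed uniformly over the in-mask voxels (an
equal-probability multinomial — the per-voxel binomial process), the
model refitted, and the fitted log-intensity recorded; voxel-wise
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (B + 1)$ (the +1
convention avoids $p = 0$). For group comparison, the two groups are
pooled, a shared intensity fitted, per-study counts regenerated from
the fitted stochastic family with the original study-to-group
assignment, and the refitted difference of group log-intensities forms
the null; two-sided p-values use $|T|$. Resamples are independent
given (seed, b) and reproducible; non-converged resamples are dropped
and counted, with a warning above 5%. Null statistics are kept
voxel-wise. Bootstrap fits condition on the observed covariates.

**GPD tail.** The bootstrap floor is $1/B$. Beyond the 90th percentile
of the null samples (configurable `tailFraction = 0.1`, at least 30
exceedances), a Generalised Pareto distribution is fitted to the
exceedances by maximum likelihood and
$p = \text{tailFraction} \cdot S_{\mathrm{GPD}}(T - u)$. A
Kolmogorov–Smirnov screen at level 0.01 falls back to the empirical
p-value when the GPD fit is poor. On an Exponential(1) null the fitted
shape concentrates near 0 and a true $10^{-4}$ p-value is recovered
within a factor of two in the large majority of replicates, which the
acceptance tests check.

## The synthetic-data generator

`simulationScenario()` defaults encode the simulation design the
method is evaluated under: three groups of 100, 100 and 500 studies
with identical truth; expected total foci per study of 1000 ("high")
or 10 ("low"); a homogeneous field or a constant background plus two
isotropic Gaussian bumps; and one uniform[−1, 1] covariate,
standardised, with a global multiplicative effect (default
$\gamma = 0.1$ — the design statement fixes the covariate distribution
but not the effect size, so a modest global effect was chosen once).
Bump geometry is likewise unspecified at source and set once: centres
offset ±25% of the first-axis extent from the grid centre, sd 5
voxels, bumps carrying 50% of total mass; all are scenario fields. The
truth field integrates exactly to the target count at covariate 0.
Counts are drawn per study (Poisson via total-then-multinomial
splitting, which is exact; NB voxel-wise; Clustered NB via the
study-level Gamma factor), optionally expanded to foci rows at
voxel-centre coordinates so the full table-in pipeline is exercised.

The generator emulates the *count structure* of CBMA data — sparse
voxel-wise counts, group imbalance, study-level covariates,
overdispersion at study or voxel level. It does not emulate spatial
uncertainty in reported coordinates, anatomically structured
intensity, between-study kernel smoothing, or reporting bias; passing
tests therefore certify the estimation and inference machinery under
the stated generative models, not robustness to those real-data
features.

**Accuracy metric.** Estimation accuracy is summarised as the mean
absolute difference between estimated and true intensity, averaged
over voxels — and over replicates by averaging the estimates first,
i.e. a systematic-bias summary; with a single replicate the same
number reflects bias plus sampling noise.

## Problem sizes used in the packaged checks

The packaged accuracy and calibration runs use, as the package's own
desk scale: the full 91×109×91 grid with a synthetic ellipsoidal
brain-like mask (233,427 in-mask voxels, P = 4,305 at the default
retention rule) with one replicate per condition for the bias
summaries; a reduced 20³ grid with 50 replicates for the
replicate-averaged bias check; the 100×100 2D configuration (pooling
three replicates) for parametric calibration; and a 24×24 2D grid
(~500 voxels) with B = 200 resamples, averaging the rejection fraction
over independent datasets, for bootstrap calibration. Simulation grids
carry 2 mm voxels by default, so the 10 mm knots sit 5 voxels apart.
Because voxel-wise p-maps are spatially correlated (roughly one
independent unit per spline basis), calibration is judged by the
Kolmogorov–Smirnov distance of pooled p-values rather than by iid
order-statistic bands, which are systematically narrower than the PP
curve's sampling noise for correlated maps. The ellipsoid mask is a
synthetic stand-in with brain-like volume and proportions; it is not
derived from any template, so template-specific constants (a
228,483-voxel mask, P = 2,624) are not expected to reproduce exactly —
the retained basis count is reported alongside the retention rule
instead.

## Numerical choices and degenerate inputs

- Voxel indices are 0-based; mm→voxel rounds half away from zero under
  the inverse affine; out-of-grid foci are flagged, not clipped.
- Covariate standardisation uses the sample sd (denominator M−1);
  zero-variance columns are rejected by name.
- Studies losing all foci to masking are retained (zero counts inform
  the likelihood); duplicate foci in one voxel accumulate as counts.
- A voxel where all study intensities vanish is a degenerate matched
  NB (point mass at zero) and is short-circuited.
- Overflow of any linear predictor past 700 raises an error naming the
  offending magnitude rather than returning Inf.
- The LRT of Poisson against NB uses unpenalised log-likelihoods, df =
  G, and reports the boundary caveat (α = 0 sits on the parameter
  boundary, making plain χ² conservative); AIC/BIC use k = GP + R (+G
  dispersions) and n = GN factorised observations.

## Known limitations

- The moment-matched NB is an approximation to the convolution of NB
  counts; only its first two moments are exact.
- Fisher-information inference degrades for sparse data (below ~200
  foci per group); the bootstrap path exists for exactly that regime,
  at substantial computational cost.
- The bootstrap loop is embarrassingly parallel over resamples but is
  executed serially here; `seed + b` reproducibility makes external
  parallelisation straightforward.
- Group-specific covariate effects are supported by design
  construction (per-group fits, or zero-padded group-specific
  columns), not by special-cased likelihood code.
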