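fitSmallTwoGroup <- function(seed = 51, target = 60,
                             groupSizes = c(12L, 10L)) {
  sc <- simulationScenario(grid = c(8L, 8L), targetFoci = target,
                           groupSizes = groupSizes, seed = seed)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 4)
  fit <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("poisson"))
  list(fit = fit, sim = sim)
}

test_that("observed information matches finite differences and yields a
          symmetric covariance", {
  fs <- fitSmallTwoGroup()
  fit <- fs$fit
  Ha <- cbmr:::poissonHessian(fit@stats, fit@design, fit@Z, fit@beta,
                              fit@gamma)
  Hf <- cbmr:::fdHessian(fit@stats, fit@design, fit@Z, fit@beta,
                         fit@gamma, numeric(), "poisson")
  expect_lt(max(abs(Ha - Hf)) / max(abs(Ha)), 1e-4)

  cv <- fisherCovariance(fit)
  expect_equal(cv$cov, t(cv$cov), tolerance = 1e-12)
  expect_true(all(diag(cv$cov) >= 0))
})

test_that("log-intensity variance equals the brute-force quadratic form
          and is nonnegative", {
  fs <- fitSmallTwoGroup(seed = 52)
  fit <- fs$fit
  cv <- fisherCovariance(fit)
  v <- logIntensityVariance(fit, cv)
  expect_true(all(v >= 0))
  X <- as.matrix(fit@design@X)
  V1 <- cv$cov[cv$betaIndex[[1]], cv$betaIndex[[1]]]
  brute <- vapply(seq_len(nrow(X)),
                  function(j) as.numeric(X[j, ] %*% V1 %*% X[j, ]),
                  numeric(1))
  expect_equal(unname(v[, 1]), brute, tolerance = 1e-10)

  # single basis column x with Var(beta) = v0: voxel variance = x^2 v0
  d1 <- interceptDesign(3)
  d1@X <- methods::as(Matrix::Matrix(matrix(c(0.5, 1, 2), 3, 1),
                                     sparse = TRUE), "CsparseMatrix")
  fake <- fs$fit
  fake@design <- d1
  fake@beta <- matrix(0, 1, 2)
  cvFake <- list(cov = diag(2) * 0.3,
                 betaIndex = list(1L, 2L), gammaIndex = integer())
  vv <- logIntensityVariance(fake, cvFake)
  expect_equal(unname(vv[, 1]), c(0.5, 1, 2)^2 * 0.3)
})

test_that("one-dimensional contrasts square the Wald statistic and
          self-contrasts are exactly null", {
  fs <- fitSmallTwoGroup(seed = 53)
  fit <- fs$fit
  cv <- fisherCovariance(fit)
  res <- contrastChi2Test(fit, cv, C = matrix(1, 1, 1),
                          groups = fit@stats@groups[1])
  eta <- fittedLogIntensity(fit)[, 1]
  se <- sqrt(logIntensityVariance(fit, cv)[, 1])
  W <- eta / se
  expect_equal(res@statMap, W^2, tolerance = 1e-10)
  expect_equal(res@df, 1)

  # C = (1, -1) applied to two copies of the same group estimates
  same <- contrastChi2Test(fit, cv, C = matrix(c(1, -1), 1),
                           groups = rep(fit@stats@groups[1], 2))
  expect_equal(max(abs(same@statMap)), 0)
  expect_equal(min(same@pMap), 1)
})

test_that("homogeneity Wald test is centred at the uniform-scatter rate
          with consistent z and p maps", {
  fs <- fitSmallTwoGroup(seed = 54)
  fit <- fs$fit
  cv <- fisherCovariance(fit)
  res <- waldHomogeneityTest(fit, fit@stats@groups[1], cv)
  g <- 1
  N <- nrow(fit@stats@Yg)
  Mg <- sum(fit@stats@groupOf == g)
  expect_equal(res@details$theta0,
               log(sum(fit@stats@Yg[, g]) / (N * Mg)))
  expect_equal(res@pMap, 1 - pnorm(res@zMap), tolerance = 1e-12)
  # theta_hat = theta0 -> W = 0 -> one-sided p = 0.5
  expect_equal(pnorm(0, lower.tail = FALSE), 0.5)

  two <- waldHomogeneityTest(fit, fit@stats@groups[1], cv,
                             alternative = "two.sided")
  expect_equal(two@pMap, 2 * pnorm(abs(two@zMap), lower.tail = FALSE))
})

test_that("covariate chi-square test matches the (gamma/se)^2 formula
          and flexible contrasts", {
  fs <- fitSmallTwoGroup(seed = 55)
  fit <- fs$fit
  cv <- fisherCovariance(fit)
  res <- covariateChi2Test(fit, cv, Cgamma = matrix(1, 1, 1))
  se2 <- cv$cov[cv$gammaIndex, cv$gammaIndex]
  expect_equal(res$statistic, fit@gamma^2 / se2, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # gamma_hat = 0.2, se = 0.1 -> statistic 4, p ~ 0.0455
  fake <- fit
  fake@gamma <- 0.2
  cvFake <- list(cov = matrix(0.01, 1, 1), betaIndex = list(),
                 gammaIndex = 1L)
  r4 <- covariateChi2Test(fake, cvFake, Cgamma = 1)
  expect_equal(r4$statistic, 4, tolerance = 1e-12)
  expect_equal(r4$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r4$p, 0.0455, tolerance = 1e-3)
})

test_that("p-value corrections follow BH step-up, Bonferroni and the
          max-null rule", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(correctPvalues(p, "bh_fdr"), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(correctPvalues(rep(1, 5), "bh_fdr"), rep(1, 5))
  expect_equal(correctPvalues(0.01, "bonferroni",
                              )[1], 0.01)
  expect_equal(correctPvalues(rep(0.01, 20), "bonferroni"),
               rep(0.2, 20))
  # BH is monotone and never below raw p
  set.seed(56)
  praw <- runif(50)
  adj <- correctPvalues(praw, "bh_fdr")
  expect_true(all(adj >= praw))
  o <- order(praw)
  expect_true(all(diff(adj[o]) >= -1e-12))

  expect_error(correctPvalues(p, "max_null"), "null")
  mx <- correctPvalues(c(0.5, 0.5), "max_null",
                       nullMaxStats = c(1, 2, 3, 4), statMap = c(2.5, 5))
  expect_equal(mx, c(0.5, 0))
})

test_that("bootstrap homogeneity p-maps are deterministic given the
          seed", {
  sc <- simulationScenario(grid = c(6L, 6L), targetFoci = 12,
                           groupSizes = 8L, seed = 57)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 3)
  spec <- fitSpec("poisson")
  boot <- bootstrapConfig(B = 100L, seed = 7L)
  r1 <- bootstrapHomogeneity(sim$stats, d, "group1", spec, boot)
  r2 <- bootstrapHomogeneity(sim$stats, d, "group1", spec, boot)
  expect_identical(r1$result@pMap, r2$result@pMap)
  expect_true(all(r1$result@pMap > 0 & r1$result@pMap <= 1))
  # +1 convention: worst case p is B/(B+1), never exactly 1 exceeded
  expect_lte(max(r1$result@pMap), 1)
})

test_that("group-comparison bootstrap is label-symmetric and preserves
          the pooled total intensity", {
  sc <- simulationScenario(grid = c(6L, 6L), targetFoci = 12,
                           groupSizes = c(8L, 6L), seed = 58)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 3)
  spec <- fitSpec("poisson")
  boot <- bootstrapConfig(B = 100L, seed = 9L)
  ab <- bootstrapGroupComparison(sim$stats, d, "group1", "group2",
                                 spec, boot)
  ba <- bootstrapGroupComparison(sim$stats, d, "group2", "group1",
                                 spec, boot)
  expect_equal(ab$observed, -ba$observed, tolerance = 1e-8)
  expect_equal(ab$result@pMap, ba$result@pMap, tolerance = 1e-12)

  # expected regenerated total equals the pooled fitted total
  fittedTotal <- sum(fittedIntensity(ab$pooledFit)[, 1]) *
    length(ab$pooledFit@stats@Yt)
  regenTotals <- vapply(1:50, function(b)
    sum(cbmr:::regenerateStats(ab$pooledFit,
                               rep(1:2, c(8, 6)),
                               c("group1", "group2"),
                               seed = 1000L + b)@Yt),
    numeric(1))
  se <- sd(regenTotals) / sqrt(length(regenTotals))
  expect_lt(abs(mean(regenTotals) - fittedTotal), 3 * se)
})

test_that("GPD tail machinery matches the exponential-tail analytics", {
  set.seed(59)
  # observed below the threshold: empirical tail proportion (+1 rule)
  x <- rexp(500)
  thr <- quantile(x, 0.9, names = FALSE)
  obs <- thr - 0.1
  r <- gpdTailPvalue(x, obs)
  expect_equal(r$method, "empirical")
  expect_equal(r$p, (1 + sum(x >= obs)) / (length(x) + 1))

  # exponential null has GPD shape xi = 0
  xis <- replicate(30, {
    fitted <- cbmr:::fitGPD(rexp(100))
    fitted$xi
  })
  expect_gte(mean(abs(xis) < 0.2), 0.9)

  # too few exceedances falls back with a warning
  expect_warning(r2 <- gpdTailPvalue(rexp(120), 10,
                                     minExceedances = 30L),
                 "exceedances")
  expect_equal(r2$method, "empirical")
})
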