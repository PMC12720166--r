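test_that("intercept-only Poisson fit recovers the closed-form MLE and
          its Fisher variance", {
  # 12 foci, N = 4 voxels, M = 3 studies -> mu_hat = 1.0
  set.seed(21)
  Yg <- matrix(as.numeric(rmultinom(1, 12, rep(1, 4))), 4, 1)
  Yt <- c(5, 4, 3)
  st <- statsFromCounts(Yg, Yt, rep(1L, 3))
  d <- interceptDesign(4)
  fit <- fitCBMR(st, d, NULL, fitSpec("poisson", lambda = 0))
  expect_equal(exp(fit@beta[1, 1]), 1.0, tolerance = 1e-8)
  expect_true(fit@converged)

  cv <- fisherCovariance(fit)
  expect_equal(cv$cov[1, 1], 1 / 12, tolerance = 1e-8)
})

test_that("Poisson objective is convex: random and homogeneous starts
          reach the same optimum", {
  sc <- simulationScenario(grid = c(8L, 8L), targetFoci = 40,
                           groupSizes = c(6L, 5L), seed = 31)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 3)
  f1 <- fitCBMR(sim$stats, d, sim$covariates@Z,
                fitSpec("poisson", lambda = 0.5, init = "homogeneous"))
  f2 <- fitCBMR(sim$stats, d, sim$covariates@Z,
                fitSpec("poisson", lambda = 0.5, init = "uniform_small",
                        seed = 99L))
  expect_equal(f1@nll, f2@nll, tolerance = 1e-6)
})

test_that("alternating NB fit descends from its Poisson warm start and
          converges", {
  sc <- simulationScenario(grid = c(8L, 8L), targetFoci = 60,
                           groupSizes = c(8L, 6L), family = "nb",
                           alphaTrue = c(0.3, 0.3), seed = 32)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 3)
  fit <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("nb"))
  expect_true(fit@converged)
  expect_true(all(fit@alpha > 0))
  # outer objective never increases between rounds
  expect_true(all(diff(fit@trace) <= 1e-8))
})

test_that("a known covariate effect is recovered within three standard
          errors on synthetic data", {
  sc <- simulationScenario(grid = c(10L, 10L), targetFoci = 100,
                           groupSizes = 200L, gammaTrue = 0.3,
                           seed = 33)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 5)
  fit <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("poisson"))
  cv <- fisherCovariance(fit)
  se <- sqrt(cv$cov[cv$gammaIndex, cv$gammaIndex])
  expect_lt(abs(fit@gamma - 0.3), 3 * se)
})

test_that("likelihood ratio test is zero for identical likelihoods and
          detects real overdispersion", {
  sc <- simulationScenario(grid = c(8L, 8L), targetFoci = 50,
                           groupSizes = c(10L, 10L), seed = 34)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 4)
  pois <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("poisson"))
  # alpha forced to (numerically) zero: same likelihood, stat 0, p = 1
  degenerate <- pois
  degenerate@spec@family <- "nb"
  lrt0 <- likelihoodRatioTest(pois, degenerate)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p, 1)
  expect_equal(lrt0$df, 2)

  # strong overdispersion: NB preferred
  scNB <- simulationScenario(grid = c(12L, 12L), targetFoci = 200,
                             groupSizes = 100L, family = "nb",
                             alphaTrue = 1, seed = 35)
  simNB <- simulateDataset(scNB, returnFoci = FALSE)
  dNB <- smallDesign(simNB$mask, 4)
  poisNB <- fitCBMR(simNB$stats, dNB, simNB$covariates@Z,
                    fitSpec("poisson"))
  nbNB <- fitCBMR(simNB$stats, dNB, simNB$covariates@Z, fitSpec("nb"))
  lrt <- likelihoodRatioTest(poisNB, nbNB)
  expect_lt(lrt$p, 0.01)
})

test_that("under Poisson data the LRT null statistic is stochastically
          below the chi-square reference (boundary effect)", {
  stats <- numeric(12)
  d <- NULL
  for (r in seq_len(12)) {
    sc <- simulationScenario(grid = c(7L, 7L), targetFoci = 40,
                             groupSizes = 15L, seed = 400L + r)
    sim <- simulateDataset(sc, returnFoci = FALSE)
    if (is.null(d)) d <- smallDesign(sim$mask, 3)
    pois <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("poisson"))
    nb <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("nb"))
    stats[r] <- max(
      2 * (nb@loglikUnpenalised - pois@loglikUnpenalised), 0)
  }
  # median of chi2_1 is ~0.455; at the alpha = 0 boundary about half
  # the mass sits at 0, so the observed median should fall below it
  expect_lt(median(stats), qchisq(0.5, df = 1))
})

test_that("information criteria follow their definitions and the AIC
          difference matches the LRT algebra", {
  sc <- simulationScenario(grid = c(8L, 8L), targetFoci = 50,
                           groupSizes = c(10L, 8L), seed = 36)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  d <- smallDesign(sim$mask, 4)
  pois <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("poisson"))
  nb <- fitCBMR(sim$stats, d, sim$covariates@Z, fitSpec("nb"))
  icP <- informationCriteria(pois)
  icN <- informationCriteria(nb)
  expect_equal(unname(icP["AIC"]),
               2 * icP[["k"]] - 2 * pois@loglikUnpenalised)
  expect_equal(unname(icP["BIC"]),
               icP[["k"]] * log(icP[["n"]]) - 2 * pois@loglikUnpenalised)
  rawStat <- 2 * (nb@loglikUnpenalised - pois@loglikUnpenalised)
  dk <- icN[["k"]] - icP[["k"]]
  expect_equal(icN[["AIC"]] - icP[["AIC"]], 2 * dk - rawStat,
               tolerance = 1e-8)
})
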