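test_that("true intensity fields integrate to the target and decay to
          background away from bumps", {
  sc <- simulationScenario(grid = c(100L, 100L), targetFoci = 1000)
  tr <- makeTrueIntensity(sc)
  expect_equal(tr@values, rep(0.1, 10000))   # 1000 / 10000 per voxel

  scB <- simulationScenario(grid = c(60L, 40L),
                            pattern = "two_gaussian_bumps",
                            targetFoci = 500, bumpSd = 3)
  trB <- makeTrueIntensity(scB)
  expect_equal(sum(trB@values), 500, tolerance = 1e-8)
  expect_true(all(trB@values > 0))
  # maximum at a bump centre
  vox <- maskIndices(scB@mask)
  ctr <- trB@params$centres
  iMax <- which.max(trB@values)
  dToCentres <- sqrt(rowSums((ctr - matrix(vox[iMax, ], 2, 3,
                                           byrow = TRUE))^2))
  expect_lt(min(dToCentres), 1)   # max at the voxel nearest a centre
  # >= 6 sd away the field is within 1% of the background
  d2 <- pmin(rowSums(sweep(vox, 2, ctr[1, ])^2),
             rowSums(sweep(vox, 2, ctr[2, ])^2))
  far <- d2 > (6 * scB@bumpSd)^2
  expect_true(any(far))
  expect_lt(max(abs(trB@values[far] - trB@params$background)) /
              trB@params$background, 0.01)

  expect_error(makeTrueIntensity(
    simulationScenario(pattern = "two_gaussian_bumps", bumpSd = 0)),
    "sd")
})

test_that("simulated study totals match the target intensity and the
          generator is seed-deterministic", {
  sc <- simulationScenario(grid = c(15L, 15L), targetFoci = 10,
                           groupSizes = c(100L, 100L), gammaTrue = 0.1,
                           seed = 61)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  # E[total | Z] = 10 exp(Z gamma); average over the realised Z
  ez <- exp(sim$covariates@Z %*% 0.1)
  expected <- 10 * mean(ez)
  mcse <- sd(sim$stats@Yt) / sqrt(length(sim$stats@Yt))
  expect_lt(abs(mean(sim$stats@Yt) - expected), 3 * mcse)

  sim2 <- simulateDataset(sc, returnFoci = FALSE)
  expect_identical(sim$stats@Yg, sim2$stats@Yg)
  expect_identical(sim$stats@Yt, sim2$stats@Yt)

  # foci-level output is consistent with the sufficient statistics
  sim3 <- simulateDataset(sc)
  st3 <- computeSufficientStats(sim3$dataset, sim3$mask)
  expect_equal(st3@Yg, sim3$stats@Yg)
  expect_equal(unname(st3@Yt), unname(sim3$stats@Yt))
})

test_that("homogeneous simulation pools to a uniform voxel
          distribution (chi-square goodness of fit)", {
  sc <- simulationScenario(grid = c(10L, 10L), targetFoci = 50,
                           groupSizes = 40L, gammaTrue = 0, seed = 62)
  sim <- simulateDataset(sc, returnFoci = FALSE)
  pooled <- rowSums(sim$stats@Yg)
  expect_true(all(sum(pooled) / length(pooled) >= 5))
  gof <- suppressWarnings(chisq.test(pooled))
  expect_gt(gof$p.value, 0.01)
})

test_that("bias metric is the mean absolute intensity difference", {
  expect_equal(biasMetric(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(biasMetric(c(1, 2, 3) + 0.25, c(1, 2, 3)), 0.25)
  expect_equal(biasMetric(c(0.1, -0.2, 0.1) + 1, rep(1, 3)),
               0.4 / 3)
  # replicate matrices are averaged before the comparison
  est <- cbind(c(1, 2), c(3, 2))
  expect_equal(biasMetric(est, c(2, 2)), 0)
  expect_error(biasMetric(1:3, 1:4), "shape")
})

test_that("PP-plot bands are Beta order-statistic quantiles with
          nominal coverage", {
  pp1 <- ppPlotData(0.4)
  expect_equal(pp1$lower, qbeta(0.025, 1, 1))
  expect_equal(pp1$upper, qbeta(0.975, 1, 1))
  expect_equal(pp1$lower, 0.025)
  expect_equal(pp1$upper, 0.975)

  set.seed(63)
  p <- runif(5000)
  pp <- ppPlotData(p)
  expect_true(all(diff(pp$observed) >= 0))
  inside <- mean(pp$observed >= pp$lower & pp$observed <= pp$upper)
  expect_gt(inside, 0.9)

  expect_error(ppPlotData(numeric()), "p-values")
})

test_that("estimation error decreases with the number of studies on
          matched seeds", {
  wins <- 0L
  d <- NULL
  for (r in 1:10) {
    scSmall <- simulationScenario(grid = c(10L, 10L), targetFoci = 30,
                                  groupSizes = 100L, seed = 700L + r)
    scBig <- simulationScenario(grid = c(10L, 10L), targetFoci = 30,
                                groupSizes = 500L, seed = 700L + r)
    simS <- simulateDataset(scSmall, returnFoci = FALSE)
    simB <- simulateDataset(scBig, returnFoci = FALSE)
    if (is.null(d)) d <- smallDesign(simS$mask, 5)
    fS <- fitCBMR(simS$stats, d, simS$covariates@Z, fitSpec("poisson"))
    fB <- fitCBMR(simB$stats, d, simB$covariates@Z, fitSpec("poisson"))
    bS <- biasMetric(fittedIntensity(fS)[, 1], simS$truth@values)
    bB <- biasMetric(fittedIntensity(fB)[, 1], simB$truth@values)
    if (bB < bS) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
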