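test_that("study intensity combines spatial and covariate effects
          multiplicatively", {
  d <- interceptDesign(2)
  # beta = 0, gamma = 0 -> mu = 1 everywhere
  fl <- studyIntensity(d, matrix(0, 3, 1), matrix(0, 1, 1), 0,
                       rep(1L, 3))
  expect_equal(fl$muX[, 1], rep(1, 2))
  expect_equal(fl$muZ, rep(1, 3))

  # x' beta = log 2 and Z gamma = log 3 -> mu = 6
  fl <- studyIntensity(d, matrix(1, 1, 1), matrix(log(2), 1, 1),
                       log(3), 1L)
  expect_equal(fl$muX[1, 1] * fl$muZ[1], 6)

  expect_error(
    studyIntensity(d, NULL, matrix(1000, 1, 1), numeric(), 1L),
    "overflow")
})

test_that("group-factorised Poisson likelihood equals the naive
          study-by-voxel likelihood on random toys", {
  for (seed in 1:5) {
    toy <- randomToy(nVox = 7, studiesPerGroup = c(2, 3), seed = seed)
    d <- interceptDesign(toy$nVox)
    # richer design: add a random nonneg column
    set.seed(seed + 100)
    X2 <- cbind(1, runif(toy$nVox))
    d@X <- methods::as(Matrix::Matrix(X2, sparse = TRUE), "CsparseMatrix")
    d@P <- 2L
    d@J <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(2L, 2L))
    beta <- matrix(rnorm(2 * toy$G, sd = 0.4), 2, toy$G)
    gamma <- 0.3
    got <- poissonNLL(toy$stats, d, toy$Z, beta, gamma)$value
    want <- naivePoissonNLL(toy$Yij, X2, beta, toy$Z, gamma, toy$groupOf)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Poisson nll of all-zero counts under constant intensity is
          N * M * c", {
  N <- 4; M <- 3; cc <- 0.7
  st <- statsFromCounts(matrix(0, N, 1), rep(0, M), rep(1L, M))
  d <- interceptDesign(N)
  v <- poissonNLL(st, d, NULL, matrix(log(cc), 1, 1), numeric())$value
  expect_equal(v, N * M * cc, tolerance = 1e-12)
})

test_that("NB moment matching reproduces the exact convolution moments
          and the Poisson limit", {
  # Mg = 1, mu = 2, alpha = 0.5 -> NB(2, 0.5) with mean 2, variance 4
  mm <- nbMomentMatch(2, 0.5)
  expect_equal(mm$rPrime, 2)
  expect_equal(mm$pPrime, 0.5)
  expect_equal(mm$mean, 2)
  expect_equal(mm$variance, 4)
  expect_equal(mm$alphaPrime, 1 / mm$rPrime)

  set.seed(5)
  for (k in 1:25) {
    mu <- runif(sample(1:6, 1), 0, 3)
    a <- runif(1, 0.05, 2)
    mm <- nbMomentMatch(mu, a)
    # matched NB moments (R convention: prob = 1 - pPrime)
    expect_equal(mm$rPrime * mm$pPrime / (1 - mm$pPrime), sum(mu),
                 tolerance = 1e-12)
    expect_equal(mm$rPrime * mm$pPrime / (1 - mm$pPrime)^2,
                 sum(mu) + a * sum(mu^2), tolerance = 1e-12)
  }

  # alpha -> 0+: pPrime -> 0 and variance -> mean
  mm <- nbMomentMatch(c(1, 2), 1e-12)
  expect_lt(mm$pPrime, 1e-10)
  expect_equal(mm$variance / mm$mean, 1, tolerance = 1e-10)

  expect_true(nbMomentMatch(c(0, 0), 0.5)$degenerate)
})

test_that("NB nll equals the direct moment-matched NB pmf on a toy", {
  toy <- randomToy(nVox = 3, studiesPerGroup = 2, seed = 42)
  d <- interceptDesign(3)
  set.seed(43)
  X2 <- cbind(1, runif(3))
  d@X <- methods::as(Matrix::Matrix(X2, sparse = TRUE), "CsparseMatrix")
  d@P <- 2L
  d@J <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(2L, 2L))
  beta <- matrix(c(0.2, -0.5), 2, 1)
  gamma <- 0.4
  alpha <- 0.6
  got <- nbNLL(toy$stats, d, toy$Z, beta, gamma, alpha,
               includeConstants = TRUE, includeAllocation = FALSE)$value
  # oracle: per-voxel moment-matched NB pmf of the group totals
  muX <- exp(X2 %*% beta)
  ez <- exp(toy$Z[, 1] * gamma)
  want <- 0
  for (j in 1:3) {
    mm <- nbMomentMatch(muX[j] * ez, alpha)
    want <- want - dnbinom(toy$stats@Yg[j, 1], size = mm$rPrime,
                           prob = 1 - mm$pPrime, log = TRUE)
  }
  expect_equal(got, unname(want), tolerance = 1e-9)
})

test_that("NB and Clustered NB approach the Poisson likelihood as the
          dispersion vanishes", {
  toy <- randomToy(nVox = 6, studiesPerGroup = c(3, 2), seed = 7)
  d <- interceptDesign(6)
  beta <- matrix(c(0.1, -0.2), 1, 2)
  gamma <- 0.25
  pois <- poissonNLL(toy$stats, d, toy$Z, beta, gamma)$value
  nb <- nbNLL(toy$stats, d, toy$Z, beta, gamma, c(1e-8, 1e-8))$value
  cl <- clusteredNbNLL(toy$stats, d, toy$Z, beta, gamma,
                       c(1e-8, 1e-8))$value
  expect_equal(nb, pois, tolerance = 1e-3)
  expect_equal(cl, pois, tolerance = 1e-3)
})

test_that("Clustered NB matches numerical marginalisation of the
          latent Gamma factor on a one-study toy", {
  # one study, two voxels
  Yj <- c(3, 1)
  st <- statsFromCounts(matrix(Yj, 2, 1), sum(Yj), 1L)
  d <- interceptDesign(2)
  set.seed(8)
  X2 <- cbind(c(1, 0), c(0, 1))   # separate intensity per voxel
  d@X <- methods::as(Matrix::Matrix(X2, sparse = TRUE), "CsparseMatrix")
  d@P <- 2L
  d@J <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(2L, 2L))
  beta <- matrix(log(c(1.4, 0.6)), 2, 1)
  alpha <- 0.8
  mu <- c(1.4, 0.6)
  integrand <- function(l)
    vapply(l, function(li)
      prod(dpois(Yj, li * mu)) *
        stats::dgamma(li, shape = 1 / alpha, rate = 1 / alpha),
      numeric(1))
  marg <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  got <- clusteredNbNLL(st, d, NULL, beta, numeric(), alpha)$value
  # clusteredNbNLL drops the data-only constants sum(log Yij!)
  want <- -log(marg) - sum(lgamma(Yj + 1))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("within-study covariance of the Clustered NB model is
          alpha * mu_j * mu_j'", {
  set.seed(9)
  alpha <- 0.5
  mu <- c(1.2, 0.7)
  n <- 20000
  lam <- rgamma(n, shape = 1 / alpha, rate = 1 / alpha)
  y1 <- rpois(n, lam * mu[1])
  y2 <- rpois(n, lam * mu[2])
  cv <- cov(y1, y2)
  se <- sd((y1 - mean(y1)) * (y2 - mean(y2))) / sqrt(n)
  expect_lt(abs(cv - alpha * mu[1] * mu[2]), 3 * se)
})

test_that("analytic gradients of all three likelihoods match central
          finite differences", {
  skip_if_not_installed("pracma")
  toy <- randomToy(nVox = 5, studiesPerGroup = c(3, 2), seed = 12)
  m <- fullGridMask(c(5, 1, 1))
  bx <- bsplineBasis1d(5, 2, "x")
  d <- suppressWarnings(tensorDesign(bx, bsplineBasis1d(1, 1, "y"),
                                     bsplineBasis1d(1, 1, "z"), m))
  P <- d@P; G <- 2
  set.seed(13)
  par0 <- c(runif(P * G, -0.3, 0.3), 0.2, log(c(0.4, 0.9)))
  lam <- 0.7
  relErr <- function(a, b) max(abs(a - b) / (1 + abs(b)))

  fP <- function(p) poissonNLL(toy$stats, d, toy$Z,
                               matrix(p[1:(P * G)], P, G), p[P * G + 1],
                               lambda = lam)$value
  rP <- poissonNLL(toy$stats, d, toy$Z, matrix(par0[1:(P * G)], P, G),
                   par0[P * G + 1], lambda = lam)
  expect_lt(relErr(c(as.vector(rP$gradBeta), rP$gradGamma),
                   pracma::grad(fP, par0[1:(P * G + 1)])), 1e-5)

  fN <- function(p) nbNLL(toy$stats, d, toy$Z,
                          matrix(p[1:(P * G)], P, G), p[P * G + 1],
                          exp(p[P * G + 2:3]), lambda = lam)$value
  rN <- nbNLL(toy$stats, d, toy$Z, matrix(par0[1:(P * G)], P, G),
              par0[P * G + 1], exp(par0[P * G + 2:3]), lambda = lam)
  expect_lt(relErr(c(as.vector(rN$gradBeta), rN$gradGamma,
                     rN$gradLogAlpha), pracma::grad(fN, par0)), 1e-5)

  fC <- function(p) clusteredNbNLL(toy$stats, d, toy$Z,
                                   matrix(p[1:(P * G)], P, G),
                                   p[P * G + 1], exp(p[P * G + 2:3]),
                                   lambda = lam)$value
  rC <- clusteredNbNLL(toy$stats, d, toy$Z,
                       matrix(par0[1:(P * G)], P, G), par0[P * G + 1],
                       exp(par0[P * G + 2:3]), lambda = lam)
  expect_lt(relErr(c(as.vector(rC$gradBeta), rC$gradGamma,
                     rC$gradLogAlpha), pracma::grad(fC, par0)), 1e-5)
})
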