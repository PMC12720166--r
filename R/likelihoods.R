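# Factorised (penalised) log-likelihoods of the CBMR count models.
#
# All three families share the log-linear intensity
#   mu_ij = exp(x_j' beta_g(i) + Z_i gamma) = muX_g[j] * muZ[i]
# and, after factorisation, consume only the sufficient statistics
# Yg (per-group voxel totals) and Yt (per-study totals). Covariate sums
#   s1_g = sum_{i in g} exp(Z_i gamma),  s2_g = sum_{i in g} exp(2 Z_i gamma)
# carry all covariate information needed at a voxel.

covariateSums <- function(Z, gamma, groupOf, G) {
  M <- length(groupOf)
  ez <- if (length(gamma)) as.vector(exp(Z %*% gamma)) else rep(1, M)
  s1 <- vapply(seq_len(G), function(g) sum(ez[groupOf == g]), numeric(1))
  s2 <- vapply(seq_len(G), function(g) sum(ez[groupOf == g]^2), numeric(1))
  list(ez = ez, s1 = s1, s2 = s2)
}

#' Study-level intensity fields
#'
#' Evaluates the group spatial intensities \code{muX_g = exp(X beta_g)},
#' the study covariate effects \code{muZ = exp(Z gamma)} and the
#' per-study total intensities \code{muT_i = muZ_i * sum_j muX_g(i)[j]}.
#'
#' @param design A \linkS4class{SpatialDesign}.
#' @param Z M x R covariate matrix (or NULL for none).
#' @param beta P x G matrix of spatial coefficients.
#' @param gamma numeric(R).
#' @param groupOf integer(M) group index per study.
#' @return List with \code{etaX} (N x G), \code{muX} (N x G), \code{muZ}
#'   (M), \code{muT} (M).
#' @export
studyIntensity <- function(design, Z, beta, gamma, groupOf) {
  eta <- designApply(design, beta)
  if (max(eta) > 700)
    stop(sprintf("overflow in exp: max linear predictor %.1f", max(eta)))
  muX <- exp(eta)
  M <- length(groupOf)
  muZ <- if (length(gamma)) {
    lp <- as.vector(Z %*% gamma)
    if (max(lp) > 700)
      stop(sprintf("overflow in exp: max covariate predictor %.1f", max(lp)))
    exp(lp)
  } else rep(1, M)
  tot <- colSums(muX)
  list(etaX = eta, muX = muX, muZ = muZ, muT = muZ * tot[groupOf])
}

penaltyValueGrad <- function(beta, lambda, J) {
  if (lambda == 0)
    return(list(value = 0, grad = matrix(0, nrow(beta), ncol(beta))))
  Jb <- as.matrix(J %*% beta)
  list(value = lambda * sum(beta * Jb), grad = 2 * lambda * Jb)
}

#' Penalised Poisson negative log-likelihood and gradient
#'
#' The group-factorised Poisson likelihood: modelling voxel-wise group
#' totals is exactly equivalent to the naive per-study, per-voxel model.
#' With \code{includeConstants = TRUE} the data-only term
#' \code{sum lgamma(Ygj + 1)} is included so the value is the exact
#' negative log-pmf of the factorised counts.
#'
#' @param stats A \linkS4class{SufficientStats}.
#' @param design A \linkS4class{SpatialDesign}.
#' @param Z covariate matrix (M x R) or NULL.
#' @param beta P x G matrix; \code{gamma} numeric(R).
#' @param gamma covariate coefficients.
#' @param lambda roughness penalty weight; \code{J} defaults to the
#'   design's penalty.
#' @param J penalty matrix.
#' @param includeConstants include data-only constants.
#' @return List with \code{value}, \code{gradBeta} (P x G),
#'   \code{gradGamma} (R).
#' @export
poissonNLL <- function(stats, design, Z, beta, gamma, lambda = 0,
                       J = design@J, includeConstants = FALSE) {
  G <- length(stats@groups)
  fl <- studyIntensity(design, Z, beta, gamma, stats@groupOf)
  cs <- covariateSums(Z, gamma, stats@groupOf, G)
  ll <- 0
  gradBeta <- matrix(0, nrow(beta), G)
  for (g in seq_len(G)) {
    Y <- stats@Yg[, g]
    ll <- ll + sum(Y * fl$etaX[, g]) - cs$s1[g] * sum(fl$muX[, g])
    if (includeConstants) ll <- ll - sum(lgamma(Y + 1))
    gradBeta[, g] <- designApplyT(design, Y - cs$s1[g] * fl$muX[, g])
  }
  gradGamma <- numeric(length(gamma))
  if (length(gamma)) {
    ll <- ll + sum(stats@Yt * as.vector(Z %*% gamma))
    gradGamma <- as.vector(crossprod(Z, stats@Yt - fl$muT))
  }
  pen <- penaltyValueGrad(beta, lambda, J)
  list(value = -ll + pen$value, gradBeta = -gradBeta + pen$grad,
       gradGamma = -gradGamma)
}

#' Moment-matched Negative Binomial for a voxel-wise sum
#'
#' The sum of independent NB counts with means \code{mu_i} and common
#' dispersion \code{alpha} is approximated by the NB distribution whose
#' first two moments equal the exact convolution moments
#' \code{mean = sum(mu)} and \code{variance = sum(mu) + alpha *
#' sum(mu^2)}. These moment identities are the normative contract; the
#' matched size is \code{rPrime = sum(mu)^2 / (alpha * sum(mu^2))} and
#' the matched probability \code{pPrime = alpha * sum(mu^2) / (sum(mu) +
#' alpha * sum(mu^2))}, so that the matched dispersion (excess-variance
#' index of the matched NB) is \code{alphaPrime = 1 / rPrime}.
#'
#' @param mu per-study intensities at one voxel.
#' @param alpha group dispersion (> 0).
#' @return List with \code{rPrime}, \code{pPrime}, \code{alphaPrime},
#'   \code{mean}, \code{variance}, \code{degenerate}.
#' @export
nbMomentMatch <- function(mu, alpha) {
  stopifnot(alpha > 0)
  m <- sum(mu)
  s2 <- sum(mu^2)
  if (m == 0)
    return(list(rPrime = NA_real_, pPrime = NA_real_,
                alphaPrime = NA_real_, mean = 0, variance = 0,
                degenerate = TRUE))
  r <- m^2 / (alpha * s2)
  p <- alpha * s2 / (m + alpha * s2)
  list(rPrime = r, pPrime = p, alphaPrime = alpha * s2 / m^2,
       mean = m, variance = m + alpha * s2, degenerate = FALSE)
}

#' Penalised Negative Binomial negative log-likelihood and gradient
#'
#' Moment-matched factorised NB likelihood of the voxel-wise group
#' totals. With shared covariates the matched size is constant over
#' voxels within a group: \code{r_g = s1_g^2 / (alpha_g s2_g)} and
#' \code{p_gj = alpha_g s2_g muX_gj / (s1_g + alpha_g s2_g muX_gj)}.
#' Gradients are with respect to beta, gamma and log(alpha).
#'
#' With \code{includeAllocation = TRUE} (default) the multinomial
#' log-probability of the per-study totals given the group totals,
#' \code{sum_i Yt_i log(muZ_i / s1_g)}, is added: the moment-matched NB
#' then models both the voxel-wise group totals and the study
#' allocation, recovers the exact Poisson likelihood in the alpha -> 0
#' limit (proper nesting for the likelihood ratio test) and retains the
#' study totals' information about gamma.
#'
#' @inheritParams poissonNLL
#' @param alpha numeric(G) dispersion per group (> 0).
#' @param includeAllocation include the study-allocation multinomial
#'   term (see Details).
#' @return List with \code{value}, \code{gradBeta}, \code{gradGamma},
#'   \code{gradLogAlpha}.
#' @export
nbNLL <- function(stats, design, Z, beta, gamma, alpha, lambda = 0,
                  J = design@J, includeConstants = FALSE,
                  includeAllocation = TRUE) {
  stopifnot(all(alpha > 0))
  G <- length(stats@groups)
  fl <- studyIntensity(design, Z, beta, gamma, stats@groupOf)
  cs <- covariateSums(Z, gamma, stats@groupOf, G)
  R <- length(gamma)
  ll <- 0
  gradBeta <- matrix(0, nrow(beta), G)
  gradGamma <- numeric(R)
  gradLogAlpha <- numeric(G)
  for (g in seq_len(G)) {
    Y <- stats@Yg[, g]
    x <- fl$muX[, g]
    u <- cs$s1[g]; w <- cs$s2[g]; a <- alpha[g]
    A <- a * w
    r <- u^2 / A
    denom <- u + A * x
    logq <- log(u) - log(denom)
    logp <- log(A) + log(x) - log(denom)
    llg <- sum(lgamma(Y + r)) - length(Y) * lgamma(r) +
      r * sum(logq) + sum(Y * logp)
    if (includeConstants) llg <- llg - sum(lgamma(Y + 1))
    totg <- sum(Y)
    if (includeAllocation) {
      llg <- llg - totg * log(u)
      if (R) {
        sel <- stats@groupOf == g
        llg <- llg + sum(stats@Yt[sel] *
                           as.vector(Z[sel, , drop = FALSE] %*% gamma))
      }
    }
    if (!is.finite(llg)) stop("non-finite NB log-likelihood (log-Gamma)")
    ll <- ll + llg
    # d ll / d x_j, premultiplied by x_j (chain rule through eta)
    xdll <- -r * A * x / denom + Y * u / denom
    gradBeta[, g] <- designApplyT(design, xdll)
    dlldr <- digamma(Y + r) - digamma(r) + logq
    Sr <- sum(dlldr)
    # alpha (via r and p), then transform to log alpha
    dlla <- Sr * (-r / a) + sum(-r * w * x / denom + Y * u / (a * denom))
    gradLogAlpha[g] <- a * dlla
    if (R) {
      dllu <- Sr * (2 * r / u) +
        sum(r * (1 / u - 1 / denom) - Y / denom)
      dllw <- Sr * (-r / w) +
        sum(-r * a * x / denom + Y * (1 / w - a * x / denom))
      sel <- stats@groupOf == g
      Zg <- Z[sel, , drop = FALSE]
      ezg <- cs$ez[sel]
      dudg <- as.vector(crossprod(Zg, ezg))
      dwdg <- 2 * as.vector(crossprod(Zg, ezg^2))
      gradGamma <- gradGamma + dllu * dudg + dllw * dwdg
      if (includeAllocation)
        gradGamma <- gradGamma +
          as.vector(crossprod(Zg, stats@Yt[sel])) - totg * dudg / u
    }
  }
  pen <- penaltyValueGrad(beta, lambda, J)
  list(value = -ll + pen$value, gradBeta = -gradBeta + pen$grad,
       gradGamma = -gradGamma, gradLogAlpha = -gradLogAlpha)
}

#' Penalised Clustered NB negative log-likelihood and gradient
#'
#' Study-factorised likelihood of the hierarchical model in which each
#' study carries a latent Gamma(1/alpha_g, 1/alpha_g) factor scaling its
#' whole intensity field (marginalised analytically; the latent factor
#' is never stored). This induces within-study covariance
#' \code{alpha_g * mu_ij * mu_ij'} between voxels. Data-only constants
#' (which involve the unavailable per-study per-voxel counts) are
#' omitted.
#'
#' @inheritParams nbNLL
#' @return List with \code{value}, \code{gradBeta}, \code{gradGamma},
#'   \code{gradLogAlpha}.
#' @export
clusteredNbNLL <- function(stats, design, Z, beta, gamma, alpha,
                           lambda = 0, J = design@J) {
  stopifnot(all(alpha > 0))
  G <- length(stats@groups)
  fl <- studyIntensity(design, Z, beta, gamma, stats@groupOf)
  R <- length(gamma)
  ll <- 0
  gradBeta <- matrix(0, nrow(beta), G)
  gradGamma <- numeric(R)
  gradLogAlpha <- numeric(G)
  totX <- colSums(fl$muX)
  for (g in seq_len(G)) {
    sel <- stats@groupOf == g
    Mg <- sum(sel)
    a <- 1 / alpha[g]
    Yt <- stats@Yt[sel]
    muT <- fl$muT[sel]
    Y <- stats@Yg[, g]
    llg <- Mg * a * log(a) - Mg * lgamma(a) + sum(lgamma(Yt + a)) -
      sum((Yt + a) * log(muT + a)) + sum(Y * fl$etaX[, g])
    if (R) llg <- llg + sum(Yt * as.vector(Z[sel, , drop = FALSE] %*% gamma))
    if (!is.finite(llg))
      stop("non-finite Clustered NB log-likelihood (log-Gamma)")
    ll <- ll + llg
    ci <- (Yt + a) / (muT + a)
    ez <- fl$muZ[sel]
    gradBeta[, g] <- designApplyT(design, Y - sum(ci * ez) * fl$muX[, g])
    if (R) {
      Zg <- Z[sel, , drop = FALSE]
      gradGamma <- gradGamma + as.vector(crossprod(Zg, Yt - ci * muT))
    }
    dllda <- Mg * (log(a) + 1) - Mg * digamma(a) + sum(digamma(Yt + a)) -
      sum(log(muT + a)) - sum(ci)
    gradLogAlpha[g] <- -a * dllda
  }
  pen <- penaltyValueGrad(beta, lambda, J)
  list(value = -ll + pen$value, gradBeta = -gradBeta + pen$grad,
       gradGamma = -gradGamma, gradLogAlpha = -gradLogAlpha)
}

# unified dispatch used by the optimiser
familyNLL <- function(family, stats, design, Z, beta, gamma, alpha,
                      lambda, includeConstants = FALSE) {
  switch(family,
    poisson = poissonNLL(stats, design, Z, beta, gamma, lambda,
                         includeConstants = includeConstants),
    nb = nbNLL(stats, design, Z, beta, gamma, alpha, lambda,
               includeConstants = includeConstants),
    clustered_nb = clusteredNbNLL(stats, design, Z, beta, gamma, alpha,
                                  lambda),
    stop("unknown family"))
}
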