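test_that("lambda derivation satisfies the unit-total-variance identity", {
  expect_equal(deriveLambda(0.005, 5227), sqrt(2 / (5227 * 0.005)))
  expect_equal(deriveLambda(0.005, 5227), 0.27664, tolerance = 1e-4)
  expect_equal(deriveLambda(1e-6, 13658151), 0.38269, tolerance = 1e-4)
  for (g in c(0.001, 0.05, 1)) for (m in c(10, 5227)) {
    lam <- deriveLambda(g, m) # defining relation of the rate rule
    expect_equal(m * g * lam^2, 2)
  }
  expect_error(deriveLambda(0, 10))
  expect_error(deriveLambda(0.5, 0))
})

test_that("truncated normal means match closed forms and stay stable", {
  expect_equal(truncatedNormalMean(0, 1, "above_zero"), sqrt(2 / pi))
  expect_equal(truncatedNormalMean(5, 0.01, "above_zero"), 5,
               tolerance = 1e-6)
  # symmetry: E[Z | Z > 0; mu] = -E[Z | Z < 0; -mu]
  for (mu in c(-3, -0.5, 0.2, 4)) {
    expect_equal(truncatedNormalMean(mu, 2, "above_zero"),
                 -truncatedNormalMean(-mu, 2, "below_zero"))
  }
  # deep tail: |mean|/sd = 30; compare against the asymptotic Mills series
  v <- truncatedNormalMean(-30, 1, "above_zero")
  expect_gt(v, 0)
  expect_equal(v, 1 / 30 - 2 / 30^3 + 10 / 30^5, tolerance = 1e-6)
  expect_error(truncatedNormalMean(0, 0), "positive")
})

test_that("posterior mean matches the quadrature oracle", {
  set.seed(14)
  for (i in 1:120) {
    Y <- runif(1, -6, 6)
    s2 <- 10^runif(1, -4, 0.5)
    lam <- 10^runif(1, -1, 1)
    gam <- 10^runif(1, -6, 0)
    a <- posteriorMeanEffect(Y, s2, lam, gam)
    b <- quadPosteriorMean(Y, s2, lam, gam)
    expect_lt(abs(a - b) / max(abs(b), 1e-12), 1e-6)
  }
})

test_that("posterior mean is antisymmetric, shrinking and sign-preserving", {
  expect_equal(posteriorMeanEffect(0, 0.1, 0.3, 0.005), 0)
  Y <- seq(-12, 12, length.out = 201)
  for (gam in c(1e-6, 0.01, 1)) {
    est <- posteriorMeanEffect(Y, 0.04, 0.2766, gam)
    expect_true(all(abs(est) <= abs(Y) + 1e-12))
    expect_true(all(sign(est) * sign(Y) >= 0))
    expect_equal(est, -rev(est), tolerance = 1e-9)
  }
  # gamma -> 0: point mass dominates, estimate collapses to 0
  expect_lt(abs(posteriorMeanEffect(0.3, 0.01, 0.2766, 1e-12)), 1e-6)
})

test_that("effect summary recovers exact least-squares coefficients", {
  set.seed(15)
  x <- rnorm(200)
  # y_{-j} proportional to the column: Y = c exactly
  r <- 3.2 * x - x * 1.0 # residual when current estimate is 1.0
  es <- effectSummary(r, 1.0, x, sigmaE2 = 2)
  expect_equal(es$Y, 3.2)
  expect_equal(es$sigma2, 2 / sum(x^2))
  # residual orthogonal to the column, estimate 0 -> Y = 0
  z <- rnorm(200)
  z <- z - x * sum(x * z) / sum(x^2)
  expect_equal(effectSummary(z, 0, x, 1)$Y, 0, tolerance = 1e-12)
  expect_error(effectSummary(z, 0, numeric(200), 1), "inert")
})

test_that("noise-only phenotypes with near-zero gamma yield a null fit", {
  pop <- smallTestPopulation(seed = 47, nMarkers = 150, ne = 50, gens = 60)
  geno <- genotypes(pop)
  st <- computeMarkerStats(pop)
  blocks <- buildDesignBlocks(geno[, st$retained],
                              markers = which(st$retained))
  set.seed(16)
  y <- rnorm(50)
  fit <- iceFit(y, blocks, "M1", gammaA = 1e-12, gammaD = 1e-12)
  expect_true(converged(fit))
  expect_lte(iterations(fit), 2L) # immediate: sweeps change nothing visible
  expect_true(all(abs(unlist(estimates(fit))) < 1e-8))
  # residual untouched: sigma_e^2 equals Var(y) exactly
  expect_equal(sigmaE2(fit), var(y))
})

test_that("sigma_e^2 is estimated within 5% of Var(y) at zero heritability", {
  set.seed(17)
  n <- 400
  geno <- sapply(runif(80, 0.1, 0.9), function(p) rbinom(n, 2L, p))
  blocks <- buildDesignBlocks(geno)
  ratios <- replicate(8, {
    y <- rnorm(n)
    fit <- iceFit(y, blocks, "M1") # standard gammas
    sigmaE2(fit) / var(y)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("a single large additive QTL is recovered by M0", {
  set.seed(18)
  n <- 500
  geno <- sapply(runif(40, 0.2, 0.8), function(p) rbinom(n, 2L, p))
  blocks <- buildDesignBlocks(geno)
  qtl <- 7
  beta <- 1.5 # on the standardized orthogonal scale
  y <- blocks@Xa[, qtl] * beta + rnorm(n, 0, 0.5)
  fit <- iceFit(y, blocks, "M0", gammaA = 0.025)
  est <- estimates(fit)$a
  postSd <- sqrt(sigmaE2(fit) / sum(blocks@Xa[, qtl]^2))
  expect_lt(abs(est[qtl] - beta), 2 * postSd)
  expect_true(all(abs(est[-qtl]) < 1e-3))
  expect_true(converged(fit))
})

test_that("residual bookkeeping matches a from-scratch recomputation", {
  pop <- smallTestPopulation(seed = 59, nMarkers = 120, ne = 60, gens = 60)
  geno <- genotypes(pop)
  st <- computeMarkerStats(pop)
  keep <- which(st$retained)
  blocks <- buildDesignBlocks(geno[, keep], markers = keep)
  set.seed(19)
  y <- blocks@Xa[, 3] * 1.2 + blocks@Xd[, 10] * 0.6 + rnorm(60, 0, 0.7)
  fit <- iceFit(y, blocks, "M1", gammaA = 0.05, checkEvery = 1L)
  expect_lt(fit@residualCheck, 1e-8)
  pred <- predictDgv(fit, blocks)
  recomputed <- (y - mean(y)) - pred$total
  expect_equal(fit@residual, unname(recomputed), tolerance = 1e-8)
})

test_that("fixed-point consistency: one extra sweep stays converged", {
  pop <- smallTestPopulation(seed = 61, nMarkers = 120, ne = 60, gens = 60)
  geno <- genotypes(pop)
  st <- computeMarkerStats(pop)
  blocks <- buildDesignBlocks(geno[, st$retained],
                              markers = which(st$retained))
  set.seed(20)
  y <- blocks@Xa[, 5] * 1.5 + rnorm(60, 0, 0.8)
  fit <- iceFit(y, blocks, "M1", gammaA = 0.05, L = 1e-8)
  expect_true(converged(fit))
  expect_lte(tail(fit@criterionTrace, 1), 1e-8)
})

test_that("covariate effects are corrected without shrinkage", {
  set.seed(22)
  n <- 400
  geno <- sapply(runif(30, 0.2, 0.8), function(p) rbinom(n, 2L, p))
  blocks <- buildDesignBlocks(geno)
  batch <- rep(c(0, 1), each = n / 2)
  y <- blocks@Xa[, 4] * 1.4 + 5 * batch + rnorm(n, 0, 0.5)
  fitNo <- iceFit(y, blocks, "M0", gammaA = 0.05)
  fitCov <- iceFit(y, blocks, "M0", gammaA = 0.05,
                   covariates = cbind(batch))
  expect_lt(abs(estimates(fitCov)$a[4] - 1.4), 0.15)
  expect_lt(sigmaE2(fitCov), sigmaE2(fitNo)) # batch variance removed
})

test_that("DGV prediction is the design times the estimates", {
  pop <- smallTestPopulation(seed = 67, nMarkers = 80, ne = 40, gens = 50)
  geno <- genotypes(pop)
  st <- computeMarkerStats(pop)
  blocks <- buildDesignBlocks(geno[, st$retained],
                              markers = which(st$retained))
  set.seed(23)
  y <- rnorm(40)
  fit <- iceFit(y, blocks, "M1", gammaA = 1e-12, gammaD = 1e-12)
  expect_equal(unname(predictDgv(fit, blocks)$total), rep(0, 40))
  fit@estimates$a[3] <- 0.7
  pred <- predictDgv(fit, blocks)
  expect_equal(unname(pred$total), blocks@Xa[, 3] * 0.7)
  expect_equal(pred$parts[, "a"], blocks@Xa[, 3] * 0.7,
               ignore_attr = TRUE)
  bad <- buildDesignBlocks(geno[, 1:5])
  expect_error(predictDgv(fit, bad), "mismatch")
})

test_that("M2 estimates planted interactions via streamed columns", {
  set.seed(24)
  n <- 600
  geno <- sapply(runif(25, 0.25, 0.75), function(p) rbinom(n, 2L, p))
  blocks <- buildDesignBlocks(geno)
  col <- interactionColumn(blocks, "aa", 3, 11)
  y <- col * 1.2 + blocks@Xa[, 5] * 0.8 + rnorm(n, 0, 0.4)
  fit <- iceFit(y, blocks, "M2", gammaA = 0.05, gammaEpi = 0.002)
  top <- topInteractions(fit, blocks, 3)
  expect_equal(top$j[1], 3)
  expect_equal(top$k[1], 11)
  expect_equal(top$source[1], "aa")
  expect_lt(abs(top$estimate[1] - 1.2), 0.2)
  # prediction uses the same streamed columns
  pred <- predictDgv(fit, blocks)
  manual <- blocks@Xa[, 5] * estimates(fit)$a[5]
  expect_lt(max(abs(pred$parts[, "aa"] -
                      col * top$estimate[1])), 0.3)
})
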