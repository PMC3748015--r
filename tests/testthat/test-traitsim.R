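# synthetic genotypes at mutually independent loci (linkage equilibrium)
leGenotypes <- function(n, freqs2) {
  sapply(freqs2, function(p) rbinom(n, 2L, p))
}

test_that("main-effect sampling follows the gamma/degree-of-dominance model", {
  set.seed(1)
  eff <- sampleMainEffects(5000, shape = 0.42, rate = 2.619,
                           domMean = 0, domSd = 0)
  expect_true(all(eff$d == 0))  # zero degree of dominance, zero d
  expect_lt(abs(mean(abs(eff$a)) - 0.42 / 2.619), 0.01) # gamma mean a/b
  expect_gt(min(table(sign(eff$a))), 2300)              # symmetric signs
  set.seed(2)
  eff2 <- sampleMainEffects(5000)
  expect_equal(eff2$d, abs(eff2$a) * eff2$degree)
  expect_error(sampleMainEffects(5, shape = -1), "positive")
})

test_that("epistatic pair sampling respects counts, ordering and sources", {
  set.seed(3)
  qtl <- sort(sample(1000, 23))
  pr <- sampleEpistaticPairs(qtl, 6, epistasisParams("23"))
  expect_equal(nrow(pr), 24)
  expect_equal(unname(table(pr$source)[c("aa", "ad", "da", "dd")]),
               rep(6L, 4), ignore_attr = TRUE)
  expect_true(all(pr$j < pr$k))
  expect_true(all(pr$j %in% qtl & pr$k %in% qtl))
  # no duplicated pair within a source
  for (s in unique(pr$source)) {
    d <- pr[pr$source == s, ]
    expect_equal(anyDuplicated(paste(d$j, d$k)), 0)
  }
  expect_equal(nrow(sampleEpistaticPairs(qtl, 0)), 0)
  expect_error(sampleEpistaticPairs(qtl[1:3], 6), "more pairs")
  # effects follow the source's normal distribution
  set.seed(4)
  big <- sampleEpistaticPairs(sort(sample(5000, 230)), 57,
                              epistasisParams("230"))
  dd <- big$effect[big$source == "dd"]
  expect_lt(abs(mean(dd) - 0.02), 4 * sqrt(0.01 / 57))
})

test_that("F-infinity genotypic values follow the product coding", {
  arch <- new("TraitArchitecture", qtl = c(1L, 2L), a = c(1, 0),
              d = c(0.5, 0),
              pairs = data.frame(source = "aa", j = 1L, k = 2L, effect = 2),
              h2 = 0.5, sigmaE2 = NA_real_, class22dose = c(2L, 2L))
  geno <- rbind(c(1L, 0L), c(2L, 2L), c(0L, 2L), c(1L, 1L))
  G <- genotypicValuesFinf(geno, arch)
  # row 1: het at locus 1 -> d = 0.5; aa product 0 * (-1) = 0
  expect_equal(G[1], 0.5)
  # row 2: both frequent homozygotes -> a + (+1)(+1) * 2
  expect_equal(G[2], 1 + 2)
  # row 3: (-1) * (+1) * 2 - 1
  expect_equal(G[3], -1 - 2)
  # row 4: het/het -> d only, aa product 0
  expect_equal(G[4], 0.5)
  archZero <- arch
  archZero@a[] <- 0; archZero@d[] <- 0; archZero@pairs$effect <- 0
  expect_equal(genotypicValuesFinf(geno, archZero), rep(0, 4))
})

test_that("residual variance calibration matches broad-sense heritability", {
  G <- rnorm(2000)
  G <- (G - mean(G)) / sd(G) # Var exactly 1
  expect_equal(calibrateResidualVariance(G, 0.5), 1)
  expect_equal(calibrateResidualVariance(G, 0.1), 9)
  expect_error(calibrateResidualVariance(rep(1, 10), 0.5), "monomorphic")
  expect_error(calibrateResidualVariance(G, 1.2), "H2")
  set.seed(5)
  y <- simulatePhenotypes(G, calibrateResidualVariance(G, 0.5))
  expect_lt(abs(var(y) - var(G) / 0.5), 0.2)
  expect_equal(simulatePhenotypes(G, 0), G)
})

test_that("single-locus translation is exact and matches a weighted oracle", {
  # HWE p = 0.5, no dominance: g_d = 0 and g_a proportional to a
  tr <- translateSingleLocus(0, 1.3, 0, c(0.25, 0.5, 0.25))
  expect_equal(tr$gd, 0, tolerance = 1e-12)
  expect_equal(tr$ga, 1.3, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:25) {
    f <- as.vector(randomFreqTriples(1, seed = i))
    a <- rnorm(1); d <- rnorm(1); mu <- rnorm(1)
    tr <- translateSingleLocus(mu, a, d, f)
    SA <- sAMatrix(f[1], f[2], f[3])
    # representation equivalence: identical genotypic values, exactly
    G1 <- epibayes:::.finfS %*% c(mu, a, d)
    G2 <- SA %*% c(tr$muStar, tr$ga, tr$gd)
    expect_equal(as.vector(G2), as.vector(G1), tolerance = 1e-10)
    # weighted-regression oracle: project genotypic values onto the
    # orthogonal columns under the genotype-frequency weights
    fit <- lm.wfit(SA, as.vector(G1), w = f)
    expect_equal(unname(fit$coefficients),
                 c(tr$muStar, tr$ga, tr$gd), tolerance = 1e-8)
  }
  expect_error(translateSingleLocus(0, 1, 0, c(1, 0, 0)), "degenerate")
})

test_that("pairwise translation is an exact change of basis", {
  z <- translatePairwise(numeric(9), c(0.3, 0.5, 0.2), c(0.2, 0.4, 0.4))
  expect_equal(unname(z$raw), numeric(9))
  # pure aa at HWE p = q = 0.5: no ad/da/dd leakage by symmetry
  hw <- c(0.25, 0.5, 0.25)
  alpha <- numeric(9); alpha[5] <- 1.7
  tr <- translatePairwise(alpha, hw, hw)
  expect_equal(unname(tr$raw[c("ad", "da", "dd")]), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(tr$raw["aa"]), 1.7, tolerance = 1e-12)
  # arbitrary inputs: identical 3x3 genotypic-value tables
  set.seed(7)
  for (i in 1:20) {
    fj <- as.vector(randomFreqTriples(1, seed = 100 + i))
    fk <- as.vector(randomFreqTriples(1, seed = 200 + i))
    alpha <- rnorm(9)
    tr <- translatePairwise(alpha, fj, fk)
    S2 <- kronecker(epibayes:::.finfS, epibayes:::.finfS)
    SA2 <- kronecker(sAMatrix(fk[1], fk[2], fk[3]),
                     sAMatrix(fj[1], fj[2], fj[3]))
    expect_equal(as.vector(SA2 %*% tr$raw), as.vector(S2 %*% alpha),
                 tolerance = 1e-9)
  }
})

test_that("marginal main effects reduce to the single-locus translation", {
  set.seed(8)
  geno <- leGenotypes(600, c(0.3, 0.6, 0.45))
  arch <- new("TraitArchitecture", qtl = 1:3, a = c(0.8, -0.3, 0.2),
              d = c(0.1, 0.05, -0.2),
              pairs = data.frame(source = character(), j = integer(),
                                 k = integer(), effect = numeric()),
              h2 = 0.5, sigmaE2 = NA_real_, class22dose = rep(2L, 3))
  truth <- orthogonalTruth(arch, geno)
  f <- epibayes:::.classFreqsOriented(geno, arch@class22dose)
  for (q in 1:3) {
    tr <- translateSingleLocus(0, arch@a[q], arch@d[q], f[, q])
    expect_equal(truth$gaStd[q], tr$gaStd)
    expect_equal(truth$gdStd[q], tr$gdStd)
  }
})

test_that("an aa pair at symmetric HWE frequencies has no additive marginal", {
  # two independent loci, both with class frequencies (1/4, 1/2, 1/4)
  geno <- cbind(rep(c(0L, 1L, 1L, 2L), each = 4), rep(c(0L, 1L, 1L, 2L), 4))
  arch <- new("TraitArchitecture", qtl = 1:2, a = c(0, 0), d = c(0, 0),
              pairs = data.frame(source = "aa", j = 1L, k = 2L, effect = 1),
              h2 = 0.5, sigmaE2 = NA_real_, class22dose = c(2L, 2L))
  truth <- orthogonalTruth(arch, geno)
  # brute-force expectation over the 9 genotype classes: E[X_j X_k | X_j]
  # is 0 at p = 0.5, so the interaction leaves no additive marginal
  expect_equal(truth$gaStd, c(0, 0), tolerance = 1e-12)
  # standardized aa effect = raw (1) times sdA_j * sdA_k = 1/2, squared 1/4
  expect_equal(unname(truth$components["aa"]), 0.25, tolerance = 1e-12)
})

test_that("component bookkeeping is exact under the product measure", {
  # population enumerating all 9 two-locus classes with product weights:
  # the orthogonal basis is exactly orthogonal, so Var(G) equals the sum
  # of squared standardized effects with no tolerance beyond roundoff
  w1 <- c(0.2, 0.5, 0.3); w2 <- c(0.4, 0.35, 0.25)
  n1 <- round(w1 * 400); n2 <- round(w2 * 400)
  geno <- cbind(rep(rep(0:2, n1), times = 400),
                rep(rep(0:2, n2), each = 400))
  arch <- new("TraitArchitecture", qtl = 1:2, a = c(0.7, -0.4),
              d = c(0.3, 0.2),
              pairs = data.frame(source = c("aa", "ad", "da", "dd"),
                                 j = 1L, k = 2L,
                                 effect = c(0.9, -0.5, 0.35, 0.6)),
              h2 = 0.5, sigmaE2 = NA_real_, class22dose = c(2L, 0L))
  G <- genotypicValuesFinf(geno, arch)
  truth <- orthogonalTruth(arch, geno)
  vG <- mean(G^2) - mean(G)^2
  expect_equal(sum(truth$components), vG, tolerance = 1e-12)
  expect_equal(genotypicValuesOrthogonal(geno, arch), G,
               tolerance = 1e-12)
})

test_that("true components sum to Var(G) under linkage equilibrium", {
  # sampled LE panel: agreement up to Monte Carlo cross-locus covariance
  set.seed(9)
  freqs <- runif(23, 0.1, 0.9)
  geno <- leGenotypes(6000, freqs)
  st <- data.frame(maf = pmin(freqs, 1 - freqs),
                   class22dose = ifelse(freqs >= 0.5, 2L, 0L))
  set.seed(10)
  qtl <- 1:23
  eff <- sampleMainEffects(23)
  pairs <- sampleEpistaticPairs(qtl, 6, epistasisParams("23"))
  arch <- new("TraitArchitecture", qtl = qtl, a = eff$a, d = eff$d,
              pairs = pairs, h2 = 0.5, sigmaE2 = NA_real_,
              class22dose = st$class22dose)
  truth <- orthogonalTruth(arch, geno)
  G <- genotypicValuesFinf(geno, arch)
  expect_lt(abs(sum(truth$components) - var(G)) / var(G), 0.12)
})

test_that("genotypic values agree between parameterisations for full architectures", {
  pop <- smallTestPopulation(seed = 41, nMarkers = 200, ne = 60, gens = 80)
  st <- computeMarkerStats(pop, mafThreshold = 0.02)
  geno <- genotypes(pop)
  set.seed(11)
  for (i in 1:5) {
    arch <- sampleArchitecture(st, 10, "23", epistasis = TRUE, h2 = 0.5,
                               nPairsPerSource = 3)
    G1 <- genotypicValuesFinf(geno, arch)
    G2 <- genotypicValuesOrthogonal(geno, arch)
    expect_lt(max(abs(G1 - G2)) / max(abs(G1)), 1e-8)
  }
})

test_that("architecture sampling respects the MAF floor and orientation", {
  pop <- smallTestPopulation(seed = 43, nMarkers = 300, ne = 60, gens = 80)
  st <- computeMarkerStats(pop, mafThreshold = 0.02)
  set.seed(12)
  arch <- sampleArchitecture(st, 15, "23", epistasis = FALSE, h2 = 0.3)
  expect_true(all(st$maf[arch@qtl] > 0.02))
  expect_equal(arch@class22dose, st$class22dose[arch@qtl])
  expect_true(validObject(arch))
  expect_error(sampleArchitecture(st, 1e5, "23"), "not enough")
})
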