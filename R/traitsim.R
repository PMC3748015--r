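#' Epistatic effect distribution parameters
#'
#' Mean and variance of the normal distributions used to draw epistatic
#' effects per source, for the 23-QTL and 230-QTL scenarios. Chosen so that
#' epistasis explains roughly a quarter of the total genetic variance.
#'
#' @param scenario "23" or "230".
#' @return data.frame with columns `source`, `mean`, `var`.
#' @export
epistasisParams <- function(scenario = c("23", "230")) {
  scenario <- match.arg(scenario)
  if (scenario == "23")
    data.frame(source = c("aa", "ad", "da", "dd"), mean = 0.2,
               var = c(0.3, 0.3, 0.2, 0.1))
  else
    data.frame(source = c("aa", "ad", "da", "dd"), mean = 0.02,
               var = c(0.03, 0.03, 0.02, 0.01))
}

#' Sample main QTL effects
#'
#' Allele substitution effect magnitudes are gamma distributed (shape
#' `shape`, rate `rate`) with random sign; the dominance effect is the
#' product of the absolute substitution effect and a normally distributed
#' degree of dominance.
#'
#' @param nQtl number of QTL.
#' @param shape,rate gamma parameters of `|a|` (rate parameterisation; the
#'   23-QTL default is rate 2.619, the 230-QTL scenario uses 8.282).
#' @param domMean,domSd normal parameters of the degree of dominance.
#' @return list with numeric vectors `a`, `d` and `degree`.
#' @export
sampleMainEffects <- function(nQtl, shape = 0.42, rate = 2.619,
                              domMean = 0.193, domSd = 0.312) {
  if (shape <= 0 || rate <= 0) stop("gamma parameters must be positive")
  a <- rgamma(nQtl, shape = shape, rate = rate) *
    sample(c(-1, 1), nQtl, replace = TRUE)
  degree <- rnorm(nQtl, domMean, domSd)
  list(a = a, d = abs(a) * degree, degree = degree)
}

#' Sample epistatic pairs and effects
#'
#' For each source, draws `nPairsPerSource` distinct unordered QTL pairs
#' (without replacement within the source; sources are sampled
#' independently, so a pair may recur across sources) and assigns each an
#' effect from the source's normal distribution.
#'
#' @param qtl integer marker indices of the QTL.
#' @param nPairsPerSource pairs per source (6 in the 23-QTL scenario, 57 in
#'   the 230-QTL scenario).
#' @param params data.frame as returned by [epistasisParams()].
#' @return data.frame with columns `source`, `j`, `k` (marker indices,
#'   `j < k`) and `effect`.
#' @export
sampleEpistaticPairs <- function(qtl, nPairsPerSource = 6,
                                 params = epistasisParams("23")) {
  nq <- length(qtl)
  total <- choose(nq, 2)
  if (nPairsPerSource > total)
    stop("requested more pairs than exist among the QTL")
  if (nPairsPerSource == 0)
    return(data.frame(source = character(), j = integer(), k = integer(),
                      effect = numeric()))
  cmb <- utils::combn(nq, 2)
  out <- lapply(seq_len(nrow(params)), function(s) {
    sel <- sample.int(total, nPairsPerSource)
    j <- pmin(qtl[cmb[1, sel]], qtl[cmb[2, sel]])
    k <- pmax(qtl[cmb[1, sel]], qtl[cmb[2, sel]])
    data.frame(source = params$source[s], j = j, k = k,
               effect = rnorm(nPairsPerSource, params$mean[s],
                              sqrt(params$var[s])))
  })
  do.call(rbind, out)
}

#' Sample a complete trait architecture
#'
#' QTL are drawn from markers with minor allele frequency above `mafMin`
#' in the supplied marker statistics (typically the base generation); main
#' effects and, optionally, epistatic pair effects are sampled with the
#' scenario's distribution parameters. The per-QTL orientation (which
#' homozygote is class 22) is frozen from the supplied statistics.
#'
#' @param stats marker statistics from [computeMarkerStats()].
#' @param nQtl number of QTL (23 or 230 in the standard scenarios).
#' @param scenario "23" or "230"; sets the gamma rate and epistatic
#'   parameters.
#' @param epistasis simulate epistatic effects?
#' @param h2 broad-sense heritability for later residual calibration.
#' @param mafMin MAF threshold for QTL eligibility.
#' @param nPairsPerSource pairs per epistatic source; default 6 ("23") or
#'   57 ("230").
#' @return A [TraitArchitecture-class] (residual variance not yet
#'   calibrated).
#' @export
sampleArchitecture <- function(stats, nQtl = 23L, scenario = c("23", "230"),
                               epistasis = FALSE, h2 = 0.5, mafMin = 0.02,
                               nPairsPerSource = NULL) {
  scenario <- match.arg(scenario)
  rate <- if (scenario == "23") 2.619 else 8.282
  if (is.null(nPairsPerSource))
    nPairsPerSource <- if (scenario == "23") 6L else 57L
  cand <- which(stats$maf > mafMin)
  if (length(cand) < nQtl) stop("not enough polymorphic markers for the QTL")
  qtl <- sort(sample(cand, nQtl))
  eff <- sampleMainEffects(nQtl, rate = rate)
  pairs <- if (epistasis)
    sampleEpistaticPairs(qtl, nPairsPerSource, epistasisParams(scenario))
  else
    data.frame(source = character(), j = integer(), k = integer(),
               effect = numeric())
  new("TraitArchitecture", qtl = as.integer(qtl), a = eff$a, d = eff$d,
      pairs = pairs, h2 = h2, sigmaE2 = NA_real_,
      class22dose = as.integer(stats$class22dose[qtl]))
}

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(
    "TraitArchitecture: %d QTL, %d epistatic pair effects, H2 = %.2f, sigmaE2 = %s\n",
    length(object@qtl), nrow(object@pairs), object@h2,
    if (is.na(object@sigmaE2)) "uncalibrated" else sprintf("%.4f", object@sigmaE2)))
})

#' Total genotypic values on the F-infinity scale
#'
#' `G_i = sum_j X_ij a_j + D_ij d_j` plus, for each epistatic pair, the
#' product-coded contribution (aa: `X_j X_k`, ad: `X_j D_k`, da: `D_j X_k`,
#' dd: `D_j D_k`) times its effect. The positive additive coefficient is
#' carried by the more frequent allele per the architecture's orientation.
#'
#' @param geno dosage matrix (individuals x panel markers).
#' @param arch a [TraitArchitecture-class].
#' @return Numeric vector of genotypic values.
#' @export
genotypicValuesFinf <- function(geno, arch) {
  if (length(arch@qtl) && max(arch@qtl) > ncol(geno))
    stop("architecture indices outside the genotype panel")
  fd <- finfDesign(geno[, arch@qtl, drop = FALSE], arch@class22dose)
  G <- as.vector(fd$X %*% arch@a + fd$D %*% arch@d)
  if (nrow(arch@pairs)) {
    pj <- match(arch@pairs$j, arch@qtl)
    pk <- match(arch@pairs$k, arch@qtl)
    for (r in seq_len(nrow(arch@pairs))) {
      src <- arch@pairs$source[r]
      left <- if (substr(src, 1, 1) == "a") fd$X[, pj[r]] else fd$D[, pj[r]]
      right <- if (substr(src, 2, 2) == "a") fd$X[, pk[r]] else fd$D[, pk[r]]
      G <- G + left * right * arch@pairs$effect[r]
    }
  }
  G
}

#' Calibrate the residual variance from broad-sense heritability
#'
#' `sigma_e^2 = Var(G) * (1 - H2) / H2`, with `Var(G)` the empirical
#' variance of total genotypic values among the training individuals
#' (including the epistatic part when simulated).
#'
#' @param G genotypic values of the training individuals.
#' @param h2 broad-sense heritability in (0, 1).
#' @return Residual variance (scalar).
#' @export
calibrateResidualVariance <- function(G, h2) {
  if (h2 <= 0 || h2 >= 1) stop("H2 must lie in (0, 1)")
  vg <- var(G)
  if (!is.finite(vg) || vg <= 0) stop("monomorphic trait: Var(G) is zero")
  vg * (1 - h2) / h2
}

#' Simulate phenotypes
#'
#' Adds iid normal residuals with variance `sigmaE2` to genotypic values.
#'
#' @param G genotypic values.
#' @param sigmaE2 residual variance (>= 0).
#' @return Numeric phenotype vector.
#' @export
simulatePhenotypes <- function(G, sigmaE2) {
  if (sigmaE2 < 0) stop("sigmaE2 must be non-negative")
  G + rnorm(length(G), 0, sqrt(sigmaE2))
}

#' Translate single-locus effects to the orthogonal scale
#'
#' Solves the representation equivalence of the genotypic values: the
#' F-infinity effects `(mu, a, d)` are mapped through the locus's
#' genotypic-value table to `(mu*, g_a, g_d)` on the orthogonal scale;
#' the standardized effects absorb the column standard deviations so that
#' standardized columns times standardized effects reproduce the same
#' genotypic values.
#'
#' @param mu population mean (0 in simulation).
#' @param a,d allele substitution and dominance effects of the locus.
#' @param freqs genotype class frequencies `c(p11, p12, p22)`.
#' @return list with `muStar`, `ga`, `gd`, `gaStd`, `gdStd` and the locus
#'   coding row.
#' @export
translateSingleLocus <- function(mu, a, d, freqs) {
  cod <- orthogonalCoding(freqs[1], freqs[2], freqs[3])
  if (cod$v <= 1e-12) stop("degenerate genotype frequencies (v = 0)")
  SA <- sAMatrix(freqs[1], freqs[2], freqs[3])
  sol <- solve(SA, .finfS %*% c(mu, a, d))
  list(muStar = sol[1], ga = sol[2], gd = sol[3],
       gaStd = sol[2] * cod$sdA, gdStd = sol[3] * cod$sdD, coding = cod)
}

#' Translate a pairwise effect vector to the orthogonal scale
#'
#' Applies the Kronecker change of basis to the 9-vector of F-infinity
#' effects of a locus pair, ordered
#' `(mu, a_j, d_j, a_k, aa, da, d_k, ad, dd)`; the standardized epistatic
#' entries are additionally multiplied by the product of the two parent
#' column standard deviations.
#'
#' @param alpha9 the F-infinity effect 9-vector in the order above.
#' @param freqsJ,freqsK genotype class frequencies of loci `j` and `k`.
#' @return list with the transformed vector `raw` (same ordering), the
#'   standardized epistatic effects `epiStd` (named aa, ad, da, dd), and the
#'   main-effect components `mainsJ` = (g_a,j, g_d,j),
#'   `mainsK` = (g_a,k, g_d,k) (unstandardized).
#' @export
translatePairwise <- function(alpha9, freqsJ, freqsK) {
  codJ <- orthogonalCoding(freqsJ[1], freqsJ[2], freqsJ[3])
  codK <- orthogonalCoding(freqsK[1], freqsK[2], freqsK[3])
  if (codJ$v <= 1e-12 || codK$v <= 1e-12)
    stop("degenerate genotype frequencies (v = 0)")
  SAj <- sAMatrix(freqsJ[1], freqsJ[2], freqsJ[3])
  SAk <- sAMatrix(freqsK[1], freqsK[2], freqsK[3])
  M <- kronecker(solve(SAk), solve(SAj)) %*% kronecker(.finfS, .finfS)
  raw <- as.vector(M %*% alpha9)
  names(raw) <- c("mu", "aJ", "dJ", "aK", "aa", "da", "dK", "ad", "dd")
  epiStd <- c(aa = raw[["aa"]] * codJ$sdA * codK$sdA,
              ad = raw[["ad"]] * codJ$sdA * codK$sdD,
              da = raw[["da"]] * codJ$sdD * codK$sdA,
              dd = raw[["dd"]] * codJ$sdD * codK$sdD)
  list(raw = raw, epiStd = epiStd,
       mainsJ = c(raw[["aJ"]], raw[["dJ"]]),
       mainsK = c(raw[["aK"]], raw[["dK"]]))
}

# class frequencies at the architecture's QTL in trait orientation
.classFreqsOriented <- function(geno, class22dose) {
  n <- nrow(geno)
  n0 <- colSums(geno == 0L)
  n1 <- colSums(geno == 1L)
  n2 <- n - n0 - n1
  p22 <- ifelse(class22dose == 2L, n2, n0) / n
  p11 <- ifelse(class22dose == 2L, n0, n2) / n
  rbind(p11 = p11, p12 = n1 / n, p22 = p22)
}

#' True effects and variance components on the orthogonal scale
#'
#' Translates the architecture's F-infinity effects into standardized
#' orthogonal effects using the genotype class frequencies of the supplied
#' (training) individuals, in the architecture's orientation. Main effects
#' are marginal: each locus's single-locus translation plus the summed
#' main-effect components of the pairwise transforms of every interaction
#' involving the locus (with main effects zeroed). Per-source true variance
#' components are the sums of squared standardized effects (a linkage
#' equilibrium approximation across loci).
#'
#' QTL that are monomorphic among the supplied individuals contribute no
#' variance; their standardized effects are set to zero.
#'
#' @param arch a [TraitArchitecture-class].
#' @param geno dosage matrix over the same panel the architecture indexes
#'   (typically the training individuals).
#' @return list with `gaStd`, `gdStd` (per QTL), `pairs` (data.frame with
#'   `source`, `j`, `k`, `effectStd`), `components` (named numeric:
#'   a, d, aa, ad, da, dd), `freqs` (oriented class-frequency matrix) and
#'   `qtl`.
#' @export
orthogonalTruth <- function(arch, geno) {
  nq <- length(arch@qtl)
  freqs <- .classFreqsOriented(geno[, arch@qtl, drop = FALSE],
                               arch@class22dose)
  cod <- orthogonalCoding(freqs[1, ], freqs[2, ], freqs[3, ])
  ga <- numeric(nq); gd <- numeric(nq)
  for (q in seq_len(nq)) {
    if (cod$inertA[q] && cod$inertD[q]) next
    sol <- translateSingleLocus(0, arch@a[q], arch@d[q], freqs[, q])
    ga[q] <- sol$ga; gd[q] <- sol$gd
  }
  pairsStd <- data.frame(source = character(), j = integer(), k = integer(),
                         effectStd = numeric())
  if (nrow(arch@pairs)) {
    key <- paste(arch@pairs$j, arch@pairs$k)
    rows <- list()
    for (pk in unique(key)) {
      sel <- arch@pairs[key == pk, , drop = FALSE]
      qJ <- match(sel$j[1], arch@qtl); qK <- match(sel$k[1], arch@qtl)
      if ((cod$inertA[qJ] && cod$inertD[qJ]) ||
          (cod$inertA[qK] && cod$inertD[qK])) {
        rows[[pk]] <- data.frame(source = sel$source, j = sel$j, k = sel$k,
                                 effectStd = 0)
        next
      }
      alpha <- numeric(9)
      pos <- c(aa = 5L, da = 6L, ad = 8L, dd = 9L)
      for (r in seq_len(nrow(sel)))
        alpha[pos[[sel$source[r]]]] <-
          alpha[pos[[sel$source[r]]]] + sel$effect[r]
      tr <- translatePairwise(alpha, freqs[, qJ], freqs[, qK])
      ga[qJ] <- ga[qJ] + tr$mainsJ[1]; gd[qJ] <- gd[qJ] + tr$mainsJ[2]
      ga[qK] <- ga[qK] + tr$mainsK[1]; gd[qK] <- gd[qK] + tr$mainsK[2]
      rows[[pk]] <- data.frame(source = sel$source, j = sel$j, k = sel$k,
                               effectStd = tr$epiStd[sel$source])
    }
    pairsStd <- do.call(rbind, rows)
    rownames(pairsStd) <- NULL
  }
  gaStd <- ga * cod$sdA
  gdStd <- gd * cod$sdD
  comp <- setNames(numeric(6), .sourceNames)
  comp["a"] <- sum(gaStd^2)
  comp["d"] <- sum(gdStd^2)
  for (s in c("aa", "ad", "da", "dd"))
    comp[s] <- sum(pairsStd$effectStd[pairsStd$source == s]^2)
  list(gaStd = gaStd, gdStd = gdStd, pairs = pairsStd, components = comp,
       freqs = freqs, qtl = arch@qtl, coding = cod,
       class22dose = arch@class22dose)
}

#' True additive genetic values
#'
#' Standardized orthogonal additive covariates (built from the truth's
#' coding) times the true marginal additive effects — the breeding-value
#' part of the genotypic value.
#'
#' @param truth result of [orthogonalTruth()].
#' @param geno dosage matrix of the target individuals over the same panel.
#' @return Numeric vector of true additive values.
#' @export
trueAdditiveValues <- function(truth, geno) {
  g <- geno[, truth$qtl, drop = FALSE]
  cod <- truth$coding
  val <- numeric(nrow(g))
  for (q in seq_along(truth$qtl)) {
    if (truth$gaStd[q] == 0 || cod$inertA[q]) next
    flip <- truth$class22dose[q] == 0L
    wa <- c(cod$wa11[q], cod$wa12[q], cod$wa22[q]) / cod$sdA[q]
    dose <- g[, q] + 1L
    if (flip) wa <- rev(wa)
    val <- val + wa[dose] * truth$gaStd[q]
  }
  val
}

#' Genotypic values reconstructed from orthogonal effects
#'
#' Reconstructs every individual's genotypic value from the translated
#' orthogonal effects (single-locus terms plus full 9-term pair expansions
#' of the epistatic effects). Up to numerical tolerance this equals
#' [genotypicValuesFinf()] — the representation equivalence of the two
#' parameterisations.
#'
#' @param geno dosage matrix.
#' @param arch a [TraitArchitecture-class].
#' @param freqGeno dosage matrix defining the genotype class frequencies of
#'   the translation (defaults to `geno`).
#' @return Numeric vector of genotypic values.
#' @export
genotypicValuesOrthogonal <- function(geno, arch, freqGeno = geno) {
  nq <- length(arch@qtl)
  freqs <- .classFreqsOriented(freqGeno[, arch@qtl, drop = FALSE],
                               arch@class22dose)
  g <- geno[, arch@qtl, drop = FALSE]
  G <- numeric(nrow(g))
  basis <- vector("list", nq) # per locus: n x 3 matrix (1, wa, wd)
  for (q in seq_len(nq)) {
    cod <- orthogonalCoding(freqs[1, q], freqs[2, q], freqs[3, q])
    wa <- c(cod$wa11, cod$wa12, cod$wa22)
    wd <- c(cod$wd11, cod$wd12, cod$wd22)
    if (arch@class22dose[q] == 0L) { wa <- rev(wa); wd <- rev(wd) }
    dose <- g[, q] + 1L
    basis[[q]] <- cbind(1, wa[dose], wd[dose])
    sol <- translateSingleLocus(0, arch@a[q], arch@d[q], freqs[, q])
    G <- G + sol$muStar + basis[[q]][, 2] * sol$ga + basis[[q]][, 3] * sol$gd
  }
  if (nrow(arch@pairs)) {
    key <- paste(arch@pairs$j, arch@pairs$k)
    for (pk in unique(key)) {
      sel <- arch@pairs[key == pk, , drop = FALSE]
      qJ <- match(sel$j[1], arch@qtl); qK <- match(sel$k[1], arch@qtl)
      alpha <- numeric(9)
      pos <- c(aa = 5L, da = 6L, ad = 8L, dd = 9L)
      for (r in seq_len(nrow(sel)))
        alpha[pos[[sel$source[r]]]] <-
          alpha[pos[[sel$source[r]]]] + sel$effect[r]
      tr <- translatePairwise(alpha, freqs[, qJ], freqs[, qK])
      bj <- basis[[qJ]]; bk <- basis[[qK]]
      # raw is ordered as (term_k x term_j) with per-locus order (1, a, d)
      for (ck in 1:3) for (cj in 1:3) {
        val <- tr$raw[(ck - 1L) * 3L + cj]
        if (val != 0) G <- G + bj[, cj] * bk[, ck] * val
      }
    }
  }
  G
}
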