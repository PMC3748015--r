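#' F-infinity genotype coding
#'
#' Codes genotypes as `X = -1, 0, 1` (homozygote, heterozygote, homozygote)
#' with a separate heterozygote indicator `D`; the positive additive
#' coefficient is assigned to the more frequent allele, i.e. to genotype
#' class 22.
#'
#' @param geno integer dosage matrix (individuals x markers, values 0/1/2).
#' @param class22dose integer per marker: which dosage (0 or 2) is genotype
#'   class 22.
#' @return list with matrices `X` (-1/0/1) and `D` (0/1).
#' @export
finfDesign <- function(geno, class22dose = rep(2L, ncol(geno))) {
  if (any(geno < 0L | geno > 2L)) stop("genotype dosages must be 0, 1 or 2")
  sgn <- matrix(rep(ifelse(class22dose == 2L, 1, -1), each = nrow(geno)),
                nrow(geno), ncol(geno))
  X <- (geno - 1) * sgn
  D <- (geno == 1L) * 1
  list(X = X, D = D)
}

#' NOIA orthogonal coding of one or more loci
#'
#' Computes the additive and dominance covariate coefficients per genotype
#' class (11, 12, 22) from genotype class frequencies, following the
#' natural-and-orthogonal-interactions (statistical scale) decomposition.
#' The additive coefficient is the centered allele count; the dominance
#' coefficients are `(-2*p12*p22, 4*p11*p22, -2*p11*p12) / v` with
#' `v = p11 + p22 - (p11 - p22)^2`. Under the given class frequencies both
#' columns have zero mean and zero cross-moment; dividing by the returned
#' standard deviations `sdA`, `sdD` yields unit frequency-weighted variance.
#'
#' @param p11,p12,p22 genotype class frequencies (vectors of equal length,
#'   each triple summing to 1; class 22 is the more frequent homozygote).
#' @return data.frame with coefficients `wa11, wa12, wa22`,
#'   `wd11, wd12, wd22`, the denominator `v`, standard deviations
#'   `sdA, sdD`, and inert flags (zero-variance columns).
#' @examples
#' orthogonalCoding(0.25, 0.5, 0.25) # additive (-1, 0, 1), dominance -/+0.5
#' @export
orthogonalCoding <- function(p11, p12, p22) {
  if (any(abs(p11 + p12 + p22 - 1) > 1e-8))
    stop("genotype class frequencies must sum to 1")
  v <- p11 + p22 - (p11 - p22)^2
  wa11 <- -p12 - 2 * p22
  wa12 <- 1 - p12 - 2 * p22
  wa22 <- 2 - p12 - 2 * p22
  ok <- v > 1e-12
  vsafe <- ifelse(ok, v, 1)
  wd11 <- ifelse(ok, -2 * p12 * p22 / vsafe, 0)
  wd12 <- ifelse(ok, 4 * p11 * p22 / vsafe, 0)
  wd22 <- ifelse(ok, -2 * p11 * p12 / vsafe, 0)
  sdA <- sqrt(pmax(p11 * wa11^2 + p12 * wa12^2 + p22 * wa22^2, 0))
  sdD <- sqrt(pmax(p11 * wd11^2 + p12 * wd12^2 + p22 * wd22^2, 0))
  tol <- 1e-10
  data.frame(wa11 = wa11, wa12 = wa12, wa22 = wa22,
             wd11 = wd11, wd12 = wd12, wd22 = wd22, v = v,
             sdA = sdA, sdD = sdD,
             inertA = !ok | sdA <= tol, inertD = !ok | sdD <= tol)
}

#' Genotypic-value design matrix of a single locus
#'
#' The 3 x 3 matrix mapping `(mu, g_a, g_d)` on the orthogonal scale to the
#' genotypic values of classes (11, 12, 22); its second and third columns
#' are the NOIA additive and dominance coefficients.
#'
#' @param p11,p12,p22 genotype class frequencies of the locus.
#' @return 3 x 3 numeric matrix.
#' @export
sAMatrix <- function(p11, p12, p22) {
  cod <- orthogonalCoding(p11, p12, p22)
  matrix(c(1, 1, 1,
           cod$wa11, cod$wa12, cod$wa22,
           cod$wd11, cod$wd12, cod$wd22), 3, 3)
}

# F-infinity design of a single locus: G = S %*% c(mu, a, d)
.finfS <- matrix(c(1, 1, 1, -1, 0, 1, 0, 1, 0), 3, 3)

#' Build orthogonal standardized design blocks
#'
#' Derives the NOIA coding from the genotype class frequencies of the given
#' (training) genotypes, orients each marker so that class 22 is the more
#' frequent homozygote, builds the additive and dominance covariate
#' matrices, and (by default) standardizes each column by its own
#' frequency-weighted standard deviation so every retained column has unit
#' variance. Markers whose additive or dominance column has zero variance
#' (e.g. no heterozygotes in training) are flagged inert; their effects stay
#' pinned at 0 rather than being dropped, keeping index stability.
#'
#' @param geno integer dosage matrix (individuals x markers) of the
#'   individuals defining the coding (training set).
#' @param markers original panel indices of the columns (bookkeeping only).
#' @param standardize divide columns by their sd (default `TRUE`).
#' @return A [DesignBlocks-class].
#' @export
buildDesignBlocks <- function(geno, markers = seq_len(ncol(geno)),
                              standardize = TRUE) {
  if (anyNA(geno)) stop("missing genotypes are not supported")
  stats <- .genoClassFreqs(geno)
  cod <- orthogonalCoding(stats$p11, stats$p12, stats$p22)
  coding <- cbind(stats, cod)
  blocks <- .codeBlocks(geno, coding, markers,
                        ids = rownames(geno) %||% as.character(seq_len(nrow(geno))))
  if (standardize) blocks <- standardizeBlocks(blocks)
  blocks
}

.genoClassFreqs <- function(geno) {
  n <- nrow(geno)
  n0 <- colSums(geno == 0L)
  n1 <- colSums(geno == 1L)
  n2 <- n - n0 - n1
  p <- (n1 + 2 * n2) / (2 * n)
  class22dose <- ifelse(p >= 0.5, 2L, 0L)
  p22 <- ifelse(class22dose == 2L, n2, n0) / n
  p11 <- ifelse(class22dose == 2L, n0, n2) / n
  data.frame(p11 = p11, p12 = n1 / n, p22 = p22, class22dose = class22dose)
}

# build Xa/Xd from a coding table (coding may come from different
# individuals than geno: prediction uses the training coding unchanged)
.codeBlocks <- function(geno, coding, markers, ids) {
  n <- nrow(geno); m <- ncol(geno)
  flip <- coding$class22dose == 0L
  # per-marker coefficient by dosage class 0/1/2
  coefA <- rbind(ifelse(flip, coding$wa22, coding$wa11),
                 coding$wa12,
                 ifelse(flip, coding$wa11, coding$wa22))
  coefD <- rbind(ifelse(flip, coding$wd22, coding$wd11),
                 coding$wd12,
                 ifelse(flip, coding$wd11, coding$wd22))
  lin <- as.vector(geno) + 1L + 3L * rep(0:(m - 1L), each = n)
  Xa <- matrix(coefA[lin], n, m)
  Xd <- matrix(coefD[lin], n, m)
  Xa[, coding$inertA] <- 0
  Xd[, coding$inertD] <- 0
  new("DesignBlocks", Xa = Xa, Xd = Xd, coding = coding,
      markers = as.integer(markers), ids = ids, standardized = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize design block columns
#'
#' Divides each additive and dominance column by its own frequency-weighted
#' standard deviation (from the coding's genotype class frequencies), after
#' which every non-inert column has frequency-weighted variance exactly 1.
#'
#' @param blocks a [DesignBlocks-class].
#' @return The standardized [DesignBlocks-class].
#' @export
standardizeBlocks <- function(blocks) {
  if (blocks@standardized) return(blocks)
  cod <- blocks@coding
  da <- ifelse(cod$inertA, 1, cod$sdA)
  dd <- ifelse(cod$inertD, 1, cod$sdD)
  blocks@Xa <- sweep(blocks@Xa, 2, da, "/")
  blocks@Xd <- sweep(blocks@Xd, 2, dd, "/")
  blocks@standardized <- TRUE
  blocks
}

#' Apply a training coding to new individuals
#'
#' Builds design blocks for (e.g. validation) individuals using the coding
#' and standardization constants derived from the training set, so
#' prediction never peeks at validation genotype frequencies.
#'
#' @param blocks training [DesignBlocks-class].
#' @param geno dosage matrix of the new individuals over the same markers.
#' @return A [DesignBlocks-class] for the new individuals.
#' @export
applyCoding <- function(blocks, geno) {
  if (ncol(geno) != ncol(blocks@Xa))
    stop("marker mismatch between fit and target panel")
  if (anyNA(geno)) stop("missing genotypes are not supported")
  out <- .codeBlocks(geno, blocks@coding, blocks@markers,
                     ids = rownames(geno) %||% as.character(seq_len(nrow(geno))))
  if (blocks@standardized) out <- standardizeBlocks(out)
  out
}

#' Interaction covariate column
#'
#' Element-wise product of the designated standardized main-effect columns:
#' aa = Xa_j * Xa_k, ad = Xa_j * Xd_k, da = Xd_j * Xa_k, dd = Xd_j * Xd_k
#' (j < k). Columns are computed on demand; storage never scales with the
#' squared marker count.
#'
#' @param blocks a [DesignBlocks-class].
#' @param source one of "aa", "ad", "da", "dd".
#' @param j,k marker column indices with `j < k`.
#' @return Numeric covariate column.
#' @export
interactionColumn <- function(blocks, source = c("aa", "ad", "da", "dd"),
                              j, k) {
  source <- match.arg(source)
  if (j >= k) stop("interaction columns require j < k")
  left <- if (substr(source, 1, 1) == "a") blocks@Xa[, j] else blocks@Xd[, j]
  right <- if (substr(source, 2, 2) == "a") blocks@Xa[, k] else blocks@Xd[, k]
  left * right
}

#' Model layout: active sources and effect counts
#'
#' M0 fits additive effects only; M1 adds dominance; M2 adds the four
#' pairwise epistatic sources with `m * (m - 1) / 2` effects each,
#' processed in the order a, d, aa, ad, da, dd.
#'
#' @param model "M0", "M1" or "M2".
#' @param m number of markers in the design.
#' @return list with `sources` (character) and `m` (named effect counts).
#' @export
modelDesign <- function(model = c("M1", "M0", "M2"), m) {
  model <- match.arg(model)
  sources <- switch(model, M0 = "a", M1 = c("a", "d"),
                    M2 = c("a", "d", "aa", "ad", "da", "dd"))
  ms <- ifelse(sources %in% c("a", "d"), m, m * (m - 1) / 2)
  list(sources = sources, m = setNames(ms, sources))
}

setMethod("show", "DesignBlocks", function(object) {
  cat(sprintf(
    "DesignBlocks: %d individuals x %d markers (%s; %d inert a, %d inert d)\n",
    nrow(object@Xa), ncol(object@Xa),
    if (object@standardized) "standardized" else "unstandardized",
    sum(object@coding$inertA), sum(object@coding$inertD)))
})
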