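#' Genome map of marker positions
#'
#' Marker positions in Morgan on a set of chromosomes. Positions are stored
#' as one sorted vector per genome with a chromosome index per marker;
#' within a chromosome positions are strictly increasing and relative to the
#' chromosome start.
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLength numeric vector of chromosome lengths in Morgan.
#' @slot positions numeric vector of marker positions (Morgan, per
#'   chromosome, starting at 0).
#' @slot chrom integer chromosome index (1-based) per marker, non-decreasing.
#' @exportClass GenomeMap
setClass("GenomeMap",
  slots = c(nChrom = "integer", chromLength = "numeric",
            positions = "numeric", chrom = "integer"))

setValidity("GenomeMap", function(object) {
  msg <- character()
  if (length(object@chromLength) != object@nChrom)
    msg <- c(msg, "chromLength must have one entry per chromosome")
  if (length(object@positions) != length(object@chrom))
    msg <- c(msg, "positions and chrom must have equal length")
  if (is.unsorted(object@chrom))
    msg <- c(msg, "markers must be ordered by chromosome")
  for (c in unique(object@chrom)) {
    p <- object@positions[object@chrom == c]
    if (any(diff(p) <= 0)) {
      msg <- c(msg, "positions must be strictly increasing within chromosome")
      break
    }
    if (any(p < 0) || any(p > object@chromLength[c]))
      msg <- c(msg, "positions must lie within the chromosome length")
  }
  if (length(msg)) msg else TRUE
})

#' Diploid population with pedigree
#'
#' Phased haplotypes plus pedigree. Haplotypes are stored markers-by-gametes
#' (columns `2i - 1`, `2i` belong to individual `i`); alleles are 0/1, and
#' genotype dosages count copies of allele 1.
#'
#' @slot haplotypes integer matrix, markers x (2 * individuals), entries 0/1.
#' @slot pedigree data.frame with columns `id`, `sire`, `dam`, `generation`,
#'   `sex` ("M"/"F") and `phenotyped` (logical); founders carry `NA` parents.
#' @slot map a [GenomeMap-class].
#' @exportClass Population
setClass("Population",
  slots = c(haplotypes = "matrix", pedigree = "data.frame", map = "GenomeMap"))

setValidity("Population", function(object) {
  msg <- character()
  ped <- object@pedigree
  need <- c("id", "sire", "dam", "generation", "sex", "phenotyped")
  if (!all(need %in% names(ped)))
    return(paste("pedigree must contain columns:", paste(need, collapse = ", ")))
  if (ncol(object@haplotypes) != 2L * nrow(ped))
    msg <- c(msg, "haplotype columns must equal 2 * number of individuals")
  if (nrow(object@haplotypes) != length(object@map@positions))
    msg <- c(msg, "haplotype rows must match the number of mapped markers")
  rng <- range(object@haplotypes)
  if (rng[1] < 0L || rng[2] > 1L)
    msg <- c(msg, "haplotype alleles must be 0/1")
  nf <- !is.na(ped$sire)
  if (any(nf)) {
    gen <- ped$generation[match(ped$sire[nf], ped$id)]
    if (any(is.na(gen)) || any(gen >= ped$generation[nf]))
      msg <- c(msg, "every non-founder's sire must exist in an earlier generation")
    gend <- ped$generation[match(ped$dam[nf], ped$id)]
    if (any(is.na(gend)) || any(gend >= ped$generation[nf]))
      msg <- c(msg, "every non-founder's dam must exist in an earlier generation")
  }
  if (length(msg)) msg else TRUE
})

#' Quantitative trait architecture
#'
#' QTL positions and their genetic effects on the F-infinity scale: allele
#' substitution effects `a`, dominance effects `d`, and optional pairwise
#' epistatic effects per source (aa, ad, da, dd). The orientation slot fixes,
#' per QTL, which homozygote is genotype class 22 (the more frequent allele
#' at sampling time carries the positive additive coefficient).
#'
#' @slot qtl integer marker indices (into the analysis panel) of the QTL.
#' @slot a numeric allele substitution effects, trait units.
#' @slot d numeric dominance effects.
#' @slot pairs data.frame with columns `source`, `j`, `k` (marker indices,
#'   `j < k`) and `effect`; zero rows when no epistasis is simulated.
#' @slot h2 broad-sense heritability used for residual-variance calibration.
#' @slot sigmaE2 residual variance (`NA` until calibrated).
#' @slot class22dose integer per QTL: the dosage (0 or 2) labelled as
#'   genotype class 22.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  slots = c(qtl = "integer", a = "numeric", d = "numeric",
            pairs = "data.frame", h2 = "numeric", sigmaE2 = "numeric",
            class22dose = "integer"))

setValidity("TraitArchitecture", function(object) {
  msg <- character()
  nq <- length(object@qtl)
  if (length(object@a) != nq || length(object@d) != nq ||
      length(object@class22dose) != nq)
    msg <- c(msg, "a, d and class22dose must have one entry per QTL")
  if (nrow(object@pairs)) {
    if (!all(c("source", "j", "k", "effect") %in% names(object@pairs)))
      msg <- c(msg, "pairs needs columns source, j, k, effect")
    else {
      if (any(object@pairs$j >= object@pairs$k))
        msg <- c(msg, "epistatic pairs must satisfy j < k")
      if (!all(object@pairs$source %in% c("aa", "ad", "da", "dd")))
        msg <- c(msg, "unknown epistatic source in pairs")
    }
  }
  if (!is.na(object@sigmaE2) && object@sigmaE2 <= 0)
    msg <- c(msg, "sigmaE2 must be positive")
  if (length(msg)) msg else TRUE
})

#' Orthogonal standardized design blocks
#'
#' Per-marker NOIA additive and dominance covariate columns, standardized to
#' unit frequency-weighted variance under the genotype frequencies of the
#' individuals the coding was derived from (the training set). Interaction
#' columns for the epistatic sources are element-wise products of these
#' columns and are computed on demand via [interactionColumn()]; they are
#' never materialised genome-wide.
#'
#' @slot Xa numeric matrix (individuals x markers), additive columns.
#' @slot Xd numeric matrix, dominance columns.
#' @slot coding data.frame of per-marker coding constants: genotype class
#'   frequencies `p11`, `p12`, `p22`, coefficients `wa0/wa1/wa2`,
#'   `wd0/wd1/wd2` indexed by dosage class, standard deviations `sdA`,
#'   `sdD`, inert flags, and `class22dose` orientation.
#' @slot markers integer indices of the retained markers in the source panel.
#' @slot ids individual ids (rows of `Xa`/`Xd`).
#' @slot standardized logical; whether columns were divided by their sd.
#' @exportClass DesignBlocks
setClass("DesignBlocks",
  slots = c(Xa = "matrix", Xd = "matrix", coding = "data.frame",
            markers = "integer", ids = "character", standardized = "logical"))

setValidity("DesignBlocks", function(object) {
  msg <- character()
  if (!identical(dim(object@Xa), dim(object@Xd)))
    msg <- c(msg, "Xa and Xd must have identical dimensions")
  if (nrow(object@coding) != ncol(object@Xa))
    msg <- c(msg, "coding must have one row per marker column")
  if (length(object@markers) != ncol(object@Xa))
    msg <- c(msg, "markers must index every column")
  if (length(msg)) msg else TRUE
})

#' Mixture-prior specification per genetic source
#'
#' For each source s the prior of an effect is a point mass at zero with
#' probability 1 - gamma_s and a Laplace distribution with rate lambda_s
#' otherwise, so Var(g) = gamma_s * 2 / lambda_s^2. When `lambda` is derived
#' from a unit total prior variance per source, lambda_s =
#' sqrt(2 / (m_s * gamma_s)).
#'
#' @slot sources character vector of active sources, in processing order.
#' @slot gamma named numeric mixing probabilities in (0, 1].
#' @slot lambda named numeric Laplace rates (> 0).
#' @slot m named integer effect counts per source.
#' @exportClass PriorSpec
setClass("PriorSpec",
  slots = c(sources = "character", gamma = "numeric", lambda = "numeric",
            m = "numeric"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  for (nm in c("gamma", "lambda", "m"))
    if (!identical(names(slot(object, nm)), object@sources))
      msg <- c(msg, paste(nm, "must be named by the active sources"))
  if (any(object@gamma <= 0) || any(object@gamma > 1))
    msg <- c(msg, "gamma must lie in (0, 1]")
  if (any(object@lambda <= 0)) msg <- c(msg, "lambda must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted ICE model
#'
#' @slot estimates named list of effect estimate vectors per source; the
#'   epistatic vectors are in row-major upper-triangle order
#'   (g[1,2], g[1,3], ..., g[m-1,m]).
#' @slot sigmaE2 final residual variance estimate.
#' @slot iterations outer iterations used.
#' @slot converged logical convergence flag.
#' @slot criterionTrace per-iteration convergence criterion.
#' @slot sigmaTrace per-iteration residual variance.
#' @slot model "M0", "M1" or "M2".
#' @slot priors the [PriorSpec-class] used.
#' @slot residual final training residual vector.
#' @slot residualCheck largest relative deviation between the maintained
#'   residual and a from-scratch recomputation (bookkeeping diagnostic).
#' @exportClass FitResult
setClass("FitResult",
  slots = c(estimates = "list", sigmaE2 = "numeric", iterations = "integer",
            converged = "logical", criterionTrace = "numeric",
            sigmaTrace = "numeric", model = "character", priors = "PriorSpec",
            residual = "numeric", residualCheck = "numeric"))

setValidity("FitResult", function(object) {
  if (object@sigmaE2 <= 0) return("sigmaE2 must be positive")
  if (object@converged &&
      length(object@criterionTrace) &&
      !is.na(tail(object@criterionTrace, 1)) &&
      tail(object@criterionTrace, 1) > 1) # loose sanity cap; L is model-specific
    return("converged fit with criterion > 1 is inconsistent")
  TRUE
})
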