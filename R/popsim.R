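#' Construct a genome map
#'
#' Places `nMarkers` markers uniformly at random on `nChrom` chromosomes
#' (marker counts proportional to chromosome length) and sorts them. The
#' default emulates a 30 Morgan cattle-style genome at 50k-chip density.
#' Randomness is drawn from the current RNG stream; call `set.seed()` first
#' for reproducibility.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength chromosome length(s) in Morgan; recycled to `nChrom`.
#' @param nMarkers total number of markers.
#' @return A [GenomeMap-class].
#' @examples
#' set.seed(1)
#' gm <- genomeMap(nChrom = 3, chromLength = 1, nMarkers = 300)
#' nMarkers(gm)
#' @export
genomeMap <- function(nChrom = 30L, chromLength = 1, nMarkers = 52273L) {
  nChrom <- as.integer(nChrom)
  nMarkers <- as.integer(nMarkers)
  if (nChrom < 1L || nMarkers < 1L)
    stop("need at least one chromosome and one marker")
  chromLength <- rep_len(as.numeric(chromLength), nChrom)
  chr <- sort(sample.int(nChrom, nMarkers, replace = TRUE,
                         prob = chromLength / sum(chromLength)))
  pos <- numeric(nMarkers)
  for (c in unique(chr)) {
    i <- which(chr == c)
    p <- sort(runif(length(i), 0, chromLength[c]))
    # enforce strictly increasing positions (ties have probability ~0)
    while (any(diff(p) <= 0)) p <- sort(runif(length(i), 0, chromLength[c]))
    pos[i] <- p
  }
  new("GenomeMap", nChrom = nChrom, chromLength = chromLength,
      positions = pos, chrom = as.integer(chr))
}

#' @rdname GenomeMap-class
#' @export
setMethod("nMarkers", "GenomeMap", function(x) length(x@positions))

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d markers on %d chromosome(s), %.2f Morgan total\n",
              nMarkers(object), object@nChrom, sum(object@chromLength)))
})

#' Extract a sub-panel of markers
#'
#' @param map a [GenomeMap-class].
#' @param idx marker indices to keep (will be sorted).
#' @return A [GenomeMap-class] restricted to `idx`.
#' @export
subsetMap <- function(map, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1L) || any(idx > nMarkers(map)))
    stop("marker index outside panel")
  new("GenomeMap", nChrom = map@nChrom, chromLength = map@chromLength,
      positions = map@positions[idx], chrom = map@chrom[idx])
}

#' Forward mutation-drift simulation of a base population
#'
#' Simulates `nGenerations` of random mating at constant effective size from
#' founders that are homozygous for the same allele at every locus. Each
#' transmitted gamete experiences Poisson recombination (no interference,
#' expected crossovers = chromosome length in Morgan) and symmetric allele
#' flip mutation at rate `mutationRate` per locus. Sexes are assigned 50/50
#' and each offspring draws its sire and dam uniformly.
#'
#' With the default cattle-style settings (Ne = 100, 52,273 SNPs on 30
#' Morgan, mutation rate 2.5e-3, 400 generations) the population reaches
#' mutation-drift balance with mean SNP heterozygosity near 0.33, about 10%
#' of loci fixed by drift, and mean adjacent-marker r^2 near 0.12.
#'
#' @param map a [GenomeMap-class].
#' @param effectiveSize number of diploid individuals (>= 2).
#' @param mutationRate per-locus, per-gamete flip probability in (0, 1);
#'   0 is allowed (pure drift).
#' @param nGenerations generations of random mating (>= 1).
#' @param seed optional integer seed.
#' @param recordHetAt integer generations at which mean heterozygosity is
#'   recorded (attribute `hetTrace` of the result).
#' @return A [Population-class] holding the final generation; the pedigree
#'   labels them as founders of generation `nGenerations`.
#' @export
simulateBasePopulation <- function(map, effectiveSize = 100L,
                                   mutationRate = 2.5e-3,
                                   nGenerations = 400L, seed = NULL,
                                   recordHetAt = integer(0)) {
  if (!is(map, "GenomeMap")) stop("map must be a GenomeMap")
  if (nMarkers(map) < 1L) stop("configuration error: zero markers")
  if (nGenerations < 1L) stop("configuration error: zero generations")
  if (effectiveSize < 2L) stop("effectiveSize must be at least 2")
  if (mutationRate < 0 || mutationRate >= 1)
    stop("mutationRate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate_base(as.integer(effectiveSize),
                           as.integer(nGenerations), mutationRate,
                           map@positions, map@chrom, map@chromLength,
                           as.integer(recordHetAt))
  ne <- as.integer(effectiveSize)
  nmale <- ne %/% 2L
  ped <- data.frame(
    id = sprintf("G%d_%d", nGenerations, seq_len(ne)),
    sire = NA_character_, dam = NA_character_,
    generation = as.integer(nGenerations),
    sex = rep(c("M", "F"), c(nmale, ne - nmale)),
    phenotyped = FALSE, stringsAsFactors = FALSE)
  pop <- new("Population", haplotypes = res$haplotypes, pedigree = ped,
             map = map)
  if (length(recordHetAt))
    attr(pop, "hetTrace") <- data.frame(generation = res$het_generation,
                                        het = res$het_trace)
  pop
}

#' Single meiosis
#'
#' Produces one gamete from a pair of phased parental haplotypes; crossover
#' counts per chromosome are Poisson with mean equal to the map length in
#' Morgan, crossover positions are uniform and there is no interference.
#'
#' @param h1,h2 integer 0/1 haplotype vectors of the parent.
#' @param map a [GenomeMap-class] matching the haplotype length.
#' @return An integer 0/1 gamete haplotype.
#' @export
meiosisGamete <- function(h1, h2, map) {
  if (length(h1) != nMarkers(map) || length(h2) != nMarkers(map))
    stop("haplotype length must match the map")
  cpp_meiosis(as.integer(h1), as.integer(h2), map@positions, map@chrom,
              map@chromLength)
}

#' Breed half-sib training and test generations
#'
#' Starting from the base population, builds successive generations each
#' consisting of `nFamilies` paternal half-sib families with
#' `nOffspringPerFamily` offspring: sires are drawn without replacement from
#' the previous generation's males and every offspring within a family has a
#' distinct dam (dams drawn without replacement per family from the previous
#' generation's females; dams may recur across families). The first
#' `nTrainGenerations` are flagged as phenotyped, the remaining
#' `nTestGenerations` are not. Offspring sexes alternate, keeping both sexes
#' available for the next generation.
#'
#' @param base a [Population-class] (the current parents).
#' @param nFamilies half-sib families per generation.
#' @param nOffspringPerFamily offspring per family.
#' @param nTrainGenerations,nTestGenerations numbers of phenotyped and
#'   unphenotyped generations.
#' @param mutationRate per-locus, per-gamete mutation rate applied during
#'   breeding (same mechanism as in the base simulation).
#' @param seed optional integer seed.
#' @return A [Population-class] containing the base individuals plus all
#'   bred generations.
#' @export
breedStructuredGenerations <- function(base, nFamilies = 50L,
                                       nOffspringPerFamily = 20L,
                                       nTrainGenerations = 2L,
                                       nTestGenerations = 2L,
                                       mutationRate = 2.5e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- base@pedigree
  if (!any(ped$sex == "M") || !any(ped$sex == "F"))
    stop("base population must contain both sexes")
  haps <- base@haplotypes
  map <- base@map
  gen0 <- max(ped$generation)
  ngen <- nTrainGenerations + nTestGenerations
  allPed <- ped
  allHaps <- list(haps)
  prevPed <- ped
  prevOffset <- 0L # column-pair offset of previous generation in prev matrix
  prevHaps <- haps
  prevStart <- 1L # row offset of the previous generation in allPed
  for (g in seq_len(ngen)) {
    males <- which(prevPed$sex == "M")
    females <- which(prevPed$sex == "F")
    # small toy pedigrees may lack a sex in the newest generation; fall
    # back to drawing the missing parents from the whole pedigree so far
    poolPed <- prevPed
    poolHaps <- prevHaps
    if (length(males) < nFamilies || length(females) < nOffspringPerFamily) {
      poolPed <- allPed
      poolHaps <- do.call(cbind, allHaps)
      males <- which(poolPed$sex == "M")
      females <- which(poolPed$sex == "F")
    }
    if (length(males) < nFamilies)
      stop("too few candidate sires in generation ", gen0 + g - 1L)
    if (length(females) < nOffspringPerFamily)
      stop("too few candidate dams in generation ", gen0 + g - 1L)
    sires <- sample(males, nFamilies)
    sireIdx <- rep(sires, each = nOffspringPerFamily)
    damIdx <- unlist(lapply(seq_len(nFamilies), function(f)
      sample(females, nOffspringPerFamily)))
    off <- cpp_breed_offspring(poolHaps, as.integer(sireIdx),
                               as.integer(damIdx), mutationRate,
                               map@positions, map@chrom, map@chromLength)
    noff <- length(sireIdx)
    gped <- data.frame(
      id = sprintf("G%d_%d", gen0 + g, seq_len(noff)),
      sire = poolPed$id[sireIdx], dam = poolPed$id[damIdx],
      generation = as.integer(gen0 + g),
      sex = rep_len(c("M", "F"), noff),
      phenotyped = g <= nTrainGenerations, stringsAsFactors = FALSE)
    allPed <- rbind(allPed, gped)
    allHaps[[g + 1L]] <- off
    prevPed <- gped
    prevHaps <- off
  }
  new("Population", haplotypes = do.call(cbind, allHaps), pedigree = allPed,
      map = map)
}

#' @rdname Population-class
#' @param individuals individual ids (character), a logical mask, or `NULL`
#'   for all individuals.
#' @export
setMethod("genotypes", "Population", function(x, individuals = NULL, ...) {
  geno <- cpp_dosages(x@haplotypes)
  rownames(geno) <- x@pedigree$id
  if (!is.null(individuals)) geno <- geno[.resolveIds(x, individuals), ,
                                          drop = FALSE]
  geno
})

#' @rdname Population-class
#' @export
setMethod("pedigree", "Population", function(x) x@pedigree)

#' @rdname Population-class
#' @export
setMethod("genomeMapOf", "Population", function(x) x@map)

#' @rdname Population-class
#' @export
setMethod("nIndividuals", "Population", function(x) nrow(x@pedigree))

#' @rdname Population-class
#' @export
setMethod("nMarkers", "Population", function(x) nrow(x@haplotypes))

setMethod("show", "Population", function(object) {
  tab <- table(object@pedigree$generation)
  cat(sprintf("Population: %d individuals, %d markers\n",
              nIndividuals(object), nMarkers(object)))
  cat("  generations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
})

.resolveIds <- function(pop, individuals) {
  ped <- pop@pedigree
  if (is.logical(individuals)) return(which(individuals))
  if (is.numeric(individuals)) return(as.integer(individuals))
  i <- match(individuals, ped$id)
  if (anyNA(i)) stop("unknown individual id(s)")
  i
}

#' Individuals of given generations
#'
#' @param pop a [Population-class].
#' @param generations generation labels.
#' @return Character vector of individual ids.
#' @export
individualsOf <- function(pop, generations) {
  ped <- pop@pedigree
  ped$id[ped$generation %in% generations]
}

#' Restrict a population to a marker subset
#'
#' @param pop a [Population-class].
#' @param idx marker indices to keep.
#' @return A [Population-class] on the reduced panel.
#' @export
subsetMarkers <- function(pop, idx) {
  idx <- sort(unique(as.integer(idx)))
  new("Population", haplotypes = pop@haplotypes[idx, , drop = FALSE],
      pedigree = pop@pedigree, map = subsetMap(pop@map, idx))
}

#' Per-marker genotype summary statistics
#'
#' Counts genotype classes in a subset of individuals. Heterozygosity is the
#' observed heterozygote frequency `p12`; the retained flag marks markers
#' with minor allele frequency above `mafThreshold`.
#'
#' @param pop a [Population-class].
#' @param individuals subset of individuals (ids, logical mask, or `NULL`
#'   for all); must be non-empty.
#' @param mafThreshold MAF cut-off for the retained flag.
#' @return data.frame with columns `marker`, `p` (allele-1 frequency), `p0`,
#'   `p1`, `p2` (dosage class frequencies), `p11`, `p12`, `p22` (class
#'   frequencies with class 22 the more frequent homozygote), `maf`, `het`,
#'   `class22dose` and `retained`.
#' @export
computeMarkerStats <- function(pop, individuals = NULL, mafThreshold = 0.01) {
  geno <- genotypes(pop, individuals)
  if (nrow(geno) == 0L) stop("empty individual subset")
  n <- nrow(geno)
  n0 <- colSums(geno == 0L)
  n1 <- colSums(geno == 1L)
  n2 <- n - n0 - n1
  p0 <- n0 / n; p1 <- n1 / n; p2 <- n2 / n
  p <- (n1 + 2 * n2) / (2 * n)
  maf <- pmin(p, 1 - p)
  class22dose <- ifelse(p >= 0.5, 2L, 0L)
  p22 <- ifelse(class22dose == 2L, p2, p0)
  p11 <- ifelse(class22dose == 2L, p0, p2)
  data.frame(marker = seq_len(ncol(geno)), p = p, p0 = p0, p1 = p1, p2 = p2,
             p11 = p11, p12 = p1, p22 = p22, maf = maf, het = p1,
             class22dose = class22dose, retained = maf > mafThreshold)
}

#' Mean linkage disequilibrium between adjacent markers
#'
#' r^2 is the squared Pearson correlation of genotype dosages between
#' adjacent retained markers within chromosomes, averaged genome-wide; pairs
#' spanning chromosome boundaries and pairs involving a monomorphic marker
#' are excluded.
#'
#' @param pop a [Population-class].
#' @param stats marker statistics from [computeMarkerStats()] (for the
#'   retained flags); `NULL` retains all markers.
#' @param individuals individual subset (as in [computeMarkerStats()]).
#' @return Mean adjacent r^2 (scalar).
#' @export
adjacentLD <- function(pop, stats = NULL, individuals = NULL) {
  keep <- if (is.null(stats)) seq_len(nMarkers(pop)) else
    which(stats$retained)
  if (length(keep) < 2L) stop("need at least two retained markers")
  geno <- genotypes(pop, individuals)[, keep, drop = FALSE]
  chr <- pop@map@chrom[keep]
  storage.mode(geno) <- "double"
  n <- nrow(geno)
  cm <- colMeans(geno)
  cv <- colMeans(geno^2) - cm^2
  j <- seq_len(ncol(geno) - 1L)
  same <- chr[j] == chr[j + 1L]
  sxy <- colMeans(geno[, j, drop = FALSE] * geno[, j + 1L, drop = FALSE])
  r2 <- (sxy - cm[j] * cm[j + 1L])^2 / (cv[j] * cv[j + 1L])
  r2 <- r2[same & cv[j] > 0 & cv[j + 1L] > 0]
  mean(r2)
}

#' Thin a marker panel
#'
#' Keeps every `step`-th marker (markers `step, 2*step, ...`), plus any
#' forced indices (for example QTL positions, which by construction of the
#' scenario harness already lie on the thinned grid).
#'
#' @param map a [GenomeMap-class] (or anything with `nMarkers()`).
#' @param step thinning step (>= 1); `1` keeps every marker.
#' @param forced indices that must be present in the result.
#' @return Sorted integer vector of retained marker indices.
#' @export
thinMarkers <- function(map, step, forced = integer(0)) {
  m <- nMarkers(map)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (length(forced) && (any(forced < 1L) || any(forced > m)))
    stop("forced index outside panel")
  sort(unique(c(as.integer(seq.int(step, m, by = step)),
                as.integer(forced))))
}
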