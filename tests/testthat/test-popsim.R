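test_that("genome map places sorted in-range markers and validates", {
  set.seed(3)
  gm <- genomeMap(nChrom = 5, chromLength = 1.5, nMarkers = 500)
  expect_equal(nMarkers(gm), 500L)
  expect_true(all(diff(gm@chrom) >= 0))
  for (c in 1:5) {
    p <- gm@positions[gm@chrom == c]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1.5))
  }
  expect_error(genomeMap(nMarkers = 0), "at least one")
})

test_that("meiosis returns the parent haplotype when both are identical", {
  set.seed(5)
  gm <- genomeMap(nChrom = 2, chromLength = 1, nMarkers = 100)
  h <- rbinom(100, 1, 0.5)
  for (i in 1:5) expect_identical(meiosisGamete(h, h, gm), as.integer(h))
})

test_that("realized recombination fractions follow the Haldane map", {
  # linked pair at distance d: recombination fraction (1 - exp(-2d))/2
  nrep <- 6000
  for (d in c(0.05, 0.2, 0.5)) {
    gm <- new("GenomeMap", nChrom = 1L, chromLength = 1,
              positions = c(0.2, 0.2 + d), chrom = c(1L, 1L))
    set.seed(round(1000 * d))
    rec <- 0
    for (i in seq_len(nrep)) {
      g <- cpp_meiosis(c(0L, 0L), c(1L, 1L), gm@positions, gm@chrom,
                       gm@chromLength)
      rec <- rec + (g[1] != g[2])
    }
    expected <- (1 - exp(-2 * d)) / 2
    se <- sqrt(expected * (1 - expected) / nrep)
    expect_lt(abs(rec / nrep - expected), 4 * se)
  }
})

test_that("no mutation from homozygous founders keeps all loci monomorphic", {
  set.seed(8)
  gm <- genomeMap(nChrom = 2, chromLength = 1, nMarkers = 50)
  pop <- simulateBasePopulation(gm, 20, 0, 60)
  expect_true(all(pop@haplotypes == 0L))
})

test_that("allele frequency is conserved in expectation under pure drift", {
  # start each replicate at p = 0.5 by giving every individual one copy
  set.seed(21)
  gm <- new("GenomeMap", nChrom = 1L, chromLength = 1,
            positions = sort(runif(30)), chrom = rep(1L, 30))
  ne <- 20
  freqs <- replicate(80, {
    # every founder heterozygous at every locus: p starts at 0.5
    haps <- matrix(rep_len(c(0L, 1L), 2 * ne * 30), nrow = 30, byrow = TRUE)
    for (g in 1:5)
      haps <- cpp_breed_offspring(haps, sample(1:(ne / 2), ne, TRUE),
                                  sample((ne / 2 + 1):ne, ne, TRUE),
                                  0, gm@positions, gm@chrom, gm@chromLength)
    mean(haps)
  })
  expect_lt(abs(mean(freqs) - 0.5), 4 * sd(freqs) / sqrt(length(freqs)))
})

test_that("heterozygosity stabilizes under mutation-drift balance", {
  set.seed(13)
  gm <- genomeMap(nChrom = 3, chromLength = 1, nMarkers = 600)
  pop <- simulateBasePopulation(gm, 50, 2.5e-3, 400,
                                recordHetAt = c(350, 400))
  tr <- attr(pop, "hetTrace")
  expect_equal(tr$generation, c(350, 400))
  # per-locus het has sd ~0.15; difference of means over 600 loci
  expect_lt(abs(diff(tr$het)), 4 * 0.15 / sqrt(600) * sqrt(2))
})

test_that("half-sib breeding yields the stated family structure", {
  pop <- smallTestPopulation(seed = 99, nMarkers = 120, ne = 50, gens = 30)
  full <- breedStructuredGenerations(pop, nFamilies = 10,
                                     nOffspringPerFamily = 8,
                                     nTrainGenerations = 2,
                                     nTestGenerations = 2, seed = 7)
  ped <- pedigree(full)
  expect_equal(sum(ped$generation > 30), 4 * 10 * 8)
  expect_equal(sum(ped$phenotyped), 2 * 10 * 8)
  expect_false(any(ped$phenotyped[ped$generation > 32]))
  for (g in 31:34) {
    pg <- ped[ped$generation == g, ]
    fam <- split(pg, pg$sire)
    expect_length(fam, 10)
    for (f in fam) {
      expect_equal(nrow(f), 8)           # one sire per family
      expect_equal(anyDuplicated(f$dam), 0) # no two offspring share a dam
      parents <- ped[match(c(f$sire[1], f$dam), ped$id), ]
      expect_true(all(parents$generation == g - 1))
      expect_true(all(parents$sex == c("M", rep("F", nrow(f)))))
    }
  }
  # pedigree acyclicity / generation monotonicity is enforced by validity
  expect_true(validObject(full))
  expect_error(breedStructuredGenerations(pop, nFamilies = 1000),
               "too few")
})

test_that("single-family breeding gives one non-founder per generation", {
  pop <- smallTestPopulation(seed = 3, nMarkers = 60, ne = 20, gens = 10)
  out <- breedStructuredGenerations(pop, 1, 1, 1, 1, seed = 2)
  ped <- pedigree(out)
  expect_equal(as.integer(table(ped$generation[ped$generation > 10])),
               c(1L, 1L))
})

test_that("marker statistics count genotype classes correctly", {
  pop <- smallTestPopulation(seed = 31, nMarkers = 50, ne = 30, gens = 40)
  # one individual per genotype class at a hand-built marker
  geno <- genotypes(pop)
  st <- computeMarkerStats(pop)
  expect_true(all(abs(st$p11 + st$p12 + st$p22 - 1) < 1e-12))
  expect_true(all(st$maf >= 0 & st$maf <= 0.5))
  expect_equal(st$het, st$p1)
  expect_equal(st$het, st$p12)
  j <- which(st$maf > 0.2)[1]
  n <- nrow(geno)
  expect_equal(st$p[j], sum(geno[, j]) / (2 * n))
  # monomorphic marker: MAF 0, not retained at threshold 0.01
  mono <- which(st$maf == 0)
  if (length(mono)) expect_false(any(st$retained[mono]))
  expect_error(computeMarkerStats(pop, character(0)), "empty|unknown")
})

test_that("three-genotype example gives uniform class frequencies", {
  pop <- smallTestPopulation(seed = 55, nMarkers = 10, ne = 30, gens = 5)
  pop@haplotypes[1, ] <- 0L
  pop@haplotypes[1, 1:2] <- c(0L, 0L)
  # build marker 1 with dosages 0,1,2 across first three individuals only
  pop2 <- pop
  pop2@haplotypes[1, ] <- rep(c(0L, 0L), 30)
  pop2@haplotypes[1, 3:4] <- c(0L, 1L)
  pop2@haplotypes[1, 5:6] <- c(1L, 1L)
  st <- computeMarkerStats(pop2, pedigree(pop2)$id[1:3])
  expect_equal(st$p11[1], 1 / 3)
  expect_equal(st$p12[1], 1 / 3)
  expect_equal(st$p22[1], 1 / 3)
  expect_equal(st$p[1], 0.5)
})

test_that("adjacent LD matches duplicated-column and independence oracles", {
  pop <- smallTestPopulation(seed = 77, nMarkers = 200, ne = 50, gens = 60)
  st <- computeMarkerStats(pop)
  # duplicated marker column: r^2 = 1
  dup <- pop
  chr <- pop@map@chrom
  ok <- st$maf > 0.2 & chr == c(chr[-1], -1L)  # next marker on same chromosome
  j <- which(ok)[1]
  dup@haplotypes[j + 1, ] <- dup@haplotypes[j, ]
  stDup <- computeMarkerStats(dup)
  stDup$retained <- FALSE
  stDup$retained[c(j, j + 1)] <- TRUE
  expect_equal(adjacentLD(dup, stDup), 1)
  # independent columns: mean r^2 near the small-sample expectation 1/(n-1)
  set.seed(9)
  n <- 50; m <- 400
  ind <- pop
  ind@haplotypes <- matrix(rbinom(m * 2 * n, 1L, 0.5), nrow = m)
  ind@map <- new("GenomeMap", nChrom = 1L, chromLength = 1,
                 positions = sort(runif(m)), chrom = rep(1L, m))
  ind@pedigree <- pedigree(pop)
  r2 <- adjacentLD(ind)
  expect_lt(abs(r2 - 1 / (n - 1)), 0.008)
})

test_that("marker thinning keeps every step-th marker and forced indices", {
  set.seed(2)
  gm <- genomeMap(nChrom = 2, chromLength = 1, nMarkers = 1000)
  expect_equal(length(thinMarkers(gm, 10)), 100L)
  expect_identical(thinMarkers(gm, 1), 1:1000)
  expect_true(all(c(3L, 997L) %in% thinMarkers(gm, 10, forced = c(3, 997))))
  expect_error(thinMarkers(gm, 10, forced = 1001), "outside")
  # paper-scale panel size: every 10th of 52,273 leaves 5,227
  gmBig <- new("GenomeMap", nChrom = 1L, chromLength = 31,
               positions = seq_len(52273) * 31 / 52274, chrom = rep(1L, 52273))
  expect_equal(length(thinMarkers(gmBig, 10)), 5227L)
})

test_that("population accessors and subsetting are consistent", {
  pop <- smallTestPopulation(seed = 11, nMarkers = 80, ne = 20, gens = 20)
  geno <- genotypes(pop)
  expect_equal(dim(geno), c(20L, 80L))
  expect_true(all(geno %in% 0:2))
  sub <- subsetMarkers(pop, c(5, 17, 40))
  expect_equal(nMarkers(sub), 3L)
  expect_equal(genotypes(sub), geno[, c(5, 17, 40)])
  expect_equal(individualsOf(pop, 20), pedigree(pop)$id)
})
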