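# Shared fixtures and independent oracles, built in code at test time.

# Independent quadrature oracle for the posterior mean under the
# point-mass/Laplace mixture prior: piecewise adaptive integration with
# breakpoints at the prior kink (0) and the two shifted posterior modes.
quadPosteriorMean <- function(Y, s2, lambda, gamma) {
  sd <- sqrt(s2)
  f <- function(g) gamma * lambda / 2 * exp(-lambda * abs(g)) * dnorm(Y, g, sd)
  lo <- min(Y, 0) - 15 * sd
  hi <- max(Y, 0) + 15 * sd
  brk <- sort(unique(pmin(pmax(
    c(lo, 0, Y - lambda * s2, Y + lambda * s2, Y, hi), lo), hi)))
  A <- B <- 0
  for (i in seq_len(length(brk) - 1)) {
    if (brk[i + 1] - brk[i] < 1e-300) next
    A <- A + integrate(function(g) g * f(g), brk[i], brk[i + 1],
                       rel.tol = 1e-12, abs.tol = 0,
                       subdivisions = 500L)$value
    B <- B + integrate(f, brk[i], brk[i + 1], rel.tol = 1e-12, abs.tol = 0,
                       subdivisions = 500L)$value
  }
  A / (B + (1 - gamma) * dnorm(Y, 0, sd))
}

# small population for unit tests (fast, polymorphic)
smallTestPopulation <- function(seed = 424, nMarkers = 400, ne = 60,
                                gens = 80) {
  set.seed(seed)
  gm <- genomeMap(nChrom = 4, chromLength = 1, nMarkers = nMarkers)
  simulateBasePopulation(gm, ne, 2.5e-3, gens)
}

# random genotype class frequency triples (strictly interior)
randomFreqTriples <- function(n, seed = 1) {
  set.seed(seed)
  p <- matrix(rexp(3 * n) + 0.02, ncol = 3)
  p / rowSums(p)
}

# Cache for the replicated study runs shared by several acceptance checks.
.acceptanceCache <- new.env(parent = emptyenv())

acceptanceRuns <- function(epistasis) {
  key <- if (epistasis) "epi" else "noepi"
  if (!is.null(.acceptanceCache[[key]])) return(.acceptanceCache[[key]])
  cfg <- scenarioConfig(nQtl = 23, epistasis = epistasis, h2 = 0.5,
                        models = "M1", nReplicates = 10,
                        seed = if (epistasis) 2L else 1L)
  out <- runScenario(cfg, archDraws = 5L)
  .acceptanceCache[[key]] <- out
  out
}
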