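# epibayes

Fast Bayesian genomic prediction with dominance and epistasis.

`epibayes` estimates genome-wide additive, dominance and pairwise
epistatic SNP effects by **iterated conditional expectation (ICE)**: each
effect is set, in turn, to its analytic posterior mean given the
phenotypes corrected for all other current estimates, under a point-mass/
Laplace mixture prior

    g_{s,j} ~ (1 - γ_s) δ₀ + γ_s Laplace(rate λ_s),   λ_s = √(2 / (m_s γ_s)),

so a full genome fit needs seconds to minutes instead of the hours to
months an MCMC sampler needs once millions of interaction effects are in
the model. Genotypes are coded with the NOIA orthogonal decomposition
(additive and dominance covariates uncorrelated at every locus under the
observed genotype frequencies, standardized to unit variance), and
epistatic covariates are element-wise products of those columns, streamed
on demand so memory never scales with m². Three model layouts are
supported: additive only (M0), additive + dominance (M1), and all pairwise
interactions (M2).

The package also contains the population and trait simulator used to
evaluate the method: a forward mutation–drift simulation of a
cattle-style population (52,273 SNPs on 30 Morgan, Ne = 100, 400
generations, mutation rate 2.5e-3), half-sib training/test generations,
QTL architectures with gamma-distributed substitution effects, normal
degrees of dominance and optional pairwise epistasis, heritability-based
residual calibration, and the exact translation of true effects to the
orthogonal scale for variance-component truth. A scenario harness
(`runScenario()`) replicates the whole pipeline deterministically from a
master seed.

Intended users: quantitative geneticists and genomic-prediction
methodologists who want to fit or benchmark non-additive marker models on
simulated or real biallelic SNP data (VCF or dosage TSV).

## Worked example

```r
library(epibayes)

set.seed(7)
gm   <- genomeMap(nChrom = 30, chromLength = 1, nMarkers = 5000)
base <- simulateBasePopulation(gm, effectiveSize = 100,
                               mutationRate = 2.5e-3, nGenerations = 400)
pop  <- breedStructuredGenerations(base, nFamilies = 50,
                                   nOffspringPerFamily = 20)

train <- individualsOf(pop, c(401, 402))   # phenotyped
test  <- individualsOf(pop, c(403, 404))   # validation

st   <- computeMarkerStats(pop, individuals = train)   # gen-400 stats
arch <- sampleArchitecture(computeMarkerStats(pop, individualsOf(pop, 400),
                                              mafThreshold = 0.02),
                           nQtl = 23, scenario = "23", epistasis = FALSE,
                           h2 = 0.5)
G    <- genotypicValuesFinf(genotypes(pop, train), arch)
y    <- simulatePhenotypes(G, calibrateResidualVariance(G, 0.5))

keep   <- which(st$retained)               # MAF > 0.01 in training
blocks <- buildDesignBlocks(genotypes(pop, train)[, keep], markers = keep)
fit    <- iceFit(y, blocks, model = "M1")  # gamma_a = gamma_d = 0.005
fit
#> FitResult (M1): 14 iteration(s), converged, sigmaE2 = 0.2121
#>   non-zero effects: a=4887, d=4765

pred <- predictDgv(fit, applyCoding(blocks, genotypes(pop, test)[, keep]))
accuracy(pred$total, genotypicValuesFinf(genotypes(pop, test), arch))
#> [1] 0.9810455
varianceComponentsLE(fit)
#>           a           d
#> 0.234100597 0.001525657
```

The fit converges in roughly 13–16 outer iterations; the accuracy (the
correlation between predicted and simulated direct genetic values in the
two unphenotyped test generations) is typically near 0.98 for this 23-QTL,
H² = 0.5 setting, and the additive LE variance component
(the sum of squared standardized additive estimates) estimates the
simulated additive variance of that replicate — here a draw with one
moderate QTL dominating. A replicated study is one call:

```r
res <- runScenario(scenarioConfig(nQtl = 23, epistasis = TRUE, h2 = 0.5,
                                  models = c("M0", "M1", "M2"),
                                  nReplicates = 10, seed = 1,
                                  nMarkers = 3000, nFamilies = 25))
summarizeScenario(res$replicates, "accuracy")
```

A thin command-line wrapper lives at `inst/scripts/epibayes.R`
(`simulate`, `fit`, `scenario` subcommands).

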