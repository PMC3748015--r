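---
title: "Fast Bayesian estimation of additive, dominance and epistatic marker effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast Bayesian estimation of additive, dominance and epistatic marker effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibayes)
```

## The problem

Genomic prediction regresses phenotypes on thousands of biallelic SNP
markers at once. Most tools assume purely additive gene action; `epibayes`
estimates additive, dominance and all pairwise epistatic marker effects
jointly, in the "p much larger than n" regime, without MCMC. It is aimed at
quantitative geneticists who want to quantify how much non-additive
variation a trait carries and how model choice affects the accuracy of
direct genetic value (DGV) prediction, especially in livestock-style
populations with strong family structure.

## Model

Phenotypes follow

$$ y = 1\mu + X_a g_a + X_d g_d + \sum_{s \in \{aa,ad,da,dd\}} X_s g_s + e,
   \qquad e_i \sim N(0, \sigma_e^2). $$

Model **M0** keeps only the additive block, **M1** adds dominance, **M2**
adds the four pairwise interaction blocks with $m(m-1)/2$ effects each.

**Genotype coding.** Each marker's additive and dominance covariates use
the natural-and-orthogonal-interactions (NOIA, statistical scale)
decomposition built from the observed genotype class frequencies
$(p_{11}, p_{12}, p_{22})$, where class 22 is the homozygote of the more
frequent allele: the additive coefficient is the centered allele count and
the dominance coefficients are
$(-2p_{12}p_{22},\, 4p_{11}p_{22},\, -2p_{11}p_{12})/v$ with
$v = p_{11} + p_{22} - (p_{11} - p_{22})^2$. Under these frequencies both
columns have zero mean and zero cross-moment, so intra-locus additive and
dominance contributions are uncorrelated without assuming Hardy–Weinberg
equilibrium (under HWE the coding reduces to Cockerham's contrasts). Each
column is then divided by its own frequency-weighted standard deviation so
every covariate has unit variance; epistatic covariates are element-wise
products of the standardized main-effect columns and are *streamed*, never
stored genome-wide, so memory never scales with $m^2$ (beyond the effect
vectors themselves). Columns that are constant in the training data are
flagged inert and their effects pinned to zero, which preserves marker
indexing.

A typographical note: the printed form of the orthogonal design matrix in
the literature this package builds on is corrupted in commonly available
extractions; the coefficients above are fixed unambiguously by the
orthogonality and unit-variance constraints, which the test suite enforces
to $10^{-10}$ for arbitrary (non-HWE) class frequencies.

**Prior.** Every effect of source $s$ is, independently,

$$ g_{s,j} \sim (1-\gamma_s)\,\delta_0 + \gamma_s\,
   \mathrm{Laplace}(0, \lambda_s), $$

a point mass at zero mixed with a Laplace slab, so
$\mathrm{Var}(g_{s,j}) = \gamma_s \cdot 2/\lambda_s^2$. The mixing
probability $\gamma_s$ encodes the expected proportion of non-zero effects
(defaults: $\gamma_a = \gamma_d = 0.005$ for the 23-QTL study conditions,
$0.05$ for 230 QTL, $10^{-6}$ for epistatic sources). The rate is derived
from the total prior variance of a source as
$\lambda_s = \sqrt{2/(m_s \gamma_s)}$ (`deriveLambda()`), e.g.
$\lambda \approx 0.2766$ for $m = 5227$, $\gamma = 0.005$. The printed
derivation of this rule in the source literature is typographically
ambiguous and, read as plain algebra with unit total prior variance, would
give $\lambda_s = \sqrt{2 m_s \gamma_s}$ instead; we resolved the
ambiguity empirically on the study conditions: the rule used here
reproduces the reported M1 convergence behaviour (about 13–16 outer
iterations) and prediction accuracy, while the algebraic alternative
roughly doubles the iteration count without improving accuracy.

## The ICE estimator

The iterative conditional expectation (ICE) algorithm cycles through all
effects (sources in the order $a, d, aa, ad, da, dd$; within a source in
index order, epistatic effects in row-major upper-triangle order) and sets
each effect to its *analytic posterior mean* given the phenotypes
corrected for all other current estimates — coordinate-wise empirical
Bayes rather than sampling. For effect $j$ with column $x$,

$$ Y_j = (x'x)^{-1} x' y_{-j}, \qquad \sigma_j^2 = (x'x)^{-1}\sigma_e^2, $$

and the posterior mean under the mixture prior has the closed form

$$ \hat g = \frac{T_1 \Theta_U(0; Y_j^-, \sigma_j^2) +
            T_2 \Theta_L(0; Y_j^+, \sigma_j^2)}{T_1 + T_2 + T_3}, $$

with $Y_j^\pm = Y_j \pm \lambda \sigma_j^2$,
$T_1 = e^{-\lambda Y_j}\,\Phi(Y_j^-/\sigma_j)$,
$T_2 = e^{\lambda Y_j}\,\Phi(-Y_j^+/\sigma_j)$, and the point-mass term
$T_3 = \frac{2(1-\gamma)}{\gamma\lambda}
e^{-\lambda^2\sigma_j^2/2}\,\phi(Y_j; 0, \sigma_j^2)$;
$\Theta_U, \Theta_L$ are upper/lower truncated-normal means. All three
terms are evaluated in the log domain (with log-scale Mills ratios), which
keeps the formula stable for $|Y|/\sigma$ beyond 30 where the naive
$e^{\lambda|Y|}$ overflows. The closed form is verified against direct
numerical quadrature of the posterior to $10^{-6}$ relative error over a
grid spanning twelve orders of magnitude of the mixture odds; the estimate
always carries the sign of $Y_j$ and never exceeds it in magnitude.

Housekeeping per outer iteration: phenotypes are centered once up front;
optional nuisance covariates (the real-data hook) are removed by ordinary
least squares, refreshed every outer iteration and never shrunk; after all
sources are processed the residual variance is re-estimated as
$\hat\sigma_e^2 = \|y - \sum_s X_s \hat g_s\|^2/(n-1)$. Iterations stop
when $\|\hat g^{(k)} - \hat g^{(k-1)}\|_2 / \|\hat g^{(k)}\|_2 \le L$
(defaults $L = 10^{-8}$, $k_{\max} = 1000$ for M0/M1; $L = 10^{-6}$,
$k_{\max} = 200$ for M2). The printed criterion is ambiguous between this
norm ratio and its square; the norm reading reproduces the reported 13–16
M1 iterations (the squared reading converges in 6–10) and is used. Reaching
$k_{\max}$ sets `converged = FALSE` but is not an error; a diverging
$\hat\sigma_e^2$ aborts with a diagnostic. Updates are Gauss–Seidel style:
$y_{-j}$ is maintained as a running residual, so effects updated earlier in
a sweep are corrected at their new values; the residual is recomputed from
scratch every tenth iteration as a bookkeeping safeguard; the suite
asserts agreement to $10^{-8}$ relative.

Estimates feed three reports: DGVs $\sum_s X_s \hat g_s$ with per-source
parts; variance components under linkage equilibrium
$\hat\sigma_s^2 = \sum_j \hat g_{s,j}^2$ (exact only in the absence of LD —
with linked markers the omitted covariance terms can bias it either way,
which is why the empirical variances of the per-source predicted values are
reported alongside); and accuracy, the Pearson correlation of predicted and
simulated DGV in the unphenotyped test generations.

## The population and trait simulator

The generator emulates a dairy-cattle-style population and is first-class,
tested code; its defaults are the study conditions.

*Genome and base population.* 52,273 SNPs placed uniformly at random on 30
chromosomes of 1 Morgan each (the sources give only the total length and
chip style; equal-length chromosomes are a stand-in). Founders are
homozygous for one allele; 400 generations of random mating at constant
size 100 (sexes fixed 50/50, parents drawn uniformly) with Poisson
crossovers (no interference, Haldane map) and symmetric allele-flip
mutation at $2.5\times10^{-3}$ per locus per *transmitted gamete*. The
per-gamete reading was chosen over per-individual because it reproduces the
reported mean SNP heterozygosity of 0.33 ($4N_e\mu = 1$ puts the stationary
frequency spectrum close to uniform, giving $E[2pq] = 1/3$); the same
arithmetic makes the reported "about 10% of loci fixed" unreachable — a
near-uniform spectrum leaves only about 1% of loci monomorphic at
$2N = 200$ — so heterozygosity, which the estimation results actually
depend on, was the calibration target. Mean adjacent-marker $r^2$ (squared
dosage correlation within chromosomes) comes out near 0.11 on the full
panel and near 0.08 on the thinned, MAF-filtered training panel, against
reported values of 0.12 and 0.07.

*Families.* Two training generations and two test generations, each of 50
paternal half-sib families with 20 offspring: sires drawn without
replacement from the previous generation's males, 20 distinct dams per
family from its females (dams may recur across families — the base
generation has only 50 females). Training individuals (n = 2,000) are
phenotyped; test generations are not.

*Trait.* 23 (or 230) QTL are drawn from thinned-panel markers with
MAF > 0.02 in generation 400. Allele substitution magnitudes are
Gamma(0.42, rate 2.619) (rate 8.282 for 230 QTL) with random sign — the
rate reading, not scale, is required to reproduce the simulated additive
variance near 0.76; dominance is $|a|$ times a N(0.193, 0.312²) degree of
dominance. Optional epistasis adds six (57) pairs per source with normal
effects (aa/ad: mean 0.2, var 0.3; da: var 0.2; dd: var 0.1 in the 23-QTL
setting; one tenth/one hundredth of that for 230 QTL), which puts roughly a
quarter of the genetic variance into interactions. Residual variance is
calibrated *per replicate* from the empirical variance of total genotypic
values (epistasis included) among the training individuals:
$\sigma_e^2 = \widehat{\mathrm{Var}}(G)(1-H^2)/H^2$; this is the only rule
that makes the simulated residual variance track the total genetic variance
at $H^2 = 0.5$ and yields realized narrow-sense heritabilities near
0.474/0.307 without/with epistasis.

*Scale translation.* Phenotypes are simulated on the F∞ scale
($X = \pm1$ for homozygotes, $D = 1$ for heterozygotes) and estimated on
the orthogonal scale, so true effects are translated by solving the
genotypic-value identity per locus, and per locus pair through the
Kronecker change of basis, with epistatic entries rescaled by the product
of the parent-column standard deviations. True *marginal* main effects add,
to each locus's own translation, the main-effect components of every
interaction involving it (with main effects zeroed), respecting the $j<k$
ordering when reading off components. This bookkeeping is exact: on an
enumerated two-locus population the reconstructed genotypic values match
the F∞ values to machine precision and the summed squared standardized
effects equal the population variance of $G$ exactly.

*What the generator does not emulate:* selection, ascertainment bias of
real chips, sex chromosomes, variable chromosome lengths, crossover
interference, multi-allelic QTL, genotype-by-environment interaction.
Passing tests therefore demonstrate correctness of the estimator under an
idealized neutral demography, not performance on real data — in
particular, real populations have allele-frequency spectra with far more
rare variants than the near-uniform spectrum here.

## Simulating only the analysis panel

Analyses use every 10th marker (5,227 of 52,273), with the QTL drawn on
that grid. Because loci mutate independently and recombination has no
interference, the joint genotype distribution at any subset of loci is
identical whether the remaining loci are simulated or not; the replicated
pipelines therefore simulate the base population at the thinned positions
only (about a tenth of the cost), while full-panel statistics
(heterozygosity, full-panel LD) use a full simulation
(`simulateFullPanel = TRUE`).

## Numerical choices and degenerate inputs

* Initialization: all effects zero, $\hat\sigma_e^2 = \mathrm{Var}(y)$;
  the first sweep therefore behaves like heavily shrunk single-marker
  regression, after which $\hat\sigma_e^2$ adapts.
* All-zero estimate vector at the convergence check: the criterion is 0/0;
  treated as converged when the change is also zero, otherwise iteration
  continues.
* Monomorphic or heterozygote-free training markers: inert columns (effects
  fixed at 0), not dropped; degenerate translation ($v = 0$) is an error
  for explicit calls and a zero-variance contribution inside the truth
  pipeline.
* MAF filtering: markers with training MAF ≤ 0.01 are excluded from the
  design; QTL eligibility uses MAF > 0.02 in the base generation.
* Missing genotypes are an error in the core; the file loader can mean-
  impute behind an explicit flag.
* Tie-breaking of allele orientation at $p = 0.5$: the allele counted by
  the dosage is treated as the frequent one.
* All randomness flows from one seeded generator per replicate; replicate
  seeds derive from the master seed and are recorded in the output.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen once: one full-panel
base-population run for the marker-statistic calibration; ten fitted
replicates of the thinned-panel 23-QTL pipeline per epistasis setting for
accuracy and convergence behaviour (the per-replicate sd of the simulated
additive variance is 0.578, so simulated-component means additionally pool
five extra architecture draws per replicate population — same generator,
same parameters, lower Monte Carlo error); and ten replicates of an M2 fit
on a 300-marker sub-panel (25 families, n = 1,000) with planted
interactions, standing in for the full-panel M2 fit, which is hours of
compute per dataset and out of desk scope. The full 52,273-marker M2 model
(about 1.3 billion effects per source) is rejected up front as infeasible.

## Known limitations

* The LE variance-component formula inherits the bias discussed above under
  strong LD (many linked QTL); compare with the empirical components.
* $\gamma_s$ is fixed, not estimated; a poor choice degrades both accuracy
  and convergence (an EM-style estimation of $\gamma_s$ is out of scope).
* With very low heritability and M2, the algorithm may fail the convergence
  criterion; such replicates are flagged and excluded from summaries, and
  their count reported.
* Accuracy of the point-mass/Laplace posterior mean is no substitute for
  full posterior uncertainty: no standard errors of effects are provided.
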