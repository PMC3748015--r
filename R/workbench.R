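#' Scenario configuration
#'
#' Bundles every knob of the simulation study. The defaults reproduce the
#' standard cattle-style study conditions: a 52,273-marker, 30 Morgan
#' genome simulated at effective size 100 for 400 generations with
#' per-locus mutation rate 2.5e-3; two training and two test generations of
#' 50 half-sib families x 20 offspring (n = 2,000 phenotyped); every 10th
#' marker analysed with a MAF > 0.01 filter; 23 QTL drawn at MAF > 0.02
#' with gamma_a = gamma_d = 0.005 and gamma = 1e-6 for epistatic sources
#' (the 230-QTL scenario uses gamma_a = gamma_d = 0.05); convergence
#' settings L = 1e-8 / kmax = 1000 for M0/M1 and L = 1e-6 / kmax = 200 for
#' M2.
#'
#' By default the base population is simulated at the thinned marker
#' positions only: loci mutate independently and recombine without
#' interference, so the joint genotype distribution at a subset of loci is
#' identical to simulating the full panel and subsetting, at a tenth of the
#' cost. Set `simulateFullPanel = TRUE` for full-panel statistics.
#'
#' @param nQtl number of QTL (23 or 230).
#' @param epistasis simulate epistatic effects?
#' @param h2 broad-sense heritability.
#' @param models character vector of models to fit per replicate.
#' @param thinStep analyse every `thinStep`-th marker.
#' @param mafThreshold training MAF filter for the analysis panel.
#' @param qtlMafMin MAF floor for QTL eligibility.
#' @param gammaA,gammaD,gammaEpi prior mixing probabilities (defaults by
#'   scenario).
#' @param L,kmax convergence settings; `NULL` uses the per-model defaults.
#' @param nReplicates number of replicates.
#' @param seed master seed; every replicate seed derives from it.
#' @param nMarkers,nChrom,chromLength,ne,mutationRate,nGenerations genome
#'   and base-population settings.
#' @param nFamilies,nOffspringPerFamily,nTrainGenerations,nTestGenerations
#'   breeding structure.
#' @param simulateFullPanel simulate all markers rather than only the
#'   thinned positions.
#' @return A classed list (`ScenarioConfig`).
#' @export
scenarioConfig <- function(nQtl = 23L, epistasis = FALSE, h2 = 0.5,
                           models = "M1", thinStep = 10L,
                           mafThreshold = 0.01, qtlMafMin = 0.02,
                           gammaA = NULL, gammaD = NULL, gammaEpi = 1e-6,
                           L = NULL, kmax = NULL, nReplicates = 10L,
                           seed = 1L, nMarkers = 52273L, nChrom = 30L,
                           chromLength = 1, ne = 100L,
                           mutationRate = 2.5e-3, nGenerations = 400L,
                           nFamilies = 50L, nOffspringPerFamily = 20L,
                           nTrainGenerations = 2L, nTestGenerations = 2L,
                           simulateFullPanel = FALSE) {
  scenario <- if (nQtl >= 100) "230" else "23"
  if (is.null(gammaA)) gammaA <- if (scenario == "230") 0.05 else 0.005
  if (is.null(gammaD)) gammaD <- gammaA
  cfg <- list(nQtl = as.integer(nQtl), scenario = scenario,
              epistasis = epistasis, h2 = h2, models = models,
              thinStep = as.integer(thinStep), mafThreshold = mafThreshold,
              qtlMafMin = qtlMafMin, gammaA = gammaA, gammaD = gammaD,
              gammaEpi = gammaEpi, L = L, kmax = kmax,
              nReplicates = as.integer(nReplicates), seed = as.integer(seed),
              nMarkers = as.integer(nMarkers), nChrom = as.integer(nChrom),
              chromLength = chromLength, ne = as.integer(ne),
              mutationRate = mutationRate,
              nGenerations = as.integer(nGenerations),
              nFamilies = as.integer(nFamilies),
              nOffspringPerFamily = as.integer(nOffspringPerFamily),
              nTrainGenerations = as.integer(nTrainGenerations),
              nTestGenerations = as.integer(nTestGenerations),
              simulateFullPanel = simulateFullPanel)
  stopifnot(cfg$h2 > 0, cfg$h2 < 1, cfg$thinStep >= 1,
            all(cfg$models %in% c("M0", "M1", "M2")))
  mAnalysis <- length(seq.int(cfg$thinStep, cfg$nMarkers, by = cfg$thinStep))
  if ("M2" %in% cfg$models && mAnalysis > 20000)
    stop("M2 with ", mAnalysis, " markers implies ",
         format(mAnalysis * (mAnalysis - 1) / 2, big.mark = ","),
         " effects per epistatic source; this exceeds feasible memory/time ",
         "(reduce the panel or drop M2)")
  cfg$fingerprint <- paste0("cfg", sum(utf8ToInt(paste(
    names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                       ""), collapse = ";")) * 1.0))
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file whose top-level keys are [scenarioConfig()] arguments.
#' @return A `ScenarioConfig`.
#' @export
readScenarioConfig <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
       else yaml::read_yaml(path)
  do.call(scenarioConfig, x)
}

#' Run one simulated replicate
#'
#' Simulate population, sample trait, thin markers, MAF-filter, build the
#' orthogonal design, fit each requested model and evaluate on the test
#' generations. Exposed mainly for the scenario harness; see
#' [runScenario()].
#'
#' @param config a `ScenarioConfig`.
#' @param seed replicate seed.
#' @param returnFits also return the fitted models and design blocks?
#' @param archDraws number of additional trait-architecture draws on the
#'   same simulated population; their true components are returned as
#'   `archStats`, giving lower-noise Monte Carlo means of the simulated
#'   variance components than the fitted replicates alone.
#' @return list with `rows` (one evaluation row per model), `truth`,
#'   `arch`, `archStats` and, if requested, `fits` and `blocks`.
#' @export
runReplicate <- function(config, seed, returnFits = FALSE, archDraws = 0L) {
  set.seed(seed)
  mapFull <- genomeMap(config$nChrom, config$chromLength, config$nMarkers)
  thinIdx <- thinMarkers(mapFull, config$thinStep)
  if (config$simulateFullPanel) {
    base <- simulateBasePopulation(mapFull, config$ne, config$mutationRate,
                                   config$nGenerations)
    baseT <- subsetMarkers(base, thinIdx)
  } else {
    baseT <- simulateBasePopulation(subsetMap(mapFull, thinIdx), config$ne,
                                    config$mutationRate, config$nGenerations)
  }
  stats400 <- computeMarkerStats(baseT, mafThreshold = config$qtlMafMin)
  pop <- breedStructuredGenerations(
    baseT, config$nFamilies, config$nOffspringPerFamily,
    config$nTrainGenerations, config$nTestGenerations,
    mutationRate = config$mutationRate)
  gen0 <- config$nGenerations
  trainIds <- individualsOf(pop, gen0 + seq_len(config$nTrainGenerations))
  testIds <- individualsOf(pop, gen0 + config$nTrainGenerations +
                             seq_len(config$nTestGenerations))
  genoTrain <- genotypes(pop, trainIds)
  genoTest <- genotypes(pop, testIds)

  arch <- sampleArchitecture(stats400, config$nQtl, config$scenario,
                             config$epistasis, config$h2, config$qtlMafMin)
  Gtrain <- genotypicValuesFinf(genoTrain, arch)
  Gtest <- genotypicValuesFinf(genoTest, arch)
  sigmaE2 <- calibrateResidualVariance(Gtrain, config$h2)
  arch@sigmaE2 <- sigmaE2
  y <- simulatePhenotypes(Gtrain, sigmaE2)

  statsTrain <- .markerStatsFromGeno(genoTrain, config$mafThreshold)
  retained <- which(statsTrain$retained)
  blocks <- buildDesignBlocks(genoTrain[, retained, drop = FALSE],
                              markers = retained)
  blocksTest <- applyCoding(blocks, genoTest[, retained, drop = FALSE])
  truth <- orthogonalTruth(arch, genoTrain)
  trueAddTest <- trueAdditiveValues(truth, genoTest)
  trueComp <- truth$components
  varG <- var(Gtrain)
  fits <- list()
  rows <- lapply(config$models, function(model) {
    prior <- priorSpec(model, length(retained), gammaA = config$gammaA,
                       gammaD = config$gammaD, gammaEpi = config$gammaEpi)
    fit <- iceFit(y, blocks, model, priors = prior, L = config$L,
                  kmax = config$kmax)
    if (returnFits) fits[[model]] <<- fit
    ev <- evaluateFit(fit, blocksTest, Gtest, trueAddTest)
    ev$criterionTrace <- I(list(fit@criterionTrace))
    ev
  })
  rows <- data.table::rbindlist(rows, fill = TRUE)
  rows$seed <- seed
  rows$nRetained <- length(retained)
  rows$mafDropped <- length(thinIdx) - length(retained)
  rows$varG <- varG
  rows$sigmaE2true <- sigmaE2
  rows$h2Realized <- unname(trueComp["a"] / (varG / config$h2))
  rows$trueRatio <- additiveRatio(trueComp)
  for (s in names(trueComp)) rows[[paste0("trueVar_", s)]] <- trueComp[s]
  out <- list(rows = rows, arch = arch, truth = truth)
  if (archDraws > 0L) {
    extra <- lapply(seq_len(archDraws), function(i) {
      archX <- sampleArchitecture(stats400, config$nQtl, config$scenario,
                                  config$epistasis, config$h2,
                                  config$qtlMafMin)
      truthX <- orthogonalTruth(archX, genoTrain)
      GX <- genotypicValuesFinf(genoTrain, archX)
      data.frame(trueVar_a = unname(truthX$components["a"]),
                 trueVar_d = unname(truthX$components["d"]),
                 trueRatio = additiveRatio(truthX$components),
                 varG = var(GX),
                 h2Realized = unname(truthX$components["a"] /
                                       (var(GX) / config$h2)))
    })
    out$archStats <- do.call(rbind, extra)
  }
  if (returnFits) {
    out$fits <- fits
    out$blocks <- blocks
  }
  out
}

.markerStatsFromGeno <- function(geno, mafThreshold) {
  n <- nrow(geno)
  n1 <- colSums(geno == 1L)
  n2 <- colSums(geno == 2L)
  p <- (n1 + 2 * n2) / (2 * n)
  maf <- pmin(p, 1 - p)
  data.frame(marker = seq_len(ncol(geno)), p = p, maf = maf,
             retained = maf > mafThreshold)
}

#' Run a replicated simulation scenario
#'
#' Executes [runReplicate()] for each replicate (seeds derived
#' deterministically from the master seed), collects per-replicate
#' evaluation rows and aggregates means and standard deviations over the
#' converged replicates.
#'
#' @param config a `ScenarioConfig`.
#' @param keepDetails keep per-replicate architectures and truths?
#' @param archDraws extra architecture draws per replicate (see
#'   [runReplicate()]); pooled into `archStats`.
#' @return list with `replicates` (data.frame, one row per replicate x
#'   model), `summary` (per model), `config`, `archStats` (when requested)
#'   and `details` (optional).
#' @export
runScenario <- function(config, keepDetails = FALSE, archDraws = 0L) {
  if (config$nReplicates == 0L)
    return(list(replicates = data.frame(), summary = data.frame(),
                config = config))
  set.seed(config$seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config$nReplicates)
  details <- list()
  rows <- vector("list", config$nReplicates)
  archStats <- list()
  for (r in seq_len(config$nReplicates)) {
    res <- runReplicate(config, repSeeds[r], archDraws = archDraws)
    res$rows$replicate <- r
    rows[[r]] <- res$rows
    if (archDraws > 0L) archStats[[r]] <- res$archStats
    if (keepDetails) details[[r]] <- res[c("arch", "truth")]
  }
  reps <- as.data.frame(data.table::rbindlist(rows, fill = TRUE))
  reps$fingerprint <- config$fingerprint
  out <- list(replicates = reps, summary = summarizeScenario(reps),
              config = config)
  if (archDraws > 0L) out$archStats <- do.call(rbind, archStats)
  if (keepDetails) out$details <- details
  out
}

#' Aggregate replicate reports
#'
#' Means (and standard deviations) over converged replicates per model, in
#' one of the standard table layouts: `"components"` (estimated and
#' simulated variance components plus accuracy), `"ratio"`
#' (additive-to-total ratios), `"accuracy"` (accuracy incl. top-10%), or
#' `"empirical"` (LE components vs empirical variances of predicted
#' values, epistasis pooled). Non-converged replicates are excluded and
#' counted.
#'
#' @param reps replicate data.frame from [runScenario()].
#' @param layout one of `"components"`, `"ratio"`, `"accuracy"`,
#'   `"empirical"`.
#' @return data.frame, one row per model.
#' @export
summarizeScenario <- function(reps, layout = c("components", "ratio",
                                               "accuracy", "empirical")) {
  layout <- match.arg(layout)
  if (!nrow(reps)) return(data.frame())
  out <- lapply(split(reps, reps$model), function(d) {
    conv <- d[d$converged, , drop = FALSE]
    n <- nrow(conv)
    msd <- function(x) if (n == 0) c(NA_real_, NA_real_) else
      c(mean(x), if (n > 1) sd(x) else NA_real_)
    base <- data.frame(model = d$model[1], nReplicates = nrow(d),
                       nConverged = n)
    cols <- switch(layout,
      components = grep("^(varLE_|trueVar_)|^(sigmaE2|sigmaE2true|accuracy|h2Realized)$",
                        names(d), value = TRUE),
      ratio = c("ratio", "trueRatio"),
      accuracy = c("accuracy", "topAccuracy"),
      empirical = grep("^(varLE_|varEmp_)", names(d), value = TRUE))
    for (cn in intersect(cols, names(d))) {
      v <- msd(conv[[cn]])
      base[[paste0("mean_", cn)]] <- v[1]
      base[[paste0("sd_", cn)]] <- v[2]
    }
    if (layout == "empirical") {
      epi <- intersect(paste0("varLE_", c("aa", "ad", "da", "dd")), names(d))
      if (length(epi) && n > 0)
        base$mean_varLE_epi <- mean(rowSums(conv[, epi, drop = FALSE]))
    }
    base
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
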