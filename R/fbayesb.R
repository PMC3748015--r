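#' Laplace rate implied by unit total prior variance
#'
#' With prior variance `Var(g) = gamma * 2 / lambda^2` per effect and
#' `m` effects in a source, requiring the total prior variance of the
#' source to be 1 gives `lambda = sqrt(2 / (m * gamma))`.
#'
#' @param gamma mixing probability in (0, 1].
#' @param m number of effects in the source (>= 1).
#' @return The Laplace rate `lambda`.
#' @examples
#' deriveLambda(0.005, 5227)    # ~0.27664
#' deriveLambda(1e-6, 13658151) # ~0.38269
#' @export
deriveLambda <- function(gamma, m) {
  if (any(gamma <= 0) || any(gamma > 1) || any(m < 1))
    stop("gamma must lie in (0, 1] and m must be >= 1")
  sqrt(2 / (m * gamma))
}

#' Mean of a truncated normal distribution
#'
#' Expected value of `N(mean, variance)` truncated at zero: side
#' `"above_zero"` keeps the upper part (Z > 0), `"below_zero"` the lower.
#' Evaluated via log-scale Mills ratios, stable for `|mean|/sd` of 30 and
#' beyond.
#'
#' @param mean,variance parameters of the untruncated normal.
#' @param side "above_zero" or "below_zero".
#' @return The truncated mean.
#' @examples
#' truncatedNormalMean(0, 1, "above_zero") # sqrt(2/pi)
#' @export
truncatedNormalMean <- function(mean, variance,
                                side = c("above_zero", "below_zero")) {
  side <- match.arg(side)
  if (any(variance <= 0)) stop("variance must be positive")
  sd <- sqrt(variance)
  z <- mean / sd
  if (side == "above_zero")
    mean + sd * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  else
    mean - sd * exp(dnorm(z, log = TRUE) -
                    pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

#' Posterior mean of a single effect under the mixture prior
#'
#' Analytic conditional expectation `E(g | Y)` where `Y ~ N(g, sigma2)` and
#' `g` has the point-mass/Laplace mixture prior with mixing probability
#' `gamma` and rate `lambda`. The three mixture terms (positive Laplace
#' branch, negative branch, point mass) are combined through truncated
#' normal means and evaluated in the log domain to avoid overflow of
#' `exp(lambda * |Y|)`.
#'
#' @param Y least-squares effect summary (vectorised).
#' @param sigma2 its sampling variance (> 0), recycled against `Y`.
#' @param lambda Laplace rate (> 0).
#' @param gamma mixing probability in (0, 1].
#' @return The posterior mean(s); always shrunk towards zero and carrying
#'   the sign of `Y`.
#' @export
posteriorMeanEffect <- function(Y, sigma2, lambda, gamma) {
  if (any(!is.finite(Y)) || any(!is.finite(sigma2)))
    stop("non-finite inputs")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (lambda <= 0 || gamma <= 0 || gamma > 1)
    stop("invalid prior parameters")
  cpp_posterior_mean(as.numeric(Y), as.numeric(sigma2), lambda, gamma)
}

#' Univariate effect summary from the running residual
#'
#' Realises the phenotypes corrected for all effects except the current one
#' as `residual + column * currentEstimate`, and returns its least-squares
#' coefficient on the column, `Y = (x'x)^{-1} x' y_{-j}`, together with the
#' sampling variance `sigma2 = (x'x)^{-1} sigmaE2`. This is the Gaussian
#' summary the posterior-mean update consumes.
#'
#' @param residual current residual vector (phenotypes minus all fitted
#'   effects).
#' @param currentEstimate the effect's current estimate.
#' @param column its covariate column.
#' @param sigmaE2 current residual variance estimate.
#' @return list with `Y` and `sigma2`.
#' @export
effectSummary <- function(residual, currentEstimate, column, sigmaE2) {
  xtx <- sum(column^2)
  if (xtx <= 0) stop("inert column: x'x is zero (effect stays 0)")
  ymj <- residual + column * currentEstimate
  list(Y = sum(column * ymj) / xtx, sigma2 = sigmaE2 / xtx)
}

#' Construct a prior specification
#'
#' One mixing probability and Laplace rate per active source of the chosen
#' model; rates default to the unit-total-prior-variance rule of
#' [deriveLambda()] applied to the per-source effect counts.
#'
#' @param model "M0", "M1" or "M2".
#' @param m number of markers in the design.
#' @param gammaA,gammaD,gammaEpi mixing probabilities for the additive,
#'   dominance and (all four) epistatic sources.
#' @param lambda optional named numeric overriding the derived rates.
#' @return A [PriorSpec-class].
#' @export
priorSpec <- function(model = c("M1", "M0", "M2"), m, gammaA = 0.005,
                      gammaD = gammaA, gammaEpi = 1e-6, lambda = NULL) {
  model <- match.arg(model)
  md <- modelDesign(model, m)
  gam <- c(a = gammaA, d = gammaD, aa = gammaEpi, ad = gammaEpi,
           da = gammaEpi, dd = gammaEpi)[md$sources]
  lam <- deriveLambda(gam, md$m)
  if (!is.null(lambda)) lam[names(lambda)] <- lambda
  new("PriorSpec", sources = md$sources, gamma = gam,
      lambda = setNames(as.numeric(lam), md$sources), m = md$m)
}

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec:\n")
  for (s in object@sources)
    cat(sprintf("  %-2s m = %12.0f  gamma = %-8g lambda = %.5f\n", s,
                object@m[s], object@gamma[s], object@lambda[s]))
})

#' Fit marker effects by iterated conditional expectation
#'
#' Centers the phenotypes, then cycles over all effects (sources in the
#' order a, d, aa, ad, da, dd; within a source in index order, epistatic
#' effects in row-major upper-triangle order), setting each effect to its
#' analytic posterior mean given the phenotypes corrected for all other
#' current estimates (Gauss-Seidel style via a maintained residual). The
#' residual variance is re-estimated once per outer iteration as
#' `RSS / (n - 1)`. Iterations stop when the relative norm change
#' of the concatenated estimate vector (ratio of Euclidean norms) is at most `L`, or at `kmax`
#' (convergence flag `FALSE`; not an error).
#'
#' Interaction covariates are streamed from the two parent columns; peak
#' working storage is independent of the squared marker count (beyond the
#' epistatic estimate vectors themselves).
#'
#' @param y numeric phenotypes of the training individuals.
#' @param blocks standardized training [DesignBlocks-class].
#' @param model "M0", "M1" or "M2".
#' @param priors a [PriorSpec-class]; default built from `gammaA`,
#'   `gammaD`, `gammaEpi`.
#' @param gammaA,gammaD,gammaEpi mixing probabilities used when `priors`
#'   is `NULL`.
#' @param L convergence threshold; defaults to 1e-8 (M0/M1) or 1e-6 (M2).
#' @param kmax iteration cap; defaults to 1000 (M0/M1) or 200 (M2).
#' @param covariates optional numeric matrix of nuisance covariates
#'   (n x q); their least-squares estimates are removed from the phenotypes
#'   anew in every outer iteration and are never shrunk.
#' @param checkEvery interval (outer iterations) for the from-scratch
#'   residual bookkeeping check; 0 disables it.
#' @return A [FitResult-class].
#' @export
iceFit <- function(y, blocks, model = c("M1", "M0", "M2"), priors = NULL,
                   gammaA = 0.005, gammaD = gammaA, gammaEpi = 1e-6,
                   L = NULL, kmax = NULL, covariates = NULL,
                   checkEvery = 10L) {
  model <- match.arg(model)
  if (!is(blocks, "DesignBlocks")) stop("blocks must be DesignBlocks")
  if (!blocks@standardized)
    stop("blocks must be standardized (see standardizeBlocks)")
  n <- length(y)
  if (n != nrow(blocks@Xa)) stop("phenotype/design size mismatch")
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  m <- ncol(blocks@Xa)
  if (is.null(priors))
    priors <- priorSpec(model, m, gammaA = gammaA, gammaD = gammaD,
                        gammaEpi = gammaEpi)
  if (is.null(L)) L <- if (model == "M2") 1e-6 else 1e-8
  if (is.null(kmax)) kmax <- if (model == "M2") 200L else 1000L
  yc <- y - mean(y)
  gam <- lam <- setNames(rep(1, 6), .sourceNames)
  gam[priors@sources] <- priors@gamma
  lam[priors@sources] <- priors@lambda
  W <- Winv <- NULL
  if (!is.null(covariates)) {
    W <- as.matrix(covariates)
    if (nrow(W) != n) stop("covariate rows must match phenotypes")
    Winv <- W %*% solve(crossprod(W))
  }
  modelInt <- match(model, c("M0", "M1", "M2")) - 1L
  res <- cpp_ice_fit(yc, blocks@Xa, blocks@Xd, modelInt,
                     unname(gam[.sourceNames]), unname(lam[.sourceNames]),
                     L, as.integer(kmax),
                     as.integer(blocks@coding$inertA),
                     as.integer(blocks@coding$inertD),
                     W, Winv, as.integer(checkEvery))
  new("FitResult", estimates = res$estimates, sigmaE2 = res$sigmaE2,
      iterations = res$iterations, converged = res$converged,
      criterionTrace = res$criterionTrace, sigmaTrace = res$sigmaTrace,
      model = model, priors = priors, residual = res$residual,
      residualCheck = res$residualCheck)
}

#' @rdname FitResult-class
#' @export
setMethod("estimates", "FitResult", function(x) x@estimates)

#' @rdname FitResult-class
#' @export
setMethod("sigmaE2", "FitResult", function(x) x@sigmaE2)

#' @rdname FitResult-class
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

#' @rdname FitResult-class
#' @export
setMethod("iterations", "FitResult", function(x) x@iterations)

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult (%s): %d iteration(s), %sconverged, sigmaE2 = %.4f\n",
    object@model, object@iterations,
    if (object@converged) "" else "NOT ", object@sigmaE2))
  nz <- vapply(object@estimates, function(g) sum(g != 0), 0L)
  cat("  non-zero effects:",
      paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
})

#' Predict direct genetic values
#'
#' `DGV_i = sum_s X_s ghat_s` for the individuals in `blocks`, which must
#' carry the training coding (see [applyCoding()]). The additive part is
#' the breeding-value proxy.
#'
#' @param fit a [FitResult-class].
#' @param blocks [DesignBlocks-class] of the target individuals.
#' @return list with `total` (numeric vector) and `parts` (matrix,
#'   individuals x active sources).
#' @export
predictDgv <- function(fit, blocks) {
  md <- modelDesign(fit@model, ncol(blocks@Xa))
  if (length(fit@estimates$a) != ncol(blocks@Xa))
    stop("marker mismatch between fit and target panel")
  modelInt <- match(fit@model, c("M0", "M1", "M2")) - 1L
  parts <- cpp_predict_parts(blocks@Xa, blocks@Xd, fit@estimates, modelInt)
  colnames(parts) <- md$sources
  rownames(parts) <- blocks@ids
  list(total = rowSums(parts), parts = parts)
}
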