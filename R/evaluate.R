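#' Accuracy of genetic value prediction
#'
#' Pearson correlation between predicted and simulated (true) direct
#' genetic values in a validation set.
#'
#' @param predicted,true numeric vectors (>= 3 individuals).
#' @return Correlation, or `NA` if either vector is constant.
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) != length(true) || length(predicted) < 3)
    stop("need at least three paired values")
  if (sd(predicted) == 0 || sd(true) == 0) return(NA_real_)
  cor(predicted, true)
}

#' Variance components under linkage equilibrium
#'
#' With standardized covariates, the genetic variance of a source is
#' estimated as the sum of squared effect estimates,
#' `sigma_s^2 = sum_j ghat_s,j^2`. Under linkage disequilibrium this is an
#' approximation: covariances of linked loci are ignored.
#'
#' @param fit a [FitResult-class] (or a named list of estimate vectors).
#' @return Named numeric vector of per-source components.
#' @export
varianceComponentsLE <- function(fit) {
  est <- if (is(fit, "FitResult")) fit@estimates else fit
  vapply(est, function(g) sum(g^2), numeric(1))
}

#' Empirical variance components of predicted genetic values
#'
#' Empirical variances of the per-source predicted genetic values in a
#' validation set; the four epistatic parts are summed into a single
#' epistasis component when `pooledEpistasis` is `TRUE`.
#'
#' @param parts matrix of per-source predicted values (individuals x
#'   sources), as returned by [predictDgv()].
#' @param pooledEpistasis pool aa/ad/da/dd into one component?
#' @return Named numeric vector of empirical variances.
#' @export
empiricalVarianceComponents <- function(parts, pooledEpistasis = TRUE) {
  if (nrow(parts) < 2) stop("variance undefined for fewer than 2 individuals")
  out <- apply(parts, 2, var)
  epi <- intersect(colnames(parts), c("aa", "ad", "da", "dd"))
  if (pooledEpistasis && length(epi)) {
    pooled <- var(rowSums(parts[, epi, drop = FALSE]))
    out <- c(out[setdiff(colnames(parts), epi)], epi = unname(pooled))
  }
  out
}

#' Additive share of the total genetic variance
#'
#' @param components named numeric vector of per-source genetic variance
#'   components (residual excluded); must contain `"a"`.
#' @return `sigma_a^2 / sum(components)`.
#' @export
additiveRatio <- function(components) {
  tot <- sum(components)
  if (tot <= 0) stop("total genetic variance is zero")
  unname(components["a"] / tot)
}

#' Accuracy among the top fraction of animals
#'
#' Selects the `ceiling(fraction * n)` individuals with the best predicted
#' additive genetic value (the breeding value) and returns the correlation
#' of predicted and true additive values within the selection.
#'
#' @param predictedAdditive,trueAdditive numeric vectors.
#' @param fraction selected fraction in (0, 1].
#' @return Correlation within the selection, `NA` if fewer than 3 selected.
#' @export
topFractionAccuracy <- function(predictedAdditive, trueAdditive,
                                fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- length(predictedAdditive)
  sel <- order(predictedAdditive, decreasing = TRUE)[seq_len(ceiling(fraction * n))]
  if (length(sel) < 3) return(NA_real_)
  if (sd(predictedAdditive[sel]) == 0 || sd(trueAdditive[sel]) == 0)
    return(NA_real_)
  cor(predictedAdditive[sel], trueAdditive[sel])
}

#' Largest estimated epistatic interactions
#'
#' Decodes the upper-triangle effect vectors of an M2 fit and returns the
#' `n` interactions with the largest absolute estimates across the four
#' epistatic sources, with marker indices resolved against the design's
#' panel.
#'
#' @param fit an M2 [FitResult-class].
#' @param blocks the training [DesignBlocks-class] of the fit.
#' @param n number of interactions to return.
#' @return data.frame with `source`, `j`, `k` (panel marker indices) and
#'   `estimate`, sorted by `|estimate|`.
#' @export
topInteractions <- function(fit, blocks, n = 10) {
  if (fit@model != "M2") stop("interactions exist only for M2 fits")
  m <- ncol(blocks@Xa)
  jj <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  kk <- sequence((m - 1L):1L) + jj
  out <- do.call(rbind, lapply(c("aa", "ad", "da", "dd"), function(s) {
    g <- fit@estimates[[s]]
    nz <- which(g != 0)
    if (!length(nz)) return(NULL)
    data.frame(source = s, j = blocks@markers[jj[nz]],
               k = blocks@markers[kk[nz]], estimate = g[nz])
  }))
  if (is.null(out))
    return(data.frame(source = character(), j = integer(), k = integer(),
                      estimate = numeric()))
  out <- out[order(-abs(out$estimate)), ]
  rownames(out) <- NULL
  head(out, n)
}

#' Evaluate a fitted model on a validation set
#'
#' Computes the standard report for one fit: total-DGV accuracy, top-10%
#' additive accuracy, LE variance components, empirical variance components
#' of the predicted per-source values (epistasis pooled), and the estimated
#' additive-to-total ratio.
#'
#' @param fit a [FitResult-class].
#' @param blocksTest validation [DesignBlocks-class] carrying the training
#'   coding.
#' @param trueDgv simulated total genotypic values of the validation
#'   individuals.
#' @param trueAdditive simulated true additive values (optional; enables
#'   the top-fraction accuracy).
#' @param topFraction fraction for the selected-animals accuracy.
#' @return One-row data.frame.
#' @export
evaluateFit <- function(fit, blocksTest, trueDgv, trueAdditive = NULL,
                        topFraction = 0.1) {
  pred <- predictDgv(fit, blocksTest)
  comp <- varianceComponentsLE(fit)
  emp <- empiricalVarianceComponents(pred$parts)
  out <- data.frame(
    model = fit@model,
    converged = fit@converged,
    iterations = fit@iterations,
    sigmaE2 = fit@sigmaE2,
    accuracy = accuracy(pred$total, trueDgv),
    ratio = additiveRatio(comp))
  for (s in names(comp)) out[[paste0("varLE_", s)]] <- unname(comp[s])
  for (s in names(emp)) out[[paste0("varEmp_", s)]] <- unname(emp[s])
  out$topAccuracy <- if (is.null(trueAdditive)) NA_real_ else
    topFractionAccuracy(pred$parts[, "a"], trueAdditive, topFraction)
  out
}
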