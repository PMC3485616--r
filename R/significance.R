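#' Null mean and variance of win percentage
#'
#' Under the null hypothesis every classifier has the same chance `q` of
#' winning each feature set, so win percentage is a weighted average of
#' Bernoulli(q) variables with the rank-based selection weights: mean `q`,
#' variance `q (1 - q) sum(w_i^2)`.
#'
#' @param weights selection weights (sum to 1), e.g. from
#'   [selectionWeights()] or [rankWeights()].
#' @param q null win chance per feature set.
#' @return named vector with elements `mean` and `variance`.
#' @export
nullMoments <- function(weights, q = 1 / 6) {
  stopifnot(q > 0, q < 1, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  c(mean = q, variance = q * (1 - q) * sum(weights^2))
}

#' Fit the beta null model for win percentage
#'
#' Method-of-moments beta distribution with mean `q` and the null variance:
#' `alpha = q (1/sum(w^2) - 1)`, `beta = (1 - q) (1/sum(w^2) - 1)`.  Critical
#' win percentages are the two-sided quantiles at the Bonferroni-adjusted
#' per-test level `familyAlpha / (nClassifiers - 1)` (for six classifiers at
#' family level 0.05 this is 0.01, i.e. the 0.5th and 99.5th percentiles).
#' When all weight sits on one sample (`sum(w^2) = 1`, N very large relative
#' to the pool) the null is a single Bernoulli; the model is flagged
#' degenerate and the bounds collapse to (0, 1).
#'
#' @inheritParams nullMoments
#' @param nClassifiers number of candidate classifiers (default 6; also the
#'   default for `q = 1/nClassifiers`).
#' @param familyAlpha family-wise false positive rate.
#' @return A [WinNullModel-class].
#' @export
fitNullBeta <- function(weights, q = 1 / nClassifiers, nClassifiers = 6L,
                        familyAlpha = 0.05) {
  sw2 <- sum(weights^2)
  if (sw2 > 1 + 1e-12) stop("sum of squared weights exceeds 1")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  stopifnot(q > 0, q < 1, nClassifiers >= 2L)
  sw2 <- min(sw2, 1)
  degenerate <- 1 - sw2 < 1e-12
  if (degenerate) {
    a <- 0; b <- 0; lo <- 0; hi <- 1
  } else {
    a <- q * (1 / sw2 - 1)
    b <- (1 - q) * (1 / sw2 - 1)
    level <- familyAlpha / (nClassifiers - 1L)
    lo <- stats::qbeta(level / 2, a, b)
    hi <- stats::qbeta(1 - level / 2, a, b)
  }
  new("WinNullModel", q = q, sumW2 = sw2, alphaShape = a, betaShape = b,
      criticalLow = lo, criticalHigh = hi,
      nClassifiers = as.integer(nClassifiers), degenerate = degenerate)
}

#' Critical win percentages
#'
#' Two-sided critical bounds of the fitted beta null at the
#' Bonferroni-adjusted per-test level `familyAlpha / (nClassifiers - 1)`.
#'
#' @param null a [WinNullModel-class].
#' @param familyAlpha family-wise false positive rate.
#' @param nClassifiers number of candidate classifiers.
#' @return numeric `c(low, high)`.
#' @export
criticalValues <- function(null, familyAlpha = 0.05,
                           nClassifiers = null@nClassifiers) {
  if (null@degenerate) return(c(low = 0, high = 1))
  level <- familyAlpha / (nClassifiers - 1L)
  c(low = stats::qbeta(level / 2, null@alphaShape, null@betaShape),
    high = stats::qbeta(1 - level / 2, null@alphaShape, null@betaShape))
}

#' Test win percentages against the null model
#'
#' Flags each classifier's win percentage as significantly high, significantly
#' low, or insignificant relative to the critical bounds.
#'
#' @param win named vector of win percentages (values in \[0, 1\]).
#' @param null a [WinNullModel-class].
#' @param familyAlpha family-wise level used to recompute the bounds
#'   (defaults to the bounds stored in the model).
#' @return data.frame with classifier, win, criticalLow, criticalHigh and
#'   verdict.
#' @export
testSignificance <- function(win, null, familyAlpha = NULL) {
  stopifnot(all(win >= 0), all(win <= 1 + 1e-12))
  bounds <- if (is.null(familyAlpha))
    c(low = null@criticalLow, high = null@criticalHigh)
  else criticalValues(null, familyAlpha)
  verdict <- ifelse(win > bounds["high"], "significantly high",
                    ifelse(win < bounds["low"], "significantly low",
                           "insignificant"))
  data.frame(classifier = if (is.null(names(win)))
    paste0("c", seq_along(win)) else names(win),
    win = as.numeric(win), criticalLow = unname(bounds["low"]),
    criticalHigh = unname(bounds["high"]), verdict = unname(verdict),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Significance report over a win curve
#'
#' For each N on a discrete win curve, fits the beta null from the selection
#' weights at that N and reports each classifier's verdict.  The optional
#' `effectiveM` down-weights the pool size to the number of independent
#' feature sets (feature sets sharing features are correlated, which
#' inflates the nominal M); by default the observed pool size is used.
#'
#' @param winTable a [WinTable-class].
#' @param N vector of subsample sizes.
#' @param q null win chance (default 1/nClassifiers).
#' @param nClassifiers number of candidate classifiers.
#' @param familyAlpha family-wise false positive rate.
#' @param effectiveM optional effective number of independent samples used
#'   for the null weights instead of the pool size M.
#' @param labels classifier labels (default: all labels seen in the table).
#' @return data.frame with one row per (N, classifier): win, criticalLow,
#'   criticalHigh, verdict.
#' @export
significanceReport <- function(winTable, N, q = 1 / nClassifiers,
                               nClassifiers = 6L, familyAlpha = 0.05,
                               effectiveM = NULL, labels = NULL) {
  stopifnot(is(winTable, "WinTable"))
  if (is.null(labels)) labels <- sort(unique(unlist(winTable@winners)))
  out <- lapply(N, function(n) {
    w <- if (is.null(effectiveM)) selectionWeights(winTable, n)
         else rankWeights(effectiveM, n)
    null <- fitNullBeta(w, q = q, nClassifiers = nClassifiers,
                        familyAlpha = familyAlpha)
    res <- testSignificance(discreteWin(winTable, n, labels), null)
    cbind(N = n, res)
  })
  do.call(rbind, out)
}

#' Write a significance report as delimited text
#'
#' @param report result of [significanceReport()].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeSignificanceReport <- function(report, path, sep = "\t") {
  utils::write.table(report, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
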