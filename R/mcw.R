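#' Planning calculus for randomized wrapper feature selection
#'
#' The Monte Carlo wrapper succeeds when its best feature set lies in the top
#' fraction `p` of all feature sets; with `N` draws with replacement the
#' failure probability is `(1 - p)^N = epsilon`.  These three functions solve
#' that relation for each quantity in turn.
#'
#' `requiredIterations()` returns the smallest integer `N` with
#' `(1 - p)^N <= epsilon`.  `topFraction()` returns the exact
#' `p = 1 - epsilon^(1/N)`; `method = "maclaurin"` gives the first-order
#' approximation `-log(epsilon) / N`, accurate to within 1% relative error
#' for large `N`.
#'
#' @param epsilon tolerated failure probability, in (0, 1).
#' @param topFraction the top fraction `p` of feature sets, in (0, 1).
#' @param nIterations number of random draws `N` (>= 1).
#' @param method exact solution or first-order Maclaurin approximation.
#' @return the missing quantity of the (epsilon, p, N) triple.
#' @examples
#' requiredIterations(0.001, 0.499)  # 10
#' topFraction(0.001, 100)           # ~0.0667
#' failureProbability(topFraction(0.001, 100), 100)  # 0.001
#' @export
requiredIterations <- function(epsilon, topFraction) {
  stopifnot(epsilon > 0, epsilon < 1)
  if (topFraction <= 0) stop("topFraction must be positive (else N is infinite)")
  stopifnot(topFraction < 1)
  n <- ceiling(log(epsilon) / log1p(-topFraction) - 1e-9)
  # guard the ceiling against float noise on exact solutions
  if ((n - 1) * log1p(-topFraction) <= log(epsilon)) n <- n - 1
  max(1L, as.integer(n))
}

#' @rdname requiredIterations
#' @export
topFraction <- function(epsilon, nIterations,
                        method = c("exact", "maclaurin")) {
  stopifnot(epsilon > 0, epsilon < 1, nIterations >= 1)
  method <- match.arg(method)
  if (method == "exact") -expm1(log(epsilon) / nIterations)
  else -log(epsilon) / nIterations
}

#' @rdname requiredIterations
#' @export
failureProbability <- function(topFraction, nIterations) {
  stopifnot(topFraction > 0, topFraction < 1, nIterations >= 1)
  exp(nIterations * log1p(-topFraction))
}

#' Expected fraction of unique feature sets when sampling with replacement
#'
#' Drawing `nDraws` feature sets with replacement from a space of size
#' `spaceSize` yields on average `(1 - (1 - 1/M)^N) * M / N` unique sets.
#' At `N = M` (large `M`) this is `1 - exp(-1)`, about 63.2%; at
#' `M = 1e6, N = 1e5` about 95%, so with-replacement sampling costs only a
#' few percent of coverage in the regimes the wrapper uses.
#'
#' @param spaceSize total number of feature sets `M`.
#' @param nDraws number of draws `N`.
#' @return expected unique fraction in (0, 1].
#' @export
expectedUniqueFraction <- function(spaceSize, nDraws) {
  stopifnot(spaceSize >= 1, nDraws >= 1)
  -expm1(nDraws * log1p(-1 / spaceSize)) * spaceSize / nDraws
}

#' Monte Carlo wrapper (MCW) feature selection
#'
#' Draws `nIterations` feature sets with replacement, scores each with
#' [bestPerformance()] (all candidate classifiers, shared CV folds), and
#' keeps the running maximum.  When a new strict maximum is found, the
#' credited classifier is drawn uniformly at random from the tying winners;
#' later ties with the incumbent maximum do not replace it.
#'
#' @inheritParams bestPerformance
#' @param nIterations number of feature sets to draw and evaluate (N).
#' @param sampler optional function(i) returning a feature set (column
#'   indices/names) for draw i; it may implement any distribution over the
#'   space, e.g. weighting subsets or a prior on subset size. The default
#'   draws uniformly with replacement from all C(F, 2) feature pairs.
#' @param seed integer seed driving the sampler and the random winner choice
#'   (one stream, consumed in draw order); CV folds use `cv@seed` on an
#'   isolated stream.
#' @return A [MCWResult-class].
#' @export
runMCW <- function(x, labels, nIterations, specs = classifierRoster(),
                   cv = cvConfig(), sampler = NULL, seed = 1L) {
  stopifnot(nIterations >= 1)
  x <- as.matrix(x)
  if (ncol(x) < 2L && is.null(sampler))
    stop("feature space is empty: need >= 2 features for pair sampling")
  specs <- .asSpecList(specs)
  .checkCvFeasible(labels, cv)
  folds <- .cvFolds(labels, cv)
  ids <- colnames(x)
  if (is.null(sampler))
    sampler <- function(i) {
      p <- sort(sample.int(ncol(x), 2L, replace = FALSE))
      if (is.null(ids)) p else ids[p]
    }
  withr::local_seed(as.integer(seed))
  xOut <- -Inf; sOut <- character(0); cOut <- NA_character_
  for (i in seq_len(nIterations)) {
    fs <- sampler(i)
    ps <- .bestPerformanceFolds(x, labels, fs, specs, folds, cv@nFolds)
    if (ps@x > xOut) {
      xOut <- ps@x
      sOut <- ps@featureSet
      cOut <- if (length(ps@winners) == 1L) ps@winners
              else sample(ps@winners, 1L)
    }
  }
  new("MCWResult", featureSet = sOut, performance = xOut, classifier = cOut,
      nIterations = as.integer(nIterations), seed = as.integer(seed))
}

#' Write an MCW result as delimited text and JSON
#'
#' @param result a [MCWResult-class].
#' @param path output stem; writes `<path>.tsv` and `<path>.json`.
#' @export
writeMCWResult <- function(result, path) {
  df <- data.frame(featureSet = paste(result@featureSet, collapse = ","),
                   performance = result@performance,
                   classifier = result@classifier,
                   nIterations = result@nIterations, seed = result@seed)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(featureSet = result@featureSet, performance = result@performance,
         classifier = result@classifier, nIterations = result@nIterations,
         seed = result@seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
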