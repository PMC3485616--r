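#' Cross-validation configuration
#'
#' The coarse default (two iterations of three-fold) keeps the per-feature-set
#' cost low enough to explore a large feature space; [fineCvConfig()] gives
#' the finer 20 x 5-fold scheme used to reanalyse top feature sets.  Fold
#' partitions depend only on the labels and the seed, so every classifier is
#' scored on identical folds and per-fold scores are paired.
#'
#' @param nFolds folds per iteration.
#' @param nIterations independent fold partitions.
#' @param seed integer seed for fold construction.
#' @param stratified partition each class separately (default), so each fold
#'   contains both classes and balanced accuracy is defined.
#' @return A [CVConfig-class].
#' @export
cvConfig <- function(nFolds = 3L, nIterations = 2L, seed = 1L,
                     stratified = TRUE) {
  new("CVConfig", nFolds = as.integer(nFolds),
      nIterations = as.integer(nIterations), seed = as.integer(seed),
      stratified = stratified)
}

#' @rdname cvConfig
#' @export
fineCvConfig <- function(seed = 1L) cvConfig(5L, 20L, seed)

# Fold assignments: list (one per iteration) of integer vectors in 1..nFolds.
# Uses an isolated RNG stream so callers' streams are untouched.
.cvFolds <- function(labels, cv) {
  labels <- as.factor(labels)
  n <- length(labels)
  withr::with_seed(cv@seed, {
    lapply(seq_len(cv@nIterations), function(it) {
      fold <- integer(n)
      if (cv@stratified) {
        for (lev in levels(labels)) {
          idx <- which(labels == lev)
          fold[sample(idx)] <- rep_len(seq_len(cv@nFolds), length(idx))
        }
      } else {
        fold[sample.int(n)] <- rep_len(seq_len(cv@nFolds), n)
      }
      fold
    })
  })
}

#' Balanced accuracy
#'
#' The average of sensitivity and specificity (binary-label AUC). Equals
#' plain accuracy when class proportions are equal; for skewed classes it is
#' the accuracy expected under balanced proportions.  An optional sensitivity
#' weight generalises to a weighted average.
#'
#' @param truth true two-class labels.
#' @param predicted predicted labels, same length.
#' @param weight weight on sensitivity (default 0.5, the plain average).
#' @return weighted average of sensitivity and specificity, or `NA` when a
#'   class is absent from `truth` (the metric is undefined for that split).
#' @examples
#' balancedAccuracy(c(1, 1, 0, 0), c(1, 1, 1, 0))  # sens 1, spec 0.5 -> 0.75
#' @export
balancedAccuracy <- function(truth, predicted, weight = 0.5) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  truth <- as.factor(truth)
  lev <- levels(truth)
  if (length(lev) != 2L) stop("truth must have exactly two class levels")
  predicted <- as.character(predicted)
  pos <- truth == lev[2L]
  if (!any(pos) || all(pos)) return(NA_real_)
  sens <- mean(predicted[pos] == lev[2L])
  spec <- mean(predicted[!pos] == lev[1L])
  weight * sens + (1 - weight) * spec
}

# Per-fold balanced accuracies for one feature set and one spec, given
# precomputed folds. Folds whose test split lacks a class yield NA.
.cvFoldScores <- function(x, labels, featureSet, spec, folds, nFolds) {
  xs <- x[, featureSet, drop = FALSE]
  labels <- as.factor(labels)
  scores <- numeric(0)
  for (fold in folds) {
    for (f in seq_len(nFolds)) {
      test <- fold == f
      if (length(unique(labels[!test])) < 2L) { scores <- c(scores, NA); next }
      model <- fitGaussianBayes(xs[!test, , drop = FALSE], labels[!test], spec)
      pred <- predict(model, xs[test, , drop = FALSE])
      scores <- c(scores, balancedAccuracy(labels[test], pred))
    }
  }
  scores
}

.checkCvFeasible <- function(labels, cv) {
  counts <- table(labels)
  if (length(counts) != 2L) stop("exactly two classes are required")
  if (min(counts) < cv@nFolds)
    stop("each class needs at least nFolds = ", cv@nFolds, " samples")
}

#' Cross-validated balanced accuracy of one classifier on one feature set
#'
#' Mean balanced accuracy over `nIterations x nFolds` held-out folds. The
#' fold partitions are a deterministic function of the labels and the CV
#' seed, so repeated calls and calls with different classifiers reuse
#' identical folds.  Folds whose held-out split lacks a class are skipped.
#'
#' @param x samples-by-features matrix.
#' @param labels two-class label vector.
#' @param featureSet column indices or names of the features to use jointly.
#' @param spec a [ClassifierSpec-class] or label.
#' @param cv a [CVConfig-class].
#' @return mean cross-validated balanced accuracy in \[0, 1\].
#' @export
crossValidate <- function(x, labels, featureSet, spec, cv = cvConfig()) {
  if (is.character(spec) && length(spec) == 1L) spec <- classifierSpec(spec)
  .checkCvFeasible(labels, cv)
  x <- as.matrix(x)
  folds <- .cvFolds(labels, cv)
  scores <- .cvFoldScores(x, labels, featureSet, spec, folds, cv@nFolds)
  if (all(is.na(scores))) stop("no fold had both classes held out")
  mean(scores, na.rm = TRUE)
}

# Rounding used to detect exact performance ties: with identical folds, tying
# classifiers produce identical fold predictions, so 12 decimals separates
# genuine ties from float noise.
.TIE_DIGITS <- 12L

.bestPerformanceFolds <- function(x, labels, featureSet, specs, folds,
                                  nFolds) {
  perf <- vapply(specs, function(sp)
    mean(.cvFoldScores(x, labels, featureSet, sp, folds, nFolds),
         na.rm = TRUE), numeric(1))
  if (all(is.na(perf))) stop("no fold had both classes held out")
  labs <- vapply(specs, function(sp) sp@label, character(1))
  r <- round(perf, .TIE_DIGITS)
  best <- max(r)
  new("PerformanceSample", x = max(perf[r == best]),
      winners = unname(labs[r == best]),
      featureSet = as.character(featureSet))
}

.asSpecList <- function(specs) {
  if (is(specs, "ClassifierSpec")) return(list(specs))
  lapply(specs, function(s) if (is.character(s)) classifierSpec(s) else s)
}

#' Best cross-validated performance over candidate classifiers
#'
#' Evaluates every candidate classifier on one feature set with identical CV
#' folds and returns the sample (x_i, C_i): the maximum mean performance and
#' the set of classifiers tying for it.
#'
#' @inheritParams crossValidate
#' @param specs list of [ClassifierSpec-class] objects or labels (default:
#'   all six).
#' @return A [PerformanceSample-class].
#' @export
bestPerformance <- function(x, labels, featureSet, specs = classifierRoster(),
                            cv = cvConfig()) {
  specs <- .asSpecList(specs)
  if (length(specs) < 1L) stop("at least one classifier spec is required")
  .checkCvFeasible(labels, cv)
  x <- as.matrix(x)
  folds <- .cvFolds(labels, cv)
  .bestPerformanceFolds(x, labels, featureSet, specs, folds, cv@nFolds)
}

#' Evaluate many feature sets (build the pool S_M)
#'
#' Applies [bestPerformance()] to each feature set with a single shared fold
#' partition, preserving order.  Evaluation is deterministic given the CV
#' seed (the folds are the only random ingredient), so results do not depend
#' on execution order or worker count.  A feature set that fails to evaluate
#' produces a recorded error entry of class `"performanceError"` rather than
#' being silently dropped.
#'
#' @inheritParams bestPerformance
#' @param featureSets non-empty list of feature index/name vectors.
#' @return list, one [PerformanceSample-class] (or `performanceError` record)
#'   per feature set.
#' @export
evaluateFeatureSpace <- function(x, labels, featureSets,
                                 specs = classifierRoster(),
                                 cv = cvConfig()) {
  if (length(featureSets) == 0L) stop("featureSets must be non-empty")
  specs <- .asSpecList(specs)
  .checkCvFeasible(labels, cv)
  x <- as.matrix(x)
  folds <- .cvFolds(labels, cv)
  lapply(seq_along(featureSets), function(i) {
    tryCatch(
      .bestPerformanceFolds(x, labels, featureSets[[i]], specs, folds,
                            cv@nFolds),
      error = function(e) structure(
        list(index = i, featureSet = featureSets[[i]],
             message = conditionMessage(e)),
        class = "performanceError"))
  })
}

#' Fine-grained reanalysis of top feature sets with paired t-tests
#'
#' Re-scores each feature set with a finer CV scheme (default 20 iterations
#' of five-fold), then compares the top classifier's per-fold scores to each
#' other classifier with a two-sided paired t-test over the shared folds.
#' The top classifier is starred when every comparison rejects at `alpha`.
#' When the paired differences have zero variance the p-value is defined as 1
#' if the means are equal and 0 otherwise.
#'
#' @inheritParams bestPerformance
#' @param featureSets list of feature sets (typically the top-ranked ones).
#' @param cv a [CVConfig-class]; default [fineCvConfig()].
#' @param alpha per-comparison significance level.
#' @return data.frame with the feature identifiers, one mean-performance
#'   column per classifier, the top classifier and whether it is starred;
#'   p-values are attached as attribute `"pvalues"`.
#' @export
fineReanalysis <- function(x, labels, featureSets,
                           specs = classifierRoster(),
                           cv = fineCvConfig(), alpha = 0.05) {
  specs <- .asSpecList(specs)
  labs <- vapply(specs, function(sp) sp@label, character(1))
  .checkCvFeasible(labels, cv)
  x <- as.matrix(x)
  folds <- .cvFolds(labels, cv)
  pmat <- matrix(NA_real_, length(featureSets), length(specs),
                 dimnames = list(NULL, labs))
  rows <- lapply(seq_along(featureSets), function(i) {
    fs <- featureSets[[i]]
    scores <- vapply(specs, function(sp)
      .cvFoldScores(x, labels, fs, sp, folds, cv@nFolds),
      numeric(cv@nFolds * cv@nIterations))
    means <- colMeans(scores, na.rm = TRUE)
    top <- which.max(round(means, .TIE_DIGITS))
    pv <- rep(NA_real_, length(specs))
    for (j in seq_along(specs)) {
      if (j == top) next
      d <- scores[, top] - scores[, j]
      d <- d[!is.na(d)]
      pv[j] <- if (isTRUE(all.equal(stats::sd(d), 0)) || length(d) < 2L) {
        if (abs(mean(d)) < 1e-12) 1 else 0
      } else stats::t.test(d)$p.value
    }
    pmat[i, ] <<- pv
    c(list(featureSet = paste(fs, collapse = ",")),
      as.list(means),
      list(top = labs[top], starred = all(pv[-top] < alpha)))
  })
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- c("featureSet", labs, "top", "starred")
  attr(out, "pvalues") <- pmat
  out
}

#' Write a fine-reanalysis table as delimited text
#'
#' One row per feature set with the feature identifiers and each
#' classifier's mean performance; the top classifier's value carries an
#' asterisk when it is significantly better than every other classifier.
#'
#' @param reanalysis result of [fineReanalysis()].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeReanalysisTable <- function(reanalysis, path, sep = "\t") {
  labs <- setdiff(names(reanalysis), c("featureSet", "top", "starred"))
  fmt <- reanalysis
  for (lab in labs) fmt[[lab]] <- sprintf("%.3f", reanalysis[[lab]])
  star <- which(reanalysis$starred)
  for (i in star) {
    lab <- reanalysis$top[i]
    fmt[i, lab] <- paste0(fmt[i, lab], "*")
  }
  genes <- do.call(rbind, strsplit(reanalysis$featureSet, ","))
  gcols <- as.data.frame(genes, stringsAsFactors = FALSE)
  names(gcols) <- paste0("Gene", seq_len(ncol(gcols)))
  utils::write.table(cbind(gcols, fmt[labs]), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
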