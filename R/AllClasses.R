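#' @import methods
NULL

.CLASSIFIER_TABLE <- data.frame(
  label     = c("NC", "DLDA", "LDA", "SDA", "UDA", "QDA"),
  pooling   = c("pooled", "pooled", "pooled", "unpooled", "unpooled", "unpooled"),
  structure = c("spherical", "diagonal", "full", "spherical", "diagonal", "full"),
  stringsAsFactors = FALSE
)

#' Classifier specification
#'
#' One of the six Gaussian Bayes classifiers obtained by crossing covariance
#' pooling (one covariance shared by both classes, giving a linear decision
#' boundary, versus per-class covariances, giving a quadratic boundary) with
#' covariance structure (spherical, diagonal or full).  The six combinations
#' correspond to nearest centroid (NC), diagonal linear discriminant analysis
#' (DLDA), linear discriminant analysis (LDA), spherical discriminant analysis
#' (SDA), uncorrelated discriminant analysis (UDA) and quadratic discriminant
#' analysis (QDA).
#'
#' @slot pooling `"pooled"` or `"unpooled"`.
#' @slot structure `"spherical"`, `"diagonal"` or `"full"`.
#' @slot label The conventional name of the classifier.
#' @export
setClass("ClassifierSpec",
  representation(pooling = "character", structure = "character",
                 label = "character"))

setValidity("ClassifierSpec", function(object) {
  hit <- .CLASSIFIER_TABLE$pooling == object@pooling &
    .CLASSIFIER_TABLE$structure == object@structure
  if (sum(hit) != 1L)
    return("pooling/structure must be one of the six supported combinations")
  if (.CLASSIFIER_TABLE$label[hit] != object@label)
    return(sprintf("label '%s' does not match (%s, %s)",
                   object@label, object@pooling, object@structure))
  TRUE
})

#' Fitted Gaussian Bayes classifier
#'
#' Per-class multivariate Gaussian model with a covariance matrix constrained
#' according to a [ClassifierSpec]. Prediction assigns the class with the
#' larger Gaussian log-density under uniform class priors.
#'
#' @slot means feature-by-class matrix of class means.
#' @slot covariances list of covariance matrices, one per class (identical
#'   matrices when pooled).
#' @slot classLevels the two class labels, in model order.
#' @slot spec the [ClassifierSpec] used for fitting.
#' @slot nTrain per-class training sample sizes.
#' @export
setClass("GaussianBayesModel",
  representation(means = "matrix", covariances = "list",
                 classLevels = "character", spec = "ClassifierSpec",
                 nTrain = "integer"))

setValidity("GaussianBayesModel", function(object) {
  k <- length(object@classLevels)
  if (ncol(object@means) != k) return("means must have one column per class")
  if (length(object@covariances) != k)
    return("covariances must have one entry per class")
  for (S in object@covariances) {
    if (!isSymmetric(unname(S), tol = 1e-8))
      return("covariance matrices must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return("covariance matrices must be positive semi-definite")
  }
  TRUE
})

#' Cross-validation configuration
#'
#' @slot nFolds number of folds per iteration (>= 2).
#' @slot nIterations number of independent fold partitions.
#' @slot seed integer seed for fold construction; identical folds are reused
#'   for every classifier so that per-fold scores are paired.
#' @slot stratified partition each class separately so every fold contains
#'   both classes.
#' @export
setClass("CVConfig",
  representation(nFolds = "integer", nIterations = "integer",
                 seed = "integer", stratified = "logical"))

setValidity("CVConfig", function(object) {
  if (object@nFolds < 2L) return("nFolds must be >= 2")
  if (object@nIterations < 1L) return("nIterations must be >= 1")
  TRUE
})

#' One feature set's best cross-validated performance
#'
#' @slot x best cross-validated balanced accuracy over the candidate
#'   classifiers, in \[0, 1\].
#' @slot winners labels of the classifiers tying for the best performance.
#' @slot featureSet identifiers of the features evaluated jointly.
#' @export
setClass("PerformanceSample",
  representation(x = "numeric", winners = "character",
                 featureSet = "character"))

setValidity("PerformanceSample", function(object) {
  if (length(object@x) != 1L || is.na(object@x)) return("x must be a scalar")
  if (length(object@winners) < 1L) return("winners must be non-empty")
  TRUE
})

#' Gaussian mixture of winning classifier performance
#'
#' Continuous model of the joint density p(x, c): for each candidate
#' classifier c, the performance x of feature sets on which c performs best is
#' Gaussian with mean `mu[c]` and standard deviation `sigma[c]`, and c wins a
#' randomly drawn feature set with prior probability `prior[c]`.
#'
#' @slot labels classifier labels.
#' @slot mu per-classifier mean winning performance.
#' @slot sigma per-classifier standard deviation (> 0).
#' @slot prior per-classifier prior p(c); non-negative, sums to 1.
#' @export
setClass("PerformanceMixture",
  representation(labels = "character", mu = "numeric", sigma = "numeric",
                 prior = "numeric"))

setValidity("PerformanceMixture", function(object) {
  k <- length(object@labels)
  if (length(object@mu) != k || length(object@sigma) != k ||
      length(object@prior) != k)
    return("labels, mu, sigma and prior must have equal length")
  if (any(object@sigma <= 0)) return("sigma must be positive")
  if (any(object@prior < 0) || abs(sum(object@prior) - 1) > 1e-8)
    return("prior must be non-negative and sum to 1")
  TRUE
})

#' Ranked table of performance samples
#'
#' The pool S_M of M (performance, winner set) samples, sorted by performance
#' in descending order.  Tied performances share a rank block: `rank` is the
#' rank of the best member of the block and `count` the block size, which is
#' exactly the bookkeeping needed by the rank-based selection weights.
#'
#' @slot x performances, sorted descending.
#' @slot winners list of winner-label sets, parallel to `x`.
#' @slot rank block rank per sample (descending, ties share the rank of the
#'   first member of their block).
#' @slot count block size per sample.
#' @slot M number of samples.
#' @export
setClass("WinTable",
  representation(x = "numeric", winners = "list", rank = "integer",
                 count = "integer", M = "integer"))

setValidity("WinTable", function(object) {
  M <- object@M
  if (length(object@x) != M || length(object@winners) != M ||
      length(object@rank) != M || length(object@count) != M)
    return("x, winners, rank and count must all have length M")
  if (is.unsorted(rev(object@x))) return("x must be sorted descending")
  if (any(vapply(object@winners, length, 1L) < 1L))
    return("every winners set must be non-empty")
  ok <- object@rank + object@count - 1L <= M & object@rank >= 1L
  if (!all(ok)) return("inconsistent rank/count bookkeeping")
  TRUE
})

#' Win percentage as a function of the number of sampled feature sets
#'
#' @slot N grid of subsample sizes.
#' @slot win matrix of win percentages, rows = N values, columns =
#'   classifiers; each row sums to 1.
#' @slot type `"continuous"` or `"discrete"`.
#' @export
setClass("WinCurve",
  representation(N = "numeric", win = "matrix", type = "character"))

setValidity("WinCurve", function(object) {
  if (nrow(object@win) != length(object@N))
    return("win must have one row per N")
  if (max(abs(rowSums(object@win) - 1)) > 1e-4)
    return("win percentages must sum to 1 for every N")
  TRUE
})

#' Null model for win percentage
#'
#' Beta distribution matched by the method of moments to the mean q and
#' variance q(1-q) sum(w_i^2) of the null win percentage, where w_i are the
#' rank-based selection weights.  Holds the critical bounds outside which a
#' win percentage is declared significantly high or low.
#'
#' @slot q null win chance per feature set (1/K for K classifiers).
#' @slot sumW2 sum of squared selection weights.
#' @slot alphaShape,betaShape beta distribution shape parameters.
#' @slot criticalLow,criticalHigh two-sided critical win percentages.
#' @slot nClassifiers number of candidate classifiers.
#' @slot degenerate TRUE when all weight sits on one sample (sumW2 = 1), in
#'   which case the null is a Bernoulli and the bounds collapse to (0, 1).
#' @export
setClass("WinNullModel",
  representation(q = "numeric", sumW2 = "numeric", alphaShape = "numeric",
                 betaShape = "numeric", criticalLow = "numeric",
                 criticalHigh = "numeric", nClassifiers = "integer",
                 degenerate = "logical"))

setValidity("WinNullModel", function(object) {
  if (object@q <= 0 || object@q >= 1) return("q must be in (0,1)")
  if (object@sumW2 <= 0 || object@sumW2 > 1 + 1e-12)
    return("sumW2 must be in (0, 1]")
  if (!object@degenerate &&
      !(object@criticalLow < object@q && object@q < object@criticalHigh))
    return("critical bounds must bracket q")
  TRUE
})

#' Result of a Monte Carlo wrapper feature-selection run
#'
#' @slot featureSet the best feature set found (S_out).
#' @slot performance its best cross-validated performance (x_out).
#' @slot classifier the classifier credited with the win (c_out), drawn
#'   uniformly from the tying winners when the running maximum was set.
#' @slot nIterations number of feature sets evaluated (N).
#' @slot seed the RNG seed used.
#' @export
setClass("MCWResult",
  representation(featureSet = "character", performance = "numeric",
                 classifier = "character", nIterations = "integer",
                 seed = "integer"))

#' Specification for a synthetic two-class expression matrix
#'
#' Describes a features-by-samples Gaussian expression matrix containing a
#' controllable number of informative feature pairs embedded among null
#' features.  Informative pairs realise one of three class-difference
#' geometries: a mean shift (favouring the pooled, linear classifiers), a
#' variance shift or a correlation shift (both favouring the unpooled,
#' quadratic-boundary classifiers).
#'
#' @slot nFeatures total number of features.
#' @slot nPerClass samples per class.
#' @slot pairTypes one of `"mean"`, `"variance"`, `"correlation"` per
#'   informative pair; pair j occupies features 2j-1 and 2j.
#' @slot effectSize per-pair effect size (mean shift in within-class SD
#'   units; multiplicative SD inflation; correlation magnitude).
#' @slot noiseSd standard deviation of additive measurement noise applied to
#'   every entry.
#' @export
setClass("ExpressionSimSpec",
  representation(nFeatures = "integer", nPerClass = "integer",
                 pairTypes = "character", effectSize = "numeric",
                 noiseSd = "numeric"))

setValidity("ExpressionSimSpec", function(object) {
  p <- length(object@pairTypes)
  if (2L * p > object@nFeatures)
    return("informative pairs need 2 * length(pairTypes) <= nFeatures")
  if (!all(object@pairTypes %in% c("mean", "variance", "correlation")))
    return("pairTypes must be 'mean', 'variance' or 'correlation'")
  if (length(object@effectSize) != p)
    return("effectSize must have one value per pair")
  if (object@nPerClass < 2L) return("need at least 2 samples per class")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})
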