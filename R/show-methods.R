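setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("%s: %s %s covariance\n", object@label, object@pooling,
              object@structure))
})

setMethod("show", "GaussianBayesModel", function(object) {
  cat(sprintf("GaussianBayesModel (%s): %d features, classes %s (n = %s)\n",
              object@spec@label, nrow(object@means),
              paste(object@classLevels, collapse = "/"),
              paste(object@nTrain, collapse = "/")))
})

setMethod("show", "CVConfig", function(object) {
  cat(sprintf("CVConfig: %d x %d-fold%s, seed %d\n", object@nIterations,
              object@nFolds, if (object@stratified) " (stratified)" else "",
              object@seed))
})

setMethod("show", "PerformanceSample", function(object) {
  cat(sprintf("PerformanceSample: x = %.4f, winners = {%s}, features = [%s]\n",
              object@x, paste(object@winners, collapse = ", "),
              paste(object@featureSet, collapse = ", ")))
})

setMethod("show", "PerformanceMixture", function(object) {
  cat(sprintf("PerformanceMixture with %d components:\n",
              length(object@labels)))
  for (k in seq_along(object@labels))
    cat(sprintf("  %s: N(%.3f, %.3f), prior %.3f\n", object@labels[k],
                object@mu[k], object@sigma[k], object@prior[k]))
})

setMethod("show", "WinTable", function(object) {
  cat(sprintf("WinTable: M = %d samples, x in [%.4f, %.4f], %d distinct\n",
              object@M, min(object@x), max(object@x),
              length(unique(object@rank))))
})

setMethod("show", "WinCurve", function(object) {
  cat(sprintf("WinCurve (%s): %d classifiers over %d values of N (%g..%g)\n",
              object@type, ncol(object@win), length(object@N),
              min(object@N), max(object@N)))
})

setMethod("show", "WinNullModel", function(object) {
  if (object@degenerate)
    cat(sprintf("WinNullModel: degenerate (all weight on one sample), q = %.4f\n",
                object@q))
  else
    cat(sprintf(
      "WinNullModel: Beta(%.3f, %.3f), q = %.4f, critical (%.4f, %.4f)\n",
      object@alphaShape, object@betaShape, object@q, object@criticalLow,
      object@criticalHigh))
})

setMethod("show", "MCWResult", function(object) {
  cat(sprintf("MCWResult: x_out = %.4f by %s on [%s] after N = %d draws\n",
              object@performance, object@classifier,
              paste(object@featureSet, collapse = ", "),
              object@nIterations))
})

setMethod("show", "ExpressionSimSpec", function(object) {
  cat(sprintf(
    "ExpressionSimSpec: %d features x %d samples (2 x %d), %d informative pairs\n",
    object@nFeatures, 2L * object@nPerClass, object@nPerClass,
    length(object@pairTypes)))
})
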