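#' Draw a random performance mixture
#'
#' Generates one [PerformanceMixture-class] from the simulation prior used to
#' validate the discrete win-percentage estimator against the continuous
#' form: component means from N(0.5, 0.1), standard deviations from
#' |N(0, 0.1)| (resampled when numerically zero), and priors by normalising
#' independent uniforms (set `priorMethod = "equal"` for fixed 1/K priors).
#'
#' @param nClassifiers number of components.
#' @param meanLoc,meanSd distribution of the component means.
#' @param sdScale scale of the half-normal standard deviations.
#' @param priorMethod `"simplex"` (normalised uniforms) or `"equal"`.
#' @param seed optional integer seed (isolated stream).
#' @return A [PerformanceMixture-class].
#' @export
randomMixture <- function(nClassifiers = 3L, meanLoc = 0.5, meanSd = 0.1,
                          sdScale = 0.1,
                          priorMethod = c("simplex", "equal"), seed = NULL) {
  priorMethod <- match.arg(priorMethod)
  draw <- function() {
    mu <- stats::rnorm(nClassifiers, meanLoc, meanSd)
    sigma <- abs(stats::rnorm(nClassifiers, 0, sdScale))
    while (any(sigma < 1e-6))
      sigma[sigma < 1e-6] <- abs(stats::rnorm(sum(sigma < 1e-6), 0, sdScale))
    prior <- if (priorMethod == "equal") rep(1 / nClassifiers, nClassifiers)
             else { u <- stats::runif(nClassifiers); u / sum(u) }
    performanceMixture(mu, sigma, prior)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Fast raw draws from p(x, c): component then conditional normal.
.drawMixture <- function(mixture, M) {
  comp <- sample.int(length(mixture@mu), M, replace = TRUE,
                     prob = mixture@prior)
  x <- stats::rnorm(M, mixture@mu[comp], mixture@sigma[comp])
  list(x = x, comp = comp)
}

#' Draw performance samples from a mixture
#'
#' Each draw picks a winning classifier from the priors and a performance
#' from that classifier's conditional Gaussian; the draws are not clipped to
#' \[0, 1\] (the mixture model is used as-is).
#'
#' @param mixture a [PerformanceMixture-class].
#' @param M number of draws.
#' @param seed optional integer seed (isolated stream).
#' @return list of M [PerformanceSample-class] objects with singleton winner
#'   sets.
#' @export
drawPerformanceSamples <- function(mixture, M, seed = NULL) {
  stopifnot(M >= 1)
  d <- if (is.null(seed)) .drawMixture(mixture, M)
       else withr::with_seed(as.integer(seed), .drawMixture(mixture, M))
  lapply(seq_len(M), function(i)
    new("PerformanceSample", x = d$x[i],
        winners = mixture@labels[d$comp[i]], featureSet = character(0)))
}

# Discrete win matrix (length(Nvec) x K) for raw draws with distinct
# performances, vectorized over N.  rowsum() aggregates the rank weights by
# winning component.
.discreteWinMatrix <- function(x, comp, K, Nvec) {
  M <- length(x)
  ord <- order(x, decreasing = TRUE)
  cl <- comp[ord]
  r <- seq_len(M)
  la <- log1p(-(r - 1) / M)
  lb <- log1p(-r / M)  # last entry -Inf -> weight term 0
  W <- exp(outer(la, Nvec)) - exp(outer(lb, Nvec))
  # rowsum() drops groups that received no draws; reinsert them as zero rows
  agg <- rowsum(W, group = cl)
  out <- matrix(0, length(Nvec), K)
  out[, as.integer(rownames(agg))] <- t(agg)
  out
}

#' Monte Carlo validation of the discrete win-percentage estimator
#'
#' Repeats the mixture illustration many times: for each randomly drawn
#' mixture, draws `M` performance samples per trial, computes the discrete
#' win percentage over a range of N, and compares it with the continuous win
#' percentage from the known mixture.  The pooled RMSE (over mixtures,
#' trials, N and classifiers) quantifies the sampling error of the discrete
#' estimator.
#'
#' @param nMixtures number of random mixtures.
#' @param nTrials trials (independent sample pools) per mixture.
#' @param M draws per trial.
#' @param nRange vector of subsample sizes N.
#' @param nClassifiers components per mixture.
#' @param seed integer root seed; per-mixture and per-trial seeds are derived
#'   from it, so results do not depend on execution order.
#' @param priorMethod prior scheme passed to [randomMixture()].
#' @return list with `rmse` (pooled, as a fraction), `perTrial` (data.frame
#'   of per-trial RMSEs) and the call parameters.
#' @export
rmseStudy <- function(nMixtures = 100L, nTrials = 100L, M = 1000L,
                      nRange = 1:40, nClassifiers = 3L, seed = 1L,
                      priorMethod = "simplex") {
  stopifnot(nMixtures >= 1, nTrials >= 1, M >= 1)
  Nvec <- as.numeric(nRange)
  sqErrSum <- 0; nCells <- 0
  perTrial <- vector("list", nMixtures)
  for (m in seq_len(nMixtures)) {
    mixSeed <- (as.integer(seed) + 7919L * m) %% .Machine$integer.max
    mix <- randomMixture(nClassifiers, priorMethod = priorMethod,
                         seed = mixSeed)
    cw <- continuousWin(mix, Nvec)
    if (is.null(dim(cw))) cw <- matrix(cw, 1L)
    trialRmse <- numeric(nTrials)
    for (t in seq_len(nTrials)) {
      trialSeed <- (mixSeed + 104729L * t) %% .Machine$integer.max
      d <- withr::with_seed(trialSeed, .drawMixture(mix, M))
      dw <- .discreteWinMatrix(d$x, d$comp, nClassifiers, Nvec)
      err2 <- (dw - cw)^2
      trialRmse[t] <- sqrt(mean(err2))
      sqErrSum <- sqErrSum + sum(err2)
      nCells <- nCells + length(err2)
    }
    perTrial[[m]] <- data.frame(mixture = m, trial = seq_len(nTrials),
                                rmse = trialRmse)
  }
  list(rmse = sqrt(sqErrSum / nCells),
       perTrial = do.call(rbind, perTrial),
       nMixtures = nMixtures, nTrials = nTrials, M = M, nRange = nRange)
}

#' Write an RMSE study as delimited text
#'
#' @param study result of [rmseStudy()].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeRmseStudy <- function(study, path, sep = "\t") {
  utils::write.table(study$perTrial, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predicted sampling error of the discrete win percentage
#'
#' Empirical error model `RMSE = 0.24 (N/M)^0.48` relating the pool size M
#' and the subsample size N to the root-mean-square error of the sampled win
#' percentage; solving for RMSE < 1% gives M > ~750 N.  The constants were
#' fitted for M >= N; outside that regime the value is still returned with a
#' warning.
#'
#' @param M pool size.
#' @param N subsample size.
#' @param a,b model constants.
#' @return predicted RMSE (as a fraction).
#' @export
predictedRmse <- function(M, N, a = 0.24, b = 0.48) {
  stopifnot(M >= 1, N >= 1)
  if (any(M < N)) warning("M < N is outside the fitted regime of the error model")
  a * (N / M)^b
}

#' Refit the error-model constants from observed RMSEs
#'
#' Log-log least squares of observed RMSE against N/M.
#'
#' @param ratio vector of N/M ratios.
#' @param rmse observed RMSEs.
#' @return named vector `c(a, b)` for RMSE = a (N/M)^b.
#' @export
fitRmseModel <- function(ratio, rmse) {
  stopifnot(length(ratio) == length(rmse), all(ratio > 0), all(rmse > 0))
  fit <- stats::lm(log(rmse) ~ log(ratio))
  c(a = unname(exp(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

#' Specify a synthetic two-class expression matrix
#'
#' @param nFeatures total features (null features are i.i.d. Gaussian shared
#'   between classes).
#' @param nPerClass samples per class.
#' @param pairTypes class-difference geometry per informative pair:
#'   `"mean"` (shift of the class means — linear boundary), `"variance"`
#'   (inflated spread in one class — quadratic boundary) or `"correlation"`
#'   (opposite-sign correlation between the pair — quadratic boundary).
#' @param effectSize one effect per pair: the mean shift in SD units, the SD
#'   inflation factor, or the correlation magnitude.
#' @param noiseSd additive measurement noise SD.
#' @return An [ExpressionSimSpec-class].
#' @export
expressionSimSpec <- function(nFeatures = 100L, nPerClass = 30L,
                              pairTypes = character(0),
                              effectSize = rep(2, length(pairTypes)),
                              noiseSd = 0.2) {
  if (length(effectSize) == 1L && length(pairTypes) > 1L)
    effectSize <- rep(effectSize, length(pairTypes))
  new("ExpressionSimSpec", nFeatures = as.integer(nFeatures),
      nPerClass = as.integer(nPerClass), pairTypes = pairTypes,
      effectSize = effectSize, noiseSd = noiseSd)
}

.rmvnorm2 <- function(n, mu, S) {
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  sweep(z %*% chol(S), 2L, mu, `+`)
}

#' Generate a synthetic two-class expression dataset
#'
#' Produces a features-by-samples matrix with binary class labels: pair j of
#' the informative pairs occupies features 2j-1 and 2j and realises its
#' declared boundary type; the remaining features are i.i.d. standard
#' Gaussians in both classes.  All features are marginally near-Gaussian, so
#' the matrix emulates a pool of Gaussian feature pairs with a controllable
#' informative fraction.
#'
#' @param spec an [ExpressionSimSpec-class].
#' @param seed optional integer seed (isolated stream).
#' @return list with `exprs` (features x samples matrix), `labels` (factor
#'   with levels C1/C2), `truth` (data.frame of informative pairs), and `se`
#'   (the same data as a [SummarizedExperiment::SummarizedExperiment]).
#' @export
generateExpression <- function(spec, seed = NULL) {
  gen <- function() {
    n <- spec@nPerClass
    F <- spec@nFeatures
    P <- length(spec@pairTypes)
    X <- matrix(stats::rnorm(F * 2L * n), F, 2L * n)
    cls <- rep(1:2, each = n)
    for (j in seq_len(P)) {
      f <- c(2L * j - 1L, 2L * j)
      e <- spec@effectSize[j]
      pair <- switch(spec@pairTypes[j],
        mean = rbind(.rmvnorm2(n, c(0, 0), diag(2)),
                     .rmvnorm2(n, c(e, e), diag(2))),
        variance = rbind(.rmvnorm2(n, c(0, 0), diag(2)),
                         .rmvnorm2(n, c(0, 0), diag(e^2, 2))),
        correlation = rbind(
          .rmvnorm2(n, c(0, 0), matrix(c(1, e, e, 1), 2)),
          .rmvnorm2(n, c(0, 0), matrix(c(1, -e, -e, 1), 2))))
      X[f, ] <- t(pair)
    }
    if (spec@noiseSd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, spec@noiseSd), nrow(X))
    rownames(X) <- sprintf("gene_%04d", seq_len(F))
    colnames(X) <- sprintf("s%03d", seq_len(2L * n))
    labels <- factor(paste0("C", cls))
    truth <- if (P > 0L)
      data.frame(pair = seq_len(P),
                 feature1 = rownames(X)[2L * seq_len(P) - 1L],
                 feature2 = rownames(X)[2L * seq_len(P)],
                 type = spec@pairTypes, effect = spec@effectSize,
                 stringsAsFactors = FALSE)
      else data.frame(pair = integer(0), feature1 = character(0),
                      feature2 = character(0), type = character(0),
                      effect = numeric(0))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = X),
      colData = S4Vectors::DataFrame(class = labels))
    list(exprs = X, labels = labels, truth = truth, se = se)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Write a synthetic expression dataset as delimited text plus JSON truth
#'
#' @param data result of [generateExpression()].
#' @param matrixPath expression matrix file (features in rows, identifier
#'   column first).
#' @param labelsPath class label file (sample, class).
#' @param truthPath optional JSON file recording the informative pairs.
#' @export
writeExpression <- function(data, matrixPath, labelsPath,
                            truthPath = NULL) {
  df <- data.frame(feature = rownames(data$exprs), data$exprs,
                   check.names = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(data$exprs),
               class = as.character(data$labels)),
    labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truthPath))
    jsonlite::write_json(data$truth, truthPath, dataframe = "rows",
                         digits = NA)
  invisible(matrixPath)
}
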