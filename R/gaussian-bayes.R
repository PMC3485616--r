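#' Construct a classifier specification
#'
#' Either give the conventional label (NC, DLDA, LDA, SDA, UDA, QDA) or the
#' pooling/structure pair; the two parameterisations are a bijection.
#'
#' @param label one of `"NC"`, `"DLDA"`, `"LDA"`, `"SDA"`, `"UDA"`, `"QDA"`.
#' @param pooling `"pooled"` or `"unpooled"` (used when `label` is missing).
#' @param structure `"spherical"`, `"diagonal"` or `"full"`.
#' @return A [ClassifierSpec-class] object.
#' @examples
#' classifierSpec("LDA")
#' classifierSpec(pooling = "unpooled", structure = "full")  # QDA
#' @export
classifierSpec <- function(label = NULL, pooling = NULL, structure = NULL) {
  tab <- .CLASSIFIER_TABLE
  if (!is.null(label)) {
    hit <- match(label, tab$label)
    if (is.na(hit)) stop("unknown classifier label: ", label)
  } else {
    hit <- which(tab$pooling == pooling & tab$structure == structure)
    if (length(hit) != 1L)
      stop("pooling must be pooled/unpooled and structure spherical/diagonal/full")
  }
  new("ClassifierSpec", pooling = tab$pooling[hit],
      structure = tab$structure[hit], label = tab$label[hit])
}

#' The six candidate classifiers
#'
#' @return A named list of the six [ClassifierSpec-class] objects in
#'   complexity order: NC, DLDA, LDA, SDA, UDA, QDA.
#' @export
classifierRoster <- function() {
  specs <- lapply(.CLASSIFIER_TABLE$label, classifierSpec)
  names(specs) <- .CLASSIFIER_TABLE$label
  specs
}

#' Degrees of freedom of a constrained Gaussian Bayes classifier
#'
#' Counts the free parameters: one mean vector per class plus the free
#' covariance parameters under the constraint (one covariance structure when
#' pooled, one per class when unpooled).  For two classes and two features
#' this yields NC 5, DLDA 6, LDA 7, SDA 6, UDA 8, QDA 10.
#'
#' @param spec a [ClassifierSpec-class] or its label.
#' @param nFeatures number of features (>= 1).
#' @param nClasses number of classes (>= 2).
#' @return integer parameter count.
#' @export
degreesOfFreedom <- function(spec, nFeatures, nClasses = 2L) {
  if (is.character(spec)) spec <- classifierSpec(spec)
  stopifnot(nFeatures >= 1L, nClasses >= 2L)
  d <- as.integer(nFeatures); k <- as.integer(nClasses)
  covPars <- switch(spec@structure,
    spherical = 1L, diagonal = d, full = (d * (d + 1L)) %/% 2L)
  k * d + covPars * (if (spec@pooling == "pooled") 1L else k)
}

# Covariance floor / ridge constants: paper-silent degenerate inputs (e.g. a
# feature constant within a class) must still yield a usable density.
.VAR_FLOOR <- 1e-12
.RIDGE_FACTOR <- 1e-9

.mlCov <- function(xc) {
  # maximum-likelihood covariance (divide by n)
  n <- nrow(xc)
  ctr <- sweep(xc, 2L, colMeans(xc))
  crossprod(ctr) / n
}

.constrainCov <- function(S, structure) {
  d <- ncol(S)
  switch(structure,
    spherical = diag(max(mean(diag(S)), .VAR_FLOOR), d),
    diagonal = diag(pmax(diag(S), .VAR_FLOOR), d),
    full = {
      ridge <- .RIDGE_FACTOR * sum(diag(S)) / d
      S <- S + diag(ridge, d)
      diag(S) <- pmax(diag(S), .VAR_FLOOR)
      S
    })
}

#' Fit a constrained-covariance Gaussian Bayes classifier
#'
#' Each class is modelled as a multivariate Gaussian: class means are the
#' per-class sample means; the covariance is the per-class maximum-likelihood
#' estimate (unpooled) or the within-class scatter divided by (n - 2)
#' (pooled), then constrained to the spec's structure (spherical: mean of the
#' per-dimension variances times the identity; diagonal: off-diagonals
#' zeroed; full: kept, with a small ridge on the diagonal against
#' singularity).
#'
#' @param x samples-by-features numeric matrix (no missing values).
#' @param labels two-class label vector, one per row of `x`.
#' @param spec a [ClassifierSpec-class] or its label.
#' @return A [GaussianBayesModel-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' y <- rep(c("A", "B"), each = 20)
#' fitGaussianBayes(x, y, "NC")
#' @export
fitGaussianBayes <- function(x, labels, spec) {
  if (is.character(spec)) spec <- classifierSpec(spec)
  x <- as.matrix(x)
  if (anyNA(x)) stop("x must not contain missing values")
  labels <- as.factor(labels)
  if (length(labels) != nrow(x))
    stop("labels must have one entry per row of x")
  lev <- levels(droplevels(labels))
  if (length(lev) != 2L) stop("exactly two classes are required")
  n <- table(factor(labels, levels = lev))
  if (any(n < 2L)) stop("each class needs at least 2 samples")

  d <- ncol(x)
  means <- matrix(0, d, 2L, dimnames = list(colnames(x), lev))
  scat <- vector("list", 2L)
  for (k in 1:2) {
    xc <- x[labels == lev[k], , drop = FALSE]
    means[, k] <- colMeans(xc)
    scat[[k]] <- .mlCov(xc) * nrow(xc)  # class scatter matrix
  }
  if (spec@pooling == "pooled") {
    S <- (scat[[1]] + scat[[2]]) / (sum(n) - 2L)
    S <- .constrainCov(S, spec@structure)
    covs <- list(S, S)
  } else {
    covs <- lapply(1:2, function(k)
      .constrainCov(scat[[k]] / n[k], spec@structure))
  }
  new("GaussianBayesModel", means = means, covariances = covs,
      classLevels = lev, spec = spec, nTrain = as.integer(n))
}

.gaussLogDensity <- function(x, mu, S) {
  # log N(x | mu, S) for all rows of x; chol with escalating ridge fallback
  d <- ncol(x)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  tries <- 0L
  while (is.null(ch) && tries < 4L) {
    tries <- tries + 1L
    S <- S + diag(10^(tries - 9) * max(sum(diag(S)) / d, .VAR_FLOOR), d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
  }
  if (is.null(ch)) stop("covariance matrix is numerically singular")
  ctr <- sweep(x, 2L, mu)
  z <- forwardsolve(t(ch), t(ctr))
  quad <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

#' Predict class labels from a fitted Gaussian Bayes model
#'
#' Assigns each sample the class maximising the Gaussian log-density under
#' uniform class priors.  Exact log-density ties break to the first class
#' level.
#'
#' @param object a [GaussianBayesModel-class].
#' @param newdata samples-by-features matrix with the training feature count.
#' @param ... ignored.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "GaussianBayesModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object@means))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         nrow(object@means))
  ld <- vapply(1:2, function(k)
    .gaussLogDensity(newdata, object@means[, k], object@covariances[[k]]),
    numeric(nrow(newdata)))
  if (!is.matrix(ld)) ld <- matrix(ld, nrow = 1L)
  object@classLevels[max.col(ld, ties.method = "first")]
})
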