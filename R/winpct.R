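# ---- mixture numerics -------------------------------------------------------

.logSumExp <- function(m) {
  # rowwise log-sum-exp of a matrix (columns = mixture components)
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

.mixLogPdf <- function(mix, x) {
  lp <- vapply(seq_along(mix@mu), function(k)
    log(mix@prior[k]) + stats::dnorm(x, mix@mu[k], mix@sigma[k], log = TRUE),
    numeric(length(x)))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1L)
  .logSumExp(lp)
}

.mixLogCdf <- function(mix, x) {
  lp <- vapply(seq_along(mix@mu), function(k)
    log(mix@prior[k]) +
      stats::pnorm(x, mix@mu[k], mix@sigma[k], log.p = TRUE),
    numeric(length(x)))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1L)
  .logSumExp(lp)
}

.mixLogSf <- function(mix, x) {
  lp <- vapply(seq_along(mix@mu), function(k)
    log(mix@prior[k]) +
      stats::pnorm(x, mix@mu[k], mix@sigma[k], lower.tail = FALSE,
                   log.p = TRUE),
    numeric(length(x)))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1L)
  .logSumExp(lp)
}

.mixPosterior <- function(mix, x) {
  # p(c | x), rows = x, cols = components; stable softmax
  lp <- vapply(seq_along(mix@mu), function(k)
    log(mix@prior[k]) + stats::dnorm(x, mix@mu[k], mix@sigma[k], log = TRUE),
    numeric(length(x)))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1L)
  post <- exp(lp - .logSumExp(lp))
  post / rowSums(post)
}

# Inverse survival function of the mixture, vectorized bisection on a
# bracket of +/- 16 sd around the component means.
.mixQuantileSf <- function(mix, s) {
  lo <- rep(min(mix@mu - 16 * mix@sigma), length(s))
  hi <- rep(max(mix@mu + 16 * mix@sigma), length(s))
  logs <- log(s)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    above <- .mixLogSf(mix, mid) > logs
    lo[above] <- mid[above]
    hi[!above] <- mid[!above]
  }
  (lo + hi) / 2
}

# Composite Gauss-Legendre nodes/weights on (0, 1): Golub-Welsch on [-1, 1],
# mapped panel-wise.  Cached after first use.
.glCache <- new.env(parent = emptyenv())
.glUnit <- function(nNodes, nPanels) {
  key <- paste(nNodes, nPanels, sep = "_")
  if (!is.null(.glCache[[key]])) return(.glCache[[key]])
  i <- seq_len(nNodes - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, nNodes, nNodes)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  wts <- 2 * e$vectors[1L, ]^2
  edges <- seq(0, 1, length.out = nPanels + 1L)
  u <- unlist(lapply(seq_len(nPanels), function(p)
    (edges[p] + edges[p + 1L]) / 2 + (edges[p + 1L] - edges[p]) / 2 * nodes))
  w <- rep(wts / 2 / nPanels, nPanels)
  .glCache[[key]] <- list(u = u, w = w)
  .glCache[[key]]
}

# ---- continuous win percentage ---------------------------------------------

#' Construct a performance mixture
#'
#' @param mu,sigma,prior per-classifier mean, standard deviation and prior of
#'   winning performance.  `prior` defaults to equal and is normalised.
#' @param labels classifier labels (default c1, c2, ...).
#' @return A [PerformanceMixture-class].
#' @examples
#' # the three-classifier illustration: a wide, a moderate and a narrow winner
#' performanceMixture(mu = c(0.50, 0.70, 0.75), sigma = c(0.20, 0.07, 0.02))
#' @export
performanceMixture <- function(mu, sigma, prior = NULL, labels = NULL) {
  k <- length(mu)
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (is.null(labels)) labels <- paste0("c", seq_len(k))
  new("PerformanceMixture", labels = labels, mu = mu, sigma = sigma,
      prior = prior / sum(prior))
}

#' Density of the best performance among N random feature sets
#'
#' For performance density p(x) with CDF P, the maximum of N i.i.d. draws has
#' density `N * P(x)^(N-1) * p(x)`.  Computed on the log scale so that very
#' large N does not underflow.
#'
#' @param x evaluation points.
#' @param nIterations subsample size N (>= 1).
#' @param mixture a [PerformanceMixture-class].
#' @return density values at `x`.
#' @export
maxDensity <- function(x, nIterations, mixture) {
  stopifnot(nIterations >= 1)
  exp(log(nIterations) + (nIterations - 1) * .mixLogCdf(mixture, x) +
        .mixLogPdf(mixture, x))
}

#' Continuous win percentage
#'
#' The probability that each classifier performs best on the best of N
#' feature sets drawn at random: `win(c) = integral p(c|x) d max-density(x)`.
#' Evaluated after the substitution `u = P(x)^N`, which maps the integral to
#' `integral_0^1 p(c | x(u)) du` with `x(u) = P^{-1}(u^{1/N})` — a smooth,
#' bounded integrand for any N (including N of order 1e10, where the raw
#' integrand is a spike in the extreme upper tail).  Gauss-Legendre
#' quadrature on (0, 1); the returned values sum to 1.
#'
#' @param mixture a [PerformanceMixture-class].
#' @param nIterations subsample size N (>= 1); may be a vector.
#' @param nNodes,nPanels quadrature resolution (composite Gauss-Legendre).
#' @return named win-percentage vector, or a matrix (rows = N values) when
#'   `nIterations` is a vector.
#' @examples
#' mix <- performanceMixture(c(0.50, 0.70, 0.75), c(0.20, 0.07, 0.02))
#' continuousWin(mix, 1)    # equal priors: 1/3 each
#' continuousWin(mix, 100)  # thorough search favours the long-tailed c1
#' @export
continuousWin <- function(mixture, nIterations, nNodes = 48L, nPanels = 8L) {
  stopifnot(all(nIterations >= 1))
  gl <- .glUnit(nNodes, nPanels)
  res <- t(vapply(nIterations, function(N) {
    s <- -expm1(log(gl$u) / N)  # survival target 1 - u^(1/N), computed stably
    x <- .mixQuantileSf(mixture, s)
    post <- .mixPosterior(mixture, x)
    if (!all(is.finite(post))) stop("non-finite integrand")
    drop(crossprod(post, gl$w))
  }, numeric(length(mixture@labels))))
  colnames(res) <- mixture@labels
  if (length(nIterations) == 1L) res[1L, ] else res
}

# ---- discrete win percentage ------------------------------------------------

#' Build a ranked win table from performance samples
#'
#' @param samples list of [PerformanceSample-class] objects, or a numeric
#'   vector of performances combined with `winners`.
#' @param winners optional list of winner-label sets parallel to a numeric
#'   `samples` vector.
#' @return A [WinTable-class] sorted by performance, descending; tied
#'   performances (after rounding to 12 decimals) share a rank block.
#' @export
winTable <- function(samples, winners = NULL) {
  if (is.numeric(samples)) {
    x <- samples
    if (is.null(winners)) winners <- as.list(rep("c1", length(x)))
  } else {
    x <- vapply(samples, function(s) s@x, numeric(1))
    winners <- lapply(samples, function(s) s@winners)
  }
  if (length(x) < 1L) stop("at least one sample is required")
  if (any(vapply(winners, length, 1L) < 1L))
    stop("every winners set must be non-empty")
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]; winners <- winners[ord]
  M <- length(x)
  xr <- round(x, .TIE_DIGITS)
  firstOfBlock <- c(TRUE, xr[-1L] != xr[-M])
  blockId <- cumsum(firstOfBlock)
  count <- as.integer(table(blockId))[blockId]
  rank <- which(firstOfBlock)[blockId]
  new("WinTable", x = x, winners = winners, rank = as.integer(rank),
      count = count, M = as.integer(M))
}

# Per-sample selection weights for block ranks r, block sizes k, pool M,
# subsample N: block weight ((M-r+1)/M)^N - ((M-r+1-k)/M)^N, split equally
# over the block.  exp/log1p keeps N up to 1e10 exact in double precision.
.rankWeights <- function(M, N, rank = seq_len(M), count = rep(1L, M)) {
  a <- exp(N * log1p(-(rank - 1) / M))
  b <- ifelse(rank - 1 + count >= M, 0, exp(N * log1p(-(rank - 1 + count) / M)))
  (a - b) / count
}

#' Rank-based selection weights
#'
#' The probability that the i-th ranked sample of the pool holds the maximum
#' of N draws with replacement.  At N = 1 every sample has weight 1/M
#' regardless of rank; as N grows the weight concentrates on the top ranks
#' (selection pressure).  Tied performances share their block's weight
#' equally.  Weights sum to 1 for every N.
#'
#' @param winTable a [WinTable-class].
#' @param nIterations subsample size N (>= 1).
#' @return numeric weights, one per sample, in the table's (descending) order.
#' @export
selectionWeights <- function(winTable, nIterations) {
  stopifnot(is(winTable, "WinTable"), nIterations >= 1)
  .rankWeights(winTable@M, nIterations, winTable@rank, winTable@count)
}

#' Uniform-rank selection weights
#'
#' Selection weights for a pool of `M` all-distinct performances — the shape
#' used by the null model, including the optional effective-sample-size
#' adjustment where `M` is reduced to the number of independent feature sets.
#'
#' @param M pool size.
#' @param nIterations subsample size N.
#' @return numeric vector of M weights summing to 1.
#' @export
rankWeights <- function(M, nIterations) {
  stopifnot(M >= 1, nIterations >= 1)
  .rankWeights(M, nIterations)
}

#' Discrete win percentage
#'
#' Win percentage estimated from a finite pool S_M of (performance, winner
#' set) samples: each sample contributes its selection weight divided by the
#' number of tying winner classifiers, summed per classifier.  Sums to 1
#' exactly (within float tolerance) at every N.
#'
#' @param samples a [WinTable-class] or a list of
#'   [PerformanceSample-class] objects.
#' @param nIterations subsample size N (>= 1).
#' @param labels classifier labels for the output (default: all labels seen).
#' @return named win-percentage vector.
#' @export
discreteWin <- function(samples, nIterations, labels = NULL) {
  wt <- if (is(samples, "WinTable")) samples else winTable(samples)
  w <- selectionWeights(wt, nIterations)
  if (is.null(labels))
    labels <- sort(unique(unlist(wt@winners)))
  win <- stats::setNames(numeric(length(labels)), labels)
  share <- w / vapply(wt@winners, length, 1L)
  for (i in seq_len(wt@M)) {
    ci <- wt@winners[[i]]
    win[ci] <- win[ci] + share[i]
  }
  win
}

#' Win percentage as a function of N
#'
#' Evaluates [discreteWin()] (for a [WinTable-class] or sample list) or
#' [continuousWin()] (for a [PerformanceMixture-class]) over a grid of
#' subsample sizes.
#'
#' @param object the pool or mixture.
#' @param N ascending grid of subsample sizes (the discrete form supports N
#'   up to 1e10 and beyond exactly, via log-scale powers).
#' @param labels optional classifier labels for the discrete form.
#' @return A [WinCurve-class].
#' @export
winCurve <- function(object, N, labels = NULL) {
  stopifnot(length(N) >= 1, !is.unsorted(N))
  if (is(object, "PerformanceMixture")) {
    win <- continuousWin(object, N)
    if (is.null(dim(win))) win <- matrix(win, 1L,
                                         dimnames = list(NULL, names(win)))
    return(new("WinCurve", N = as.numeric(N), win = win,
               type = "continuous"))
  }
  wt <- if (is(object, "WinTable")) object else winTable(object)
  if (is.null(labels)) labels <- sort(unique(unlist(wt@winners)))
  win <- t(vapply(N, function(n) discreteWin(wt, n, labels),
                  numeric(length(labels))))
  colnames(win) <- labels
  new("WinCurve", N = as.numeric(N), win = win, type = "discrete")
}

#' Default logarithmic N grid
#'
#' @param from,to decade range.
#' @param perDecade grid points per decade.
#' @return integer-valued N grid, logarithmically spaced, deduplicated.
#' @export
logNGrid <- function(from = 0, to = 10, perDecade = 10) {
  unique(round(10^seq(from, to, by = 1 / perDecade)))
}

#' Write a win curve as delimited text
#'
#' @param curve a [WinCurve-class].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeWinCurve <- function(curve, path, sep = "\t") {
  df <- data.frame(N = curve@N, curve@win, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot win-percentage curves
#'
#' Log-x win percentage per classifier versus N, optionally overlaying the
#' statistically insignificant band from a significance report.
#'
#' @param curve a [WinCurve-class].
#' @param band optional data.frame with columns N, criticalLow, criticalHigh
#'   (as produced by [significanceReport()]).
#' @return a ggplot object.
#' @export
plotWinCurve <- function(curve, band = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotWinCurve requires the ggplot2 package")
  df <- data.frame(N = rep(curve@N, ncol(curve@win)),
                   classifier = rep(colnames(curve@win),
                                    each = length(curve@N)),
                   win = as.vector(curve@win))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$win,
                                        colour = .data$classifier))
  if (!is.null(band)) {
    bd <- unique(band[, c("N", "criticalLow", "criticalHigh")])
    p <- p + ggplot2::geom_ribbon(
      data = bd, ggplot2::aes(x = .data$N, ymin = .data$criticalLow,
                              ymax = .data$criticalHigh),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6)
  }
  p + ggplot2::geom_line() + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "N (feature sets explored)", y = "win percentage")
}
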