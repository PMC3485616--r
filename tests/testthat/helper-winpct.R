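# Shared fixtures, all generated in code.

# Two well-separated Gaussian clouds (linearly separable for any of the six).
separableData <- function(n = 30L, d = 2L, gap = 6, seed = 42L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d, mean = gap), n, d))
    list(x = x, labels = rep(c("A", "B"), each = n))
  })
}

# Quadratic-boundary data: same means, very different spread per class.
varianceShiftData <- function(n = 40L, ratio = 4, seed = 7L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2L), n, 2L),
               matrix(rnorm(n * 2L, sd = ratio), n, 2L))
    list(x = x, labels = rep(c("A", "B"), each = n))
  })
}

# Null two-class data: no class signal at all.
nullData <- function(nFeatures = 20L, n = 30L, seed = 99L) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2L * n * nFeatures), 2L * n, nFeatures)
    colnames(x) <- sprintf("f%02d", seq_len(nFeatures))
    list(x = x, labels = rep(c("A", "B"), each = n))
  })
}

# Independent oracle for the discrete win percentage: enumerate all M^N
# ordered with-replacement draws; the winning sample of a draw is the first
# drawn occurrence of the maximum performance, and its tying classifiers
# split the credit equally.
enumWinOracle <- function(x, winners, N) {
  M <- length(x)
  labels <- sort(unique(unlist(winners)))
  win <- stats::setNames(numeric(length(labels)), labels)
  grid <- as.matrix(expand.grid(rep(list(seq_len(M)), N)))
  for (r in seq_len(nrow(grid))) {
    draw <- grid[r, ]
    xs <- x[draw]
    first <- draw[which.max(xs)]  # which.max: first occurrence of the max
    ci <- winners[[first]]
    win[ci] <- win[ci] + 1 / (M^N) / length(ci)
  }
  win
}

# Random win table with occasional exact ties and random winner sets.
randomWinTableCase <- function(M, nLabels = 3L) {
  labels <- LETTERS[seq_len(nLabels)]
  x <- round(runif(M), 1L)  # coarse grid forces ties
  winners <- lapply(seq_len(M), function(i)
    sample(labels, sample.int(nLabels, 1L)))
  list(x = x, winners = winners)
}
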