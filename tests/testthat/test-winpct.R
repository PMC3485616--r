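eqMixture <- function()
  performanceMixture(c(0.50, 0.70, 0.75), c(0.20, 0.07, 0.02))

test_that("max-density reduces to p(x) at N = 1 and integrates to one", {
  mix <- eqMixture()
  xs <- seq(-0.5, 1.5, by = 0.05)
  direct <- rowSums(vapply(1:3, function(k)
    mix@prior[k] * dnorm(xs, mix@mu[k], mix@sigma[k]), numeric(length(xs))))
  expect_equal(maxDensity(xs, 1, mix), direct, tolerance = 1e-12)
  for (N in c(2, 7, 50))
    expect_equal(integrate(function(x) maxDensity(x, N, mix), -2, 3,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
})

test_that("the expected maximum of six standard normals is mu + 1.27 sigma", {
  std <- performanceMixture(0, 1)
  m6 <- integrate(function(x) x * maxDensity(x, 6, std), -10, 10,
                  rel.tol = 1e-10)$value
  expect_equal(m6, 1.27, tolerance = 0.005)
  # location-scale: shifts and scales carry through the order statistic
  shifted <- performanceMixture(0.5, 0.1)
  m6s <- integrate(function(x) x * maxDensity(x, 6, shifted), -1, 2,
                   rel.tol = 1e-10)$value
  expect_equal(m6s, 0.5 + 0.1 * m6, tolerance = 1e-6)
})

test_that("continuous win percentage matches direct quadrature and sums to 1", {
  mix <- eqMixture()
  expect_equal(unname(continuousWin(mix, 1)), rep(1 / 3, 3),
               tolerance = 1e-9)
  # independent route: integrate p(c)p(x|c) N P(x)^(N-1) dx in x-space
  F <- function(x) colSums(mix@prior * vapply(x, function(xx)
    pnorm(xx, mix@mu, mix@sigma), numeric(3)))
  for (N in c(2, 5, 17, 40)) {
    w <- continuousWin(mix, N)
    direct <- vapply(1:3, function(k)
      integrate(function(x) mix@prior[k] * dnorm(x, mix@mu[k], mix@sigma[k]) *
                  N * F(x)^(N - 1), -2, 3, rel.tol = 1e-11)$value, numeric(1))
    expect_equal(unname(w), direct, tolerance = 2e-5)
    expect_equal(sum(w), 1, tolerance = 1e-6)
  }
  # remains normalised and finite at extreme N
  big <- continuousWin(mix, c(1e6, 1e10))
  expect_equal(unname(rowSums(big)), c(1, 1), tolerance = 1e-6)
  expect_true(all(is.finite(big)))
})

test_that("the illustrative mixture changes favourite as N grows", {
  mix <- eqMixture()
  w <- continuousWin(mix, 1:40)
  am <- apply(w, 1, which.max)
  # narrow-but-high c3 leads for small N, moderate c2 takes over, and the
  # long-tailed c1 wins once at least 27 feature sets are explored
  expect_true(all(am[2:11] == 3))
  expect_true(all(am[12:26] == 2))
  strict1 <- which(w[, 1] > pmax(w[, 2], w[, 3]))
  expect_identical(min(strict1), 27L)
  expect_true(all(am[27:40] == 1))
  # at astronomically large N the widest tail wins outright
  expect_gt(continuousWin(mix, 1e6)[1], 0.999)
})

test_that("win tables rank descending with shared tie blocks", {
  wt <- winTable(c(0.7, 0.9, 0.7, 0.8), list("A", "B", "C", c("A", "C")))
  expect_equal(wt@x, c(0.9, 0.8, 0.7, 0.7))
  expect_identical(wt@rank, c(1L, 2L, 3L, 3L))
  expect_identical(wt@count, c(1L, 1L, 2L, 2L))
  expect_error(winTable(numeric(0)), "at least one")
  expect_error(winTable(c(1, 2), list("A", character(0))), "non-empty")
})

test_that("selection weights are uniform at N=1 and concentrate as N grows", {
  set.seed(6)
  wt <- winTable(runif(25), as.list(sample(LETTERS[1:3], 25, TRUE)))
  expect_equal(selectionWeights(wt, 1), rep(1 / 25, 25))
  # enumeration oracle for M = 2 distinct values at N = 2: draws (1,1),(1,2),
  # (2,1) put rank 1 on top -> 3/4, (2,2) -> 1/4
  wt2 <- winTable(c(0.9, 0.8), list("A", "B"))
  expect_equal(selectionWeights(wt2, 2), c(3 / 4, 1 / 4))
  # large N: all weight on the top block
  w <- selectionWeights(wt, 1e8)
  expect_equal(w[1], 1, tolerance = 1e-8)
  expect_lt(max(w[-1]), 1e-8)
  # weights sum to one for any N
  for (N in c(1, 2, 3, 10, 1e3, 1e10))
    expect_equal(sum(selectionWeights(wt, N)), 1, tolerance = 1e-12)
  # selection pressure: cumulative top-k weight never decreases with N
  cum5 <- cumsum(selectionWeights(wt, 5))
  cum20 <- cumsum(selectionWeights(wt, 20))
  expect_true(all(cum20 - cum5 >= -1e-12))
})

test_that("discrete win equals exhaustive enumeration over all ordered draws", {
  # hand example first: two samples, N = 2
  s <- list(new("PerformanceSample", x = 0.9, winners = "A",
                featureSet = "p1"),
            new("PerformanceSample", x = 0.8, winners = "B",
                featureSet = "p2"))
  expect_equal(discreteWin(s, 2), c(A = 0.75, B = 0.25))
  # ties split evenly at any N
  tie <- winTable(0.8, list(c("A", "B")))
  for (N in c(1, 3, 1e6))
    expect_equal(discreteWin(tie, N), c(A = 0.5, B = 0.5))
  # property: random tables with ties and multi-winner sets vs the M^N oracle
  set.seed(1234)
  cases <- list(c(M = 4L, N = 4L), c(M = 6L, N = 3L), c(M = 8L, N = 2L),
                c(M = 5L, N = 5L), c(M = 3L, N = 6L))
  for (cs in cases) {
    tab <- randomWinTableCase(cs["M"])
    wt <- winTable(tab$x, tab$winners)
    got <- discreteWin(wt, cs["N"])
    want <- enumWinOracle(tab$x, tab$winners, cs["N"])
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("win curves evaluate both forms over a grid and normalise", {
  set.seed(9)
  samples <- drawPerformanceSamples(eqMixture(), 300, seed = 5L)
  grid <- logNGrid(0, 6, 3)
  curve <- winCurve(samples, grid)
  expect_s4_class(curve, "WinCurve")
  expect_identical(curve@type, "discrete")
  expect_equal(unname(rowSums(curve@win)), rep(1, length(grid)),
               tolerance = 1e-12)
  # N = 1 with singleton winners: win is just the winner frequency
  freq <- table(factor(vapply(samples, function(s) s@winners[1],
                              character(1)), levels = colnames(curve@win)))
  expect_equal(unname(curve@win[1, ]), as.vector(freq) / 300,
               tolerance = 1e-12)
  cc <- winCurve(eqMixture(), c(1, 10, 100))
  expect_identical(cc@type, "continuous")
  expect_equal(unname(rowSums(cc@win)), rep(1, 3), tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeWinCurve(curve, f)
  back <- read.delim(f)
  expect_equal(back$N, curve@N)
  expect_equal(as.matrix(back[-1]), curve@win, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("discrete win converges to the continuous value as M grows", {
  mix <- eqMixture()
  Ns <- c(1, 5, 15, 40)
  cw <- continuousWin(mix, Ns)
  reps <- 30L
  est <- array(dim = c(reps, length(Ns), 3))
  for (r in seq_len(reps)) {
    smp <- withr::with_seed(100L + r, winpct:::.drawMixture(mix, 4000L))
    est[r, , ] <- winpct:::.discreteWinMatrix(smp$x, smp$comp, 3L, Ns)
  }
  # the continuous value lies inside the empirical 95% band of the sampled
  # estimates, and the mean error is small
  for (j in seq_along(Ns)) for (k in 1:3) {
    band <- quantile(est[, j, k], c(0.025, 0.975))
    expect_true(cw[j, k] >= band[1] - 0.02 && cw[j, k] <= band[2] + 0.02)
  }
  expect_lt(sqrt(mean((sweep(est, c(2, 3), cw))^2)), 0.03)
})
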