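test_that("random mixtures follow the simulation prior and are reproducible", {
  m1 <- randomMixture(seed = 4L)
  m2 <- randomMixture(seed = 4L)
  expect_identical(m1@mu, m2@mu)
  expect_identical(m1@prior, m2@prior)
  expect_true(all(m1@sigma > 0))
  expect_equal(sum(m1@prior), 1)
  # distribution recovery over many draws
  mus <- unlist(lapply(1:2000, function(i) randomMixture(seed = i)@mu))
  n <- length(mus)
  expect_lt(abs(mean(mus) - 0.5), 3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(mus) - 0.1), 0.01)
  eq <- randomMixture(seed = 1L, priorMethod = "equal")
  expect_equal(eq@prior, rep(1 / 3, 3))
})

test_that("performance draws follow p(c) and p(x|c)", {
  mix <- performanceMixture(c(0.4, 0.8), c(0.1, 0.05), prior = c(0.7, 0.3),
                            labels = c("lin", "quad"))
  smp <- drawPerformanceSamples(mix, 3000, seed = 6L)
  expect_length(smp, 3000)
  winners <- vapply(smp, function(s) s@winners, character(1))
  phat <- mean(winners == "lin")
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / 3000))
  xs <- vapply(smp, function(s) s@x, numeric(1))
  expect_lt(abs(mean(xs[winners == "lin"]) - 0.4), 0.01)
  # single-component mixture: all winners identical
  mono <- drawPerformanceSamples(performanceMixture(0.6, 0.1), 20, seed = 1L)
  expect_true(all(vapply(mono, function(s) s@winners, character(1)) == "c1"))
  # discrete win at N = 1 recovers the priors
  w1 <- discreteWin(smp, 1)
  expect_equal(unname(w1["lin"]), phat, tolerance = 1e-12)
})

test_that("the RMSE study shrinks with the pool size and is seed-stable", {
  s1 <- rmseStudy(nMixtures = 4L, nTrials = 4L, M = 500L, nRange = 1:20,
                  seed = 12L)
  s2 <- rmseStudy(nMixtures = 4L, nTrials = 4L, M = 500L, nRange = 1:20,
                  seed = 12L)
  expect_identical(s1$rmse, s2$rmse)
  big <- rmseStudy(nMixtures = 4L, nTrials = 4L, M = 20000L, nRange = 1:20,
                   seed = 12L)
  expect_lt(big$rmse, s1$rmse)
  expect_lt(big$rmse, 0.02)  # law of large numbers
  expect_identical(nrow(s1$perTrial), 16L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRmseStudy(s1, f)
  expect_identical(nrow(read.delim(f)), 16L)
})

test_that("the error model predicts RMSE from the M/N ratio", {
  expect_equal(predictedRmse(100, 100), 0.24)
  expect_equal(predictedRmse(100, 1), 0.24 * 0.01^0.48, tolerance = 1e-12)
  # RMSE < 1% requires roughly M > 750 N
  ratio <- uniroot(function(r) predictedRmse(r, 1) - 0.01, c(10, 1e5))$root
  expect_equal(ratio, 750, tolerance = 0.01)
  expect_warning(predictedRmse(5, 10), "regime")
  # refit recovers the constants from noiseless model data
  r <- c(0.001, 0.01, 0.1, 1)
  fit <- fitRmseModel(r, 0.24 * r^0.48)
  expect_equal(unname(fit["a"]), 0.24, tolerance = 1e-8)
  expect_equal(unname(fit["b"]), 0.48, tolerance = 1e-8)
})

test_that("generated expression data realises the declared geometry", {
  spec <- expressionSimSpec(nFeatures = 30L, nPerClass = 25L,
                            pairTypes = c("mean", "variance", "correlation"),
                            effectSize = c(2, 3, 0.8), noiseSd = 0.1)
  d1 <- generateExpression(spec, seed = 21L)
  d2 <- generateExpression(spec, seed = 21L)
  expect_identical(d1$exprs, d2$exprs)
  expect_identical(dim(d1$exprs), c(30L, 50L))
  expect_identical(nrow(d1$truth), 3L)
  expect_s4_class(d1$se, "SummarizedExperiment")
  c1 <- d1$labels == "C1"
  # mean-shift pair separates the class means
  expect_gt(mean(d1$exprs[1, !c1]) - mean(d1$exprs[1, c1]), 1)
  # variance-shift pair inflates class-2 spread without moving the mean
  expect_gt(sd(d1$exprs[3, !c1]) / sd(d1$exprs[3, c1]), 1.6)
  # no systematic shift: averaged over 20 seeds the class-mean gap is
  # within 3 SE of zero (per-seed SE = sqrt((1 + e^2)/nPerClass), e = 3)
  gaps <- vapply(1:20, function(s) {
    d <- generateExpression(spec, seed = s)
    i1 <- d$labels == "C1"
    mean(d$exprs[3, !i1]) - mean(d$exprs[3, i1])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 3 * sqrt((1 + 9) / 25) / sqrt(20))
  # correlation-shift pair flips the sign of the within-class correlation
  expect_gt(cor(d1$exprs[5, c1], d1$exprs[6, c1]), 0.4)
  expect_lt(cor(d1$exprs[5, !c1], d1$exprs[6, !c1]), -0.4)
})

test_that("null expression data scores at chance for every classifier", {
  spec <- expressionSimSpec(nFeatures = 16L, nPerClass = 24L,
                            pairTypes = character(0), noiseSd = 0.2)
  d <- generateExpression(spec, seed = 31L)
  cv <- cvConfig(seed = 7L)
  sets <- withr::with_seed(5L, replicate(25, sort(sample.int(16, 2)),
                                         simplify = FALSE))
  perf <- vapply(sets, function(fs)
    crossValidate(t(d$exprs), d$labels, fs, "NC", cv), numeric(1))
  expect_lt(abs(mean(perf) - 0.5), 0.05)
  # the best of six on null data sits above 0.5: picking the maximum of
  # several noisy estimates biases the winner's score upward
  best <- vapply(sets[1:12], function(fs)
    bestPerformance(t(d$exprs), d$labels, fs, cv = cv)@x, numeric(1))
  expect_gt(mean(best), 0.5)
})

test_that("informative pairs recruit the matching classifier family", {
  cv <- cvConfig(seed = 13L)
  countWinners <- function(type, effect, family, R = 20L) {
    hits <- 0L; base <- 0L
    for (r in seq_len(R)) {
      spec <- expressionSimSpec(nFeatures = 2L, nPerClass = 25L,
                                pairTypes = type, effectSize = effect,
                                noiseSd = 0.1)
      d <- generateExpression(spec, seed = 500L + r)
      ps <- bestPerformance(t(d$exprs), d$labels, 1:2, cv = cv)
      hits <- hits + any(ps@winners %in% family)
      permLab <- withr::with_seed(900L + r, sample(d$labels))
      psPerm <- bestPerformance(t(d$exprs), permLab, 1:2, cv = cv)
      base <- base + any(psPerm@winners %in% family)
    }
    c(hits = hits, base = base, R = R)
  }
  # strong mean shift: a pooled/linear classifier (NC among them) should win
  lin <- countWinners("mean", 3, c("NC", "DLDA", "LDA"))
  expect_gte(lin["hits"], 0.8 * lin["R"])
  # strong variance shift: an unpooled classifier should win far more often
  # than on permuted labels
  quad <- countWinners("variance", 4, c("SDA", "UDA", "QDA"))
  expect_gte(quad["hits"], 0.8 * quad["R"])
})

test_that("expression writers round-trip through delimited text", {
  spec <- expressionSimSpec(nFeatures = 8L, nPerClass = 5L,
                            pairTypes = "mean", effectSize = 2)
  d <- generateExpression(spec, seed = 3L)
  mf <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  tf <- withr::local_tempfile(fileext = ".json")
  writeExpression(d, mf, lf, tf)
  se <- loadDataset(mf, lf)
  expect_equal(SummarizedExperiment::assay(se, "exprs"), d$exprs,
               tolerance = 1e-12)
  expect_identical(as.character(se$class), as.character(d$labels))
  truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_identical(truth$type, "mean")
})
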