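test_that("balanced accuracy is the (weighted) mean of sensitivity and specificity", {
  expect_equal(balancedAccuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  # all predicted positive: sensitivity 1, specificity 0
  expect_equal(balancedAccuracy(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0.5)
  # sens 0.8, spec 0.6 -> 0.7
  truth <- rep(c("neg", "pos"), each = 10)
  pred <- c(rep("neg", 6), rep("pos", 4), rep("pos", 8), rep("neg", 2))
  expect_equal(balancedAccuracy(truth, pred), 0.7)
  expect_equal(balancedAccuracy(truth, pred, weight = 1), 0.8)
  expect_equal(balancedAccuracy(truth, pred, weight = 0), 0.6)
  # class-relabel invariance: swapping labels swaps sens/spec, mean unchanged
  swap <- function(v) ifelse(v == "pos", "neg", "pos")
  expect_equal(balancedAccuracy(swap(truth), swap(pred)), 0.7)
  # equals plain accuracy when class proportions are equal
  expect_equal(balancedAccuracy(truth, pred), mean(truth == pred))
  # undefined when a class is absent
  expect_true(is.na(balancedAccuracy(factor(rep("pos", 4),
                                            levels = c("neg", "pos")),
                                     c("neg", "pos", "pos", "pos"))))
  expect_error(balancedAccuracy(truth, pred[-1]), "length")
})

test_that("cross-validation is deterministic, fold-shared and feature-order invariant", {
  d <- separableData(n = 15L)
  cv <- cvConfig(seed = 31L)
  a <- crossValidate(d$x, d$labels, 1:2, "LDA", cv)
  expect_identical(a, crossValidate(d$x, d$labels, 1:2, "LDA", cv))
  expect_identical(a, crossValidate(d$x, d$labels, 2:1, "LDA", cv))
  expect_equal(a, 1.0)  # separable clouds
  # every class must have at least nFolds samples
  expect_error(crossValidate(d$x[c(1:2, 16:30), ], d$labels[c(1:2, 16:30)],
                             1:2, "LDA", cv), "nFolds")
})

test_that("cross-validated performance is at chance on label-permuted data", {
  d <- nullData(nFeatures = 12L, n = 24L, seed = 3L)
  cv <- cvConfig(seed = 17L)
  sets <- withr::with_seed(8L, replicate(40, sort(sample.int(12, 2)),
                                         simplify = FALSE))
  perf <- vapply(sets, function(fs)
    crossValidate(d$x, d$labels, fs, "LDA", cv), numeric(1))
  expect_lt(abs(mean(perf) - 0.5), 0.04)
})

test_that("best performance is the max over classifiers, with exact-tie winners", {
  d <- separableData(n = 12L, gap = 2, seed = 9L)
  cv <- cvConfig(seed = 5L)
  specs <- classifierRoster()
  ps <- bestPerformance(d$x, d$labels, 1:2, specs, cv)
  each <- vapply(specs, function(sp)
    crossValidate(d$x, d$labels, 1:2, sp, cv), numeric(1))
  expect_equal(ps@x, max(each))
  expect_setequal(ps@winners, names(each)[round(each, 12) == round(max(each), 12)])
  # single spec: winners is that singleton
  one <- bestPerformance(d$x, d$labels, 1:2, list(classifierSpec("QDA")), cv)
  expect_identical(one@winners, "QDA")
  expect_equal(one@x, each[["QDA"]])
  # duplicated feature gives SDA/NC (and UDA/DLDA, LDA/QDA) identical fold
  # predictions up to the constraint; at minimum ties must be detected when
  # two specs score identically
  expect_true(length(ps@winners) >= 1)
})

test_that("identical classifiers under symmetry land in the same winner set", {
  # one informative feature duplicated: diagonal and full covariances agree,
  # so DLDA/LDA tie exactly (as do UDA/QDA) on every fold
  d <- separableData(n = 12L, gap = 3, seed = 13L)
  x <- cbind(d$x[, 1], d$x[, 1])
  cv <- cvConfig(seed = 2L)
  ps <- bestPerformance(x, d$labels, 1:2, classifierRoster(), cv)
  if ("DLDA" %in% ps@winners) expect_true("LDA" %in% ps@winners)
  if ("UDA" %in% ps@winners) expect_true("QDA" %in% ps@winners)
})

test_that("evaluateFeatureSpace equals a sequential loop and records errors", {
  d <- separableData(n = 12L, gap = 1.5, seed = 77L)
  x <- cbind(d$x, matrix(rnorm(96), 24, 4))
  cv <- cvConfig(seed = 11L)
  sets <- list(1:2, c(3L, 4L), c(2L, 5L), 1:2)  # includes a duplicate
  specs <- classifierRoster()
  res <- evaluateFeatureSpace(x, d$labels, sets, specs, cv)
  seq <- lapply(sets, function(fs) bestPerformance(x, d$labels, fs, specs, cv))
  for (i in seq_along(sets)) {
    expect_equal(res[[i]]@x, seq[[i]]@x)
    expect_identical(res[[i]]@winners, seq[[i]]@winners)
  }
  # duplicates are bitwise identical
  expect_identical(res[[1]]@x, res[[4]]@x)
  expect_identical(res[[1]]@winners, res[[4]]@winners)
  expect_error(evaluateFeatureSpace(x, d$labels, list(), specs, cv),
               "non-empty")
  # an invalid feature set becomes a recorded error entry, not a skip
  res2 <- evaluateFeatureSpace(x, d$labels, list(1:2, c(1L, 99L)), specs, cv)
  expect_s4_class(res2[[1]], "PerformanceSample")
  expect_s3_class(res2[[2]], "performanceError")
  expect_identical(res2[[2]]$index, 2L)
})

test_that("fine reanalysis stars a truly better classifier and handles exact ties", {
  d <- varianceShiftData(n = 40L, ratio = 4, seed = 15L)
  cv <- cvConfig(5L, 10L, seed = 19L)
  out <- fineReanalysis(d$x, d$labels, list(1:2), classifierRoster(), cv,
                        alpha = 0.05)
  labs <- names(classifierRoster())
  expect_identical(names(out), c("featureSet", labs, "top", "starred"))
  # the quadratic boundary favours an unpooled classifier over NC ...
  expect_true(out$top %in% c("SDA", "UDA", "QDA"))
  pv <- attr(out, "pvalues")
  expect_lt(pv[1, "NC"], 0.05)
  expect_gt(out[[out$top[1]]][1], out$NC[1])
  # a duplicated-feature design makes DLDA/LDA identical on every fold:
  # zero-variance zero-mean differences must give p = 1, never star
  x2 <- cbind(d$x[, 1], d$x[, 1])
  out2 <- fineReanalysis(d$x, d$labels, list(1:2),
                         list(classifierSpec("LDA"), classifierSpec("LDA")),
                         cv)
  expect_false(out2$starred[1])
  expect_equal(unname(attr(out2, "pvalues")[1, 2]), 1)
})

test_that("reanalysis table writer marks the significant top classifier", {
  d <- varianceShiftData(n = 30L, ratio = 5, seed = 4L)
  colnames(d$x) <- c("geneA", "geneB")
  cv <- cvConfig(5L, 8L, seed = 3L)
  out <- fineReanalysis(d$x, d$labels, list(c("geneA", "geneB")),
                        classifierRoster(), cv)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReanalysisTable(out, f)
  tab <- read.delim(f, colClasses = "character")
  expect_identical(names(tab)[1:2], c("Gene1", "Gene2"))
  expect_identical(tab$Gene1, "geneA")
  stars <- grepl("\\*", unlist(tab[1, names(classifierRoster())]))
  expect_identical(sum(stars), as.integer(out$starred[1]))
  if (out$starred[1])
    expect_true(grepl("\\*$", tab[1, out$top[1]]))
})
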