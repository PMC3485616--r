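#' Load a two-class expression dataset from delimited text
#'
#' Expects features in rows with an identifier column first and samples in
#' columns (the transposed layout is auto-detected by matching the label
#' count against the matrix dimensions).  Labels come from a separate
#' two-column file (sample, class) or from a vector.  Rows with missing or
#' non-numeric entries are rejected with an error naming the offending cell;
#' duplicate feature identifiers are disambiguated with suffixes and
#' reported.
#'
#' @param matrixPath delimited text matrix file.
#' @param labelsPath optional label file (columns sample, class).
#' @param labels optional label vector, one per sample, used instead of
#'   `labelsPath`.
#' @param sep field delimiter.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` (features x samples) and a two-level `class` column.
#' @export
loadDataset <- function(matrixPath, labelsPath = NULL, labels = NULL,
                        sep = "\t") {
  raw <- data.table::fread(matrixPath, sep = sep, header = TRUE,
                           data.table = FALSE, colClasses = NULL)
  ids <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d (feature '%s'), column '%s'",
                     v[bad[1L]], bad[1L], ids[bad[1L]], names(vals)[j]))
      vals[[j]] <- num
    }
  }
  X <- as.matrix(vals)
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)
    stop("missing values in rows: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  if (is.null(labels)) {
    if (is.null(labelsPath)) stop("provide labelsPath or labels")
    lab <- utils::read.delim(labelsPath, sep = sep,
                             stringsAsFactors = FALSE)
    labels <- lab[[ncol(lab)]]
    if (!is.null(lab$sample) && all(colnames(X) %in% lab$sample))
      labels <- labels[match(colnames(X), lab$sample)]
  }
  if (length(labels) == nrow(X) && length(labels) != ncol(X)) {
    # transposed layout: the file's rows were samples, its headers features
    smp <- ids
    feat <- colnames(X)
    X <- t(X)
    rownames(X) <- feat
    colnames(X) <- smp
    ids <- feat
  }
  if (length(labels) != ncol(X))
    stop("label count (", length(labels), ") does not match sample count (",
         ncol(X), ")")
  if (anyDuplicated(ids)) {
    ndup <- sum(duplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
    message("disambiguated ", ndup, " duplicate feature identifier(s)")
  }
  rownames(X) <- ids
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(class = labels,
                                   row.names = colnames(X)))
}

#' Write a dataset as delimited text
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` and `class` column data.
#' @param matrixPath,labelsPath output files.
#' @param sep field delimiter.
#' @export
writeDataset <- function(se, matrixPath, labelsPath, sep = "\t") {
  X <- SummarizedExperiment::assay(se, "exprs")
  df <- data.frame(feature = rownames(X), X, check.names = FALSE)
  data.table::fwrite(df, matrixPath, sep = sep)
  utils::write.table(
    data.frame(sample = colnames(X),
               class = as.character(se$class)),
    labelsPath, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

.exprsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "exprs")
  else as.matrix(x)
}

.labelsOf <- function(x, labels = NULL) {
  if (!is.null(labels)) return(labels)
  if (is(x, "SummarizedExperiment")) return(x$class)
  stop("labels are required when x is a plain matrix")
}

# Standard error of the sample excess kurtosis (exact small-sample form).
.kurtosisSE <- function(n) {
  seSkew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  2 * seSkew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Gaussian feature filter based on the kurtosis standard error
#'
#' Keeps features whose bias-corrected sample excess kurtosis is within
#' `zThreshold` standard errors of zero, i.e. features compatible with
#' marginal normality — the eligibility rule that defines the pool of
#' Gaussian feature pairs the classifiers assume.  The standard error uses
#' the exact small-sample formula, not the asymptotic sqrt(24/n).
#'
#' @param x a SummarizedExperiment (assay `exprs`) or features-by-samples
#'   matrix.
#' @param zThreshold number of kurtosis standard errors tolerated (default
#'   2; `Inf` keeps everything).
#' @return list with `eligible` (feature identifiers kept), `report`
#'   (kept/total counts and the threshold) and `perFeature` (data.frame of
#'   excess kurtosis and z-scores).
#' @export
gaussianFilter <- function(x, zThreshold = 2) {
  X <- .exprsOf(x)
  n <- ncol(X)
  if (n < 4L) stop("kurtosis needs at least 4 samples")
  g2 <- apply(X, 1L, e1071::kurtosis, type = 2L)
  se <- .kurtosisSE(n)
  z <- g2 / se
  keep <- abs(z) <= zThreshold
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  list(eligible = ids[keep],
       report = list(total = nrow(X), kept = sum(keep),
                     zThreshold = zThreshold, kurtosisSE = se),
       perFeature = data.frame(feature = ids, excessKurtosis = g2, z = z,
                               eligible = keep, stringsAsFactors = FALSE))
}

#' Enumerate all unordered feature pairs
#'
#' @param features vector of feature identifiers (length F >= 2).
#' @return list with `count` = F(F-1)/2, `nextPair()` (an iterator yielding
#'   each unordered pair once in deterministic lexicographic order, then
#'   `NULL`), and `reset()`.
#' @export
enumeratePairs <- function(features) {
  F <- length(features)
  if (F < 2L) stop("need at least 2 features to form pairs")
  i <- 1L; j <- 1L
  list(
    count = F * (F - 1) / 2,
    nextPair = function() {
      j <<- j + 1L
      if (j > F) { i <<- i + 1L; j <<- i + 1L }
      if (i >= F) return(NULL)
      features[c(i, j)]
    },
    reset = function() { i <<- 1L; j <<- 1L; invisible(NULL) })
}

#' Sample feature pairs uniformly with replacement
#'
#' @param features vector of feature identifiers.
#' @param M number of pairs to draw.
#' @param seed optional integer seed (isolated stream).
#' @return list of M unordered pairs.
#' @export
samplePairs <- function(features, M, seed = NULL) {
  F <- length(features)
  if (F < 2L) stop("need at least 2 features to form pairs")
  draw <- function() lapply(seq_len(M), function(i)
    features[sort(sample.int(F, 2L))])
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one serialisable object;
#' all randomness flows from the single root `seed`.
#'
#' @param M number of feature pairs to sample (ignored in exhaustive mode).
#' @param exhaustive evaluate every eligible pair instead of sampling.
#' @param nGrid vector of subsample sizes N for the win curve.
#' @param seed root seed.
#' @param coarseCv,fineCv fold/iteration settings as `c(nFolds, nIterations)`.
#' @param zThreshold Gaussian-filter threshold ([gaussianFilter()]).
#' @param familyAlpha family-wise false positive rate for significance.
#' @param q null win chance (default 1/6 for the six-classifier roster).
#' @param effectiveM optional effective independent-sample count for the
#'   null model.
#' @param fineTop number of top feature sets to reanalyse with the fine CV
#'   scheme (0 disables the reanalysis).
#' @param classifiers classifier labels to evaluate.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(M = 200L, exhaustive = FALSE,
                      nGrid = logNGrid(0, 4, 2), seed = 1L,
                      coarseCv = c(3L, 2L), fineCv = c(5L, 20L),
                      zThreshold = 2, familyAlpha = 0.05,
                      q = 1 / length(classifiers), effectiveM = NULL,
                      fineTop = 0L,
                      classifiers = names(classifierRoster())) {
  cfg <- list(M = as.integer(M), exhaustive = isTRUE(exhaustive),
              nGrid = as.numeric(nGrid), seed = as.integer(seed),
              coarseCv = as.integer(coarseCv), fineCv = as.integer(fineCv),
              zThreshold = as.numeric(zThreshold),
              familyAlpha = as.numeric(familyAlpha), q = as.numeric(q),
              effectiveM = if (is.null(effectiveM)) NULL
                           else as.integer(effectiveM),
              fineTop = as.integer(fineTop),
              classifiers = as.character(classifiers))
  stopifnot(cfg$M >= 1L, length(cfg$coarseCv) == 2L, length(cfg$fineCv) == 2L,
            cfg$familyAlpha > 0, cfg$familyAlpha < 1, cfg$q > 0, cfg$q < 1,
            all(cfg$classifiers %in% .CLASSIFIER_TABLE$label))
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @param path YAML file.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname runConfig
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg[!vapply(cfg, is.null, TRUE)])
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full win-percentage pipeline
#'
#' Filter to Gaussian features, sample (or exhaust) the feature-pair space,
#' evaluate every candidate classifier per pair with coarse CV, build the
#' ranked win table and win curve over the N grid, fit the null model and
#' report significance per N, and optionally reanalyse the top feature sets
#' with the fine CV scheme.  Every stage is seeded from the config's root
#' seed and logged with its size; with `checkpointDir` set, completed stages
#' are written to disk and reused on rerun.
#'
#' @param dataset a SummarizedExperiment (assay `exprs`, `class` column) or
#'   a features-by-samples matrix combined with `labels`.
#' @param config a [runConfig()].
#' @param labels labels when `dataset` is a plain matrix.
#' @param checkpointDir optional directory for resumable stage checkpoints.
#' @return list of class `winpctAnalysis` with elements `filter`, `samples`
#'   (the S_M pool), `errors`, `winTable`, `winCurve`, `significance`,
#'   `reanalysis` (or NULL), and `config`.
#' @export
runPipeline <- function(dataset, config = runConfig(), labels = NULL,
                        checkpointDir = NULL) {
  X <- .exprsOf(dataset)
  labels <- .labelsOf(dataset, labels)
  ckpt <- function(name, expr) {
    if (is.null(checkpointDir)) return(expr)
    dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(checkpointDir, paste0(name, ".rds"))
    if (file.exists(f)) { .logStage(name, "(resumed from checkpoint)");
                          return(readRDS(f)) }
    val <- expr
    saveRDS(val, f)
    val
  }

  .logStage("filter", sprintf("%d features x %d samples", nrow(X), ncol(X)))
  filt <- ckpt("filter", gaussianFilter(X, config$zThreshold))
  elig <- filt$eligible
  if (length(elig) < 2L) stop("fewer than 2 features pass the Gaussian filter")
  .logStage("filter", sprintf("kept %d / %d features", length(elig),
                              nrow(X)))

  space <- enumeratePairs(elig)
  featureSets <- if (config$exhaustive) {
    cmb <- utils::combn(elig, 2L, simplify = FALSE)
    .logStage("pairs", sprintf("exhaustive: %d pairs", length(cmb)))
    cmb
  } else {
    .logStage("pairs", sprintf("sampling M = %d of %.0f pairs", config$M,
                               space$count))
    samplePairs(elig, config$M, seed = config$seed)
  }

  cv <- cvConfig(config$coarseCv[1L], config$coarseCv[2L],
                 seed = config$seed)
  specs <- lapply(config$classifiers, classifierSpec)
  t0 <- Sys.time()
  res <- ckpt("evaluate",
              evaluateFeatureSpace(t(X), labels, featureSets, specs, cv))
  ok <- !vapply(res, inherits, TRUE, "performanceError")
  .logStage("evaluate", sprintf("%d sets in %.1fs (%d failed)", length(res),
                                as.numeric(Sys.time() - t0, units = "secs"),
                                sum(!ok)))

  wt <- winTable(res[ok])
  curve <- ckpt("wincurve", winCurve(wt, config$nGrid,
                                     labels = config$classifiers))
  .logStage("wincurve", sprintf("%d N values", length(config$nGrid)))

  sig <- significanceReport(wt, config$nGrid, q = config$q,
                            nClassifiers = length(config$classifiers),
                            familyAlpha = config$familyAlpha,
                            effectiveM = config$effectiveM,
                            labels = config$classifiers)
  .logStage("significance", sprintf("%d verdicts", nrow(sig)))

  rean <- NULL
  if (config$fineTop > 0L) {
    xs <- vapply(res[ok], function(s) s@x, numeric(1))
    top <- order(xs, decreasing = TRUE)[seq_len(min(config$fineTop,
                                                    sum(ok)))]
    topSets <- lapply(res[ok][top], function(s) s@featureSet)
    fcv <- cvConfig(config$fineCv[1L], config$fineCv[2L],
                    seed = config$seed)
    t0 <- Sys.time()
    rean <- ckpt("reanalysis",
                 fineReanalysis(t(X), labels, topSets, specs, fcv,
                                alpha = config$familyAlpha))
    .logStage("reanalysis", sprintf("%d sets in %.1fs", length(topSets),
                                    as.numeric(Sys.time() - t0,
                                               units = "secs")))
  }

  structure(list(filter = filt, samples = res[ok], errors = res[!ok],
                 winTable = wt, winCurve = curve, significance = sig,
                 reanalysis = rean, config = config),
            class = "winpctAnalysis")
}
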