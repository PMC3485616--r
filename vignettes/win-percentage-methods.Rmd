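---
title: "Win percentage: methods and implementation notes"
author: "winpct package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Win percentage: methods and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winpct)
```

## Motivation

Choosing a classifier for a biological prediction problem is usually framed
as "which model scores best on my data?". When the feature space is enormous
— say, all pairs of genes on a microarray — that question is incomplete: a
classifier that performs superbly on one specific feature pair may be
useless on almost every other pair, while a more modest but robust
classifier may be the better bet when only a limited number of feature sets
can be explored. The *win percentage* makes this trade-off explicit: it is
the probability that a classifier attains the best cross-validated
performance on the best of `N` randomly drawn feature sets. It is therefore
a function of the search effort `N`, and different classifiers can be
preferred at different exploration depths.

## The candidate classifiers

`winpct` ships six Gaussian Bayes classifiers obtained by crossing two
design axes:

* **pooling** — one covariance shared by both classes (linear decision
  boundary) or one covariance per class (quadratic boundary);
* **structure** — spherical (`sigma^2 I`), diagonal, or full covariance.

This yields NC, DLDA, LDA (pooled spherical/diagonal/full) and SDA, UDA,
QDA (unpooled spherical/diagonal/full). Class priors are fixed uniform, so
prediction assigns the class with the larger Gaussian log-density. For two
classes and `d` features the parameter counts are `2d` mean parameters plus
1, `d`, or `d(d+1)/2` covariance parameters, doubled when unpooled:

```{r df}
vapply(names(classifierRoster()), degreesOfFreedom, integer(1), d = 2L)
```

Implementation notes: covariances are maximum-likelihood estimates (pooled
scatter divided by `n - 2`); variances are floored at `1e-12` and full
covariances receive a relative ridge of `1e-9 * trace/d` so degenerate
training splits cannot produce singular fits; prediction ties resolve to
the first class level, deterministically.

## Performance and cross-validation

Performance is **balanced accuracy** — the mean of sensitivity and
specificity — which is insensitive to class imbalance and equals plain
accuracy on balanced data. The default protocol is 2-fold cross-validation
repeated 3 times with stratified folds. Folds are derived once from the
configuration seed and shared by all six classifiers, so

* the same feature set always yields bit-identical scores, and
* per-fold scores are *paired* across classifiers, which licenses the
  paired t-tests used in the fine reanalysis (20 repetitions of 5-fold CV
  on the top feature sets).

`bestPerformance()` records, per feature set, the maximum score `x` and the
set of classifiers attaining it (ties are detected after rounding to 12
decimals). `evaluateFeatureSpace()` maps this over a list of feature sets.

## Continuous win percentage

For a performance mixture with per-classifier densities
`p(x | c)` and priors `p(c)`, the winning performance of the best of `N`
draws has density `N P(x)^(N-1) p(x)`, and

```
win(c) = ∫ p(c | x) · N · P(x)^(N-1) · p(x) dx .
```

Substituting `u = P(x)^N` turns this into `∫₀¹ p(c | x(u)) du` with
`x(u) = F⁻¹(u^(1/N))`, which is bounded, smooth, and independent of the
magnitude of `N`. The implementation:

* computes the survival target `s = 1 - u^(1/N)` as `-expm1(log(u)/N)`,
  which stays accurate for `N` as large as `1e10`;
* inverts the mixture CDF by bisection on the log-survival function (60
  iterations inside a ±16σ bracket);
* integrates with composite Gauss–Legendre quadrature (48 nodes × 8
  panels); agreement with an independent adaptive quadrature in `x`-space
  is a few parts in `1e6`.

A three-component example with a wide mediocre classifier, a moderate one,
and a narrow specialist shows the characteristic crossover: the specialist
wins for small `N`, the moderate classifier for intermediate `N`, and the
wide one once `N` reaches 27:

```{r crossover}
mix <- performanceMixture(c(0.50, 0.70, 0.75), c(0.20, 0.07, 0.02))
w <- continuousWin(mix, c(1, 5, 15, 27, 40))
round(w, 3)
```

## Discrete win percentage

With an evaluated pool of `M` feature sets (performance `x_i`, winner set
`C_i`), sampling `N` sets with replacement selects rank `r` as the best
with probability

```
w_r = ((M - r + 1) / M)^N  -  ((M - r) / M)^N ,
```

generalised to tie blocks by replacing the inner term with the block
boundaries. The discrete win percentage credits `w_i / |C_i|` to each
classifier in the winner set — equal apportionment within a tie block is
equivalent, by exchangeability, to picking one tied sample at random. The
implementation evaluates the weights as differences of
`exp(N · log1p(-k/M))`, which is exact even at astronomical `N`, and is
verified in the tests against exhaustive `M^N` enumeration. At `N = 1` the
weights are uniform (`1/M`); as `N` grows they concentrate on the top
ranks — the *selection pressure* of the wrapper.

## Sampling error and planning

Because the pool of `M` sets is itself a sample, the discrete win
percentage carries sampling error. Simulation over random mixtures (see
`rmseStudy()`) shows the pooled RMSE scales almost exactly as `M^(-1/2)`
at fixed `N`; the package also exposes the empirical error model
`predictedRmse(M, N) = 0.24 (N/M)^0.48`, whose 1% contour is `M ≈ 750 N`.

Planning a Monte Carlo wrapper run uses the exact relation
`ε = (1 - p)^N` between the failure tolerance `ε`, the target top fraction
`p`, and the number of draws `N`:

```{r plan}
requiredIterations(epsilon = 1e-6, topFraction = 0.0137)
signif(topFraction(1e-3, 100), 3)
expectedUniqueFraction(1e6, 1e5)
```

## Significance of a win percentage

Under the null hypothesis that winners are assigned to samples at random
with probability `q = 1/K`, the win percentage is a weighted Bernoulli sum
with mean `q` and variance `q(1 - q) Σ w_i²`. A beta distribution matched
to these moments provides two-sided critical values; the default family
level 0.05 is split over the `K - 1 = 5` independent comparisons among six
classifiers, so each tail uses 0.005. As `N` grows, `Σ w_i²` grows, the
null widens, and larger deviations from `1/K` are needed for significance.
When the pool was built from correlated feature sets, `effectiveM` lets
the user discount the number of independent samples. The degenerate case
`Σ w_i² = 1` (all weight on one sample) yields the vacuous band (0, 1).

## Synthetic data

Two generators support validation end to end:

* `randomMixture()` draws mixture components with means from
  `N(0.5, 0.1)`, standard deviations from `|N(0, 0.1)|`, and priors either
  uniform on the simplex (default) or equal — both readings of "uniform
  priors" are supported.
* `generateExpression()` builds a features × samples matrix with planted
  informative pairs of three geometries: a **mean** shift (favouring the
  pooled, linear classifiers), a **variance** inflation, and a
  **correlation** sign flip (both favouring the unpooled, quadratic
  classifiers), plus Gaussian noise. The tests verify that each geometry
  recruits the matching classifier family far above a permuted-label
  baseline.

## Pipeline

`runPipeline()` chains the pieces: kurtosis-based Gaussian filtering
(`gaussianFilter()`, cut at `z` standard errors of the exact small-sample
kurtosis SE), pair enumeration or sampling, feature-space evaluation, the
win table and win curve, per-`N` significance verdicts, and the optional
fine reanalysis of the top sets. All stages derive their randomness from
the single configuration seed, so reruns are bit-identical; optional RDS
checkpoints allow resuming the expensive evaluation stage.

## Limitations

* The continuous form requires a parametric (Gaussian mixture) performance
  model; the discrete form is the practical tool for real data.
* Balanced accuracy is the only performance measure implemented.
* The beta null assumes exchangeable winner assignments; correlated
  feature sets are only approximately handled via `effectiveM`.
* A permutation-based empirical null (shuffling winner labels) is
  exercised in the test suite but not exposed as a first-class API.
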