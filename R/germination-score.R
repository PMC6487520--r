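## Germination target score and its Bernoulli-derived noise model.
##
## Each seed is a two-stage Bernoulli trial: it germinates with probability
## p, and a germinated seed is additionally well-germinated with
## probability q. A seed contributes Z = 1{germinated} + 1{well-germinated}
## to the score y = (Ng + Nwg) / N, so E y = p(1+q) and, for one seed,
## Var Z = p(1+3q) - p^2 (1+q)^2. For a run of N seeds y is approximately
## normal with variance Var Z / N, which is used as an input-dependent
## noise level for the GP.

#' Construct a germination count
#'
#' @param N seeds placed.
#' @param Ng germinated seeds (radicle emerged), \emph{including} the
#'   well-germinated ones.
#' @param Nwg well-germinated seeds.
#' @return a validated [GerminationCount-class].
#' @examples
#' germinationCount(100, 80, 33)
#' @export
germinationCount <- function(N, Ng, Nwg) {
  new("GerminationCount", N = as.integer(N), Ng = as.integer(Ng),
      Nwg = as.integer(Nwg))
}

#' Germination target score
#'
#' `y = (Ng + Nwg) / N`, in \[0, 2\]: each germinated seed counts once and
#' each well-germinated seed counts once more. This is the quantity the
#' optimizer maximizes.
#'
#' @param count a [GerminationCount-class], or `N` seeds when `Ng`/`Nwg`
#'   are given directly.
#' @param Ng,Nwg counts, when not passing a GerminationCount (vectorized).
#' @return numeric score(s) in \[0, 2\].
#' @examples
#' targetScore(germinationCount(100, 73, 0))   # 0.73
#' targetScore(germinationCount(100, 80, 33))  # 1.13
#' @export
targetScore <- function(count, Ng = NULL, Nwg = NULL) {
  if (is(count, "GerminationCount")) {
    validObject(count)
    return((count@Ng + count@Nwg) / count@N)
  }
  N <- count
  stopIfNot(!is.null(Ng) && !is.null(Nwg), "need Ng and Nwg")
  stopIfNot(all(Nwg >= 0 & Nwg <= Ng & Ng <= N),
            "need 0 <= Nwg <= Ng <= N")
  (Ng + Nwg) / N
}

#' Germination efficiency as percent of the metric maximum
#'
#' The score y has maximum 2 (every seed well-germinated); efficiency is
#' `y / 2 * 100`.
#'
#' @param y score(s) in \[0, 2\].
#' @param digits if non-NULL, decimal half-up rounding to this many places
#'   (reports use one decimal).
#' @return percent value(s).
#' @examples
#' efficiencyPercent(0.73)  # 36.5
#' efficiencyPercent(1.13)  # 56.5
#' @export
efficiencyPercent <- function(y, digits = NULL) {
  stopIfNot(all(y >= 0 & y <= 2), "score must lie in [0, 2]")
  e <- y / 2 * 100
  if (!is.null(digits)) e <- roundHalfUp(e, digits)
  e
}

#' Mean of the score under the two-stage Bernoulli model
#'
#' @param p germination probability in \[0, 1\].
#' @param q conditional well-germination probability in \[0, 1\].
#' @return `p * (1 + q)` (vectorized).
#' @export
modelMean <- function(p, q) {
  stopIfNot(all(p >= 0 & p <= 1 & q >= 0 & q <= 1), "p, q must lie in [0, 1]")
  p * (1 + q)
}

#' Single-seed score variance under the two-stage Bernoulli model
#'
#' Variance of Z = 1\{germinated\} + 1\{well-germinated\} for one seed:
#' `p (1 + 3 q) - p^2 (1 + q)^2`. For a run of N seeds the score variance
#' is this divided by N.
#'
#' @inheritParams modelMean
#' @return variance(s), nonnegative on the unit square, maximum 1 at
#'   `(p, q) = (0.5, 1)`.
#' @export
modelVariance <- function(p, q) {
  stopIfNot(all(p >= 0 & p <= 1 & q >= 0 & q <= 1), "p, q must lie in [0, 1]")
  p * (1 + 3 * q) - p^2 * (1 + q)^2
}

#' Global noise-variance floor
#'
#' `max over (p, q) of modelVariance / N = 1 / N`; with N = 100 seeds this
#' gives the 0.01 lower bound used for the white-noise kernel
#' hyperparameter.
#'
#' @param N seeds per run, >= 1.
#' @return `1 / N`.
#' @export
varianceFloorGlobal <- function(N) {
  stopIfNot(all(N >= 1), "N must be >= 1")
  1 / N
}

#' Per-observation noise-variance floor
#'
#' `y (2 - y) / N`: the supremum of the single-seed variance over all
#' (p, q) consistent with observed mean y, divided by N. (The gap
#' `y(2-y) - modelVariance` equals `p (1 - q) >= 0`, with equality at
#' q = 1, p = y/2.)
#'
#' @param y observed score(s) in \[0, 2\].
#' @param N seeds per run, >= 1.
#' @return floor value(s).
#' @export
varianceFloorPerObs <- function(y, N) {
  stopIfNot(all(y >= 0 & y <= 2), "score must lie in [0, 2]")
  stopIfNot(all(N >= 1), "N must be >= 1")
  y * (2 - y) / N
}

#' Exact two-stage Bernoulli sampler of the score
#'
#' Draws `G ~ Binomial(N, p)`, then `W ~ Binomial(G, q)`, and returns
#' `(G + W) / N`. The exact finite-N counterpart of the normal
#' approximation behind [modelMean()] / [modelVariance()].
#'
#' @inheritParams modelMean
#' @param N seeds per run.
#' @param reps number of independent runs to draw.
#' @return numeric vector of `reps` scores.
#' @export
sampleScore <- function(p, q, N, reps = 1) {
  G <- rbinom(reps, N, p)
  W <- rbinom(reps, G, q)
  (G + W) / N
}
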