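## S4 classes for the germination-optimization framework.

PSPACE_COLS <- c("name", "unit", "low", "high", "scaled_high",
                 "eps_exploit", "eps_explore", "precision")

#' ParameterSpace: the controllable-condition space
#'
#' An ordered set of controllable parameters (chamber temperatures at fixed
#' time points, water supplied on each day, ...) with physical bounds, the
#' upper end of the linear scaling target (e.g. temperatures to \[0, 1\],
#' water to \[0, 0.5\]), per-parameter exploitation/exploration distance
#' thresholds in physical units, and the device rounding precision.
#' Coordinates of parameter vectors are positional against this order.
#'
#' @slot params data.frame with columns `name`, `unit`, `low`, `high`,
#'   `scaled_high`, `eps_exploit`, `eps_explore`, `precision`, one row per
#'   controllable parameter.
#' @export
setClass("ParameterSpace", representation(params = "data.frame"))

setValidity("ParameterSpace", function(object) {
  p <- object@params
  if (!all(PSPACE_COLS %in% names(p)))
    return(paste("params must have columns:", paste(PSPACE_COLS, collapse = ", ")))
  if (nrow(p) < 1) return("at least one parameter required")
  if (anyDuplicated(p$name)) return("parameter names must be unique")
  if (!all(p$low < p$high)) return("each low must be < high")
  if (!all(p$scaled_high > 0)) return("scaled_high must be positive")
  if (!all(p$eps_exploit > 0)) return("eps_exploit must be positive")
  if (!all(p$eps_exploit < p$eps_explore))
    return("eps_exploit must be < eps_explore")
  if (!all(p$eps_explore <= p$high - p$low))
    return("eps_explore must not exceed the physical range")
  if (!all(p$precision > 0)) return("precision must be positive")
  TRUE
})

#' GerminationCount: raw outcome of one germination run
#'
#' `N` seeds placed, `Ng` with an emerged radicle (inclusive of the
#' well-germinated), `Nwg` meeting the stricter well-germinated criterion.
#'
#' @slot N integer, seeds placed (positive).
#' @slot Ng integer, germinated seeds (includes well-germinated).
#' @slot Nwg integer, well-germinated seeds.
#' @export
setClass("GerminationCount",
         representation(N = "integer", Ng = "integer", Nwg = "integer"))

setValidity("GerminationCount", function(object) {
  if (length(object@N) != 1 || length(object@Ng) != 1 || length(object@Nwg) != 1)
    return("N, Ng, Nwg must be scalars")
  if (object@N < 1) return("N must be >= 1")
  if (object@Nwg < 0 || object@Nwg > object@Ng)
    return("need 0 <= Nwg <= Ng (Ng counts well-germinated seeds too)")
  if (object@Ng > object@N) return("need Ng <= N")
  TRUE
})

#' GPFit: a fitted Gaussian-process regression model
#'
#' Constant-mean GP with covariance
#' \eqn{k(x_i, x_j) = \alpha C_{5/2}(x_i/\rho, x_j/\rho) + \sigma^2 \delta_{ij}}.
#' The constant mean is the mean of the training targets. The effective
#' diagonal noise at observation i is \eqn{\sigma^2} in `"global"` mode and
#' \eqn{\max(\sigma^2, floor_i)} in `"per-obs"` mode. Stores the Cholesky
#' factor of the regularized kernel matrix and the cached solve
#' \eqn{(K + D)^{-1}(y - m)} so prediction is cheap.
#'
#' @slot alpha,rho,sigma2 fitted hyperparameters (amplitude, isotropic
#'   length-scale, white-noise variance).
#' @slot bounds 3 x 2 matrix of box bounds used in fitting (rows alpha,
#'   rho, sigma2).
#' @slot mean constant GP mean (mean of the training targets).
#' @slot X n x d matrix of scaled training inputs.
#' @slot y numeric training targets.
#' @slot floors per-observation noise-variance lower bounds.
#' @slot noiseMode `"global"` or `"per-obs"`.
#' @slot L upper-triangular Cholesky factor of K + D (+ jitter).
#' @slot alphaVec cached \eqn{(K+D)^{-1}(y-m)}.
#' @slot logLik log marginal likelihood at the optimum.
#' @export
setClass("GPFit", representation(
  alpha = "numeric", rho = "numeric", sigma2 = "numeric",
  bounds = "matrix", mean = "numeric",
  X = "matrix", y = "numeric", floors = "numeric", noiseMode = "character",
  L = "matrix", alphaVec = "numeric", logLik = "numeric"))

setValidity("GPFit", function(object) {
  n <- nrow(object@X)
  if (length(object@y) != n) return("y length must match rows of X")
  if (length(object@floors) != n) return("floors length must match rows of X")
  if (!object@noiseMode %in% c("global", "per-obs"))
    return("noiseMode must be 'global' or 'per-obs'")
  if (object@alpha <= 0 || object@rho <= 0 || object@sigma2 <= 0)
    return("hyperparameters must be positive")
  TRUE
})

#' GroundTruth: simulator response surfaces
#'
#' Smooth germination-probability surfaces over the scaled parameter box:
#' `p(s)` is the probability that a seed germinates at scaled condition `s`,
#' `q(s)` the conditional probability that a germinated seed is
#' well-germinated. Both map into \[0, 1\].
#'
#' @slot p,q functions from a scaled vector (or matrix of rows) to \[0, 1\].
#' @slot description free-text description of the surface.
#' @slot optimumHint scaled coordinates of the maximizer of `p(1+q)` when
#'   known analytically; length 0 when unknown.
#' @export
setClass("GroundTruth", representation(
  p = "function", q = "function",
  description = "character", optimumHint = "numeric"))

#' Suggestion: one proposed experimental condition
#'
#' @slot x physical-unit coordinates, rounded to device precision.
#' @slot xScaled scaled coordinates of the (rounded) point.
#' @slot acquisitionValue UCB value at the suggestion.
#' @slot kappaUsed the exploration weight under which it was found.
#' @slot exploitSlack normalized exploitation metric (feasible iff >= 1).
#' @slot exploreSlack normalized exploration metric (feasible iff <= 1).
#' @slot feasible whether both distance constraints hold (tolerance 1e-6).
#' @export
setClass("Suggestion", representation(
  x = "numeric", xScaled = "numeric", acquisitionValue = "numeric",
  kappaUsed = "numeric", exploitSlack = "numeric", exploreSlack = "numeric",
  feasible = "logical"))

#' GermSession: a human-in-the-loop optimization session
#'
#' Holds the experiment configuration (parameter space, seeds per trial,
#' batch size, kappa policy, kernel bounds, RNG seed), the ordered trial
#' ledger, and the current GP fit (or NULL when stale/absent).
#'
#' @slot config named list, see [newSession()].
#' @slot ledger data.frame trial ledger, see [newSession()] for columns.
#' @slot fit a [GPFit-class] or NULL.
#' @export
setClass("GermSession", representation(
  config = "list", ledger = "data.frame", fit = "ANY"))
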