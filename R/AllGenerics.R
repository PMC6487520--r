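## Generics and simple accessors / show methods.

#' Map physical parameter values to scaled coordinates
#'
#' @param space a [ParameterSpace-class].
#' @param x numeric vector (positional against the space) or a matrix with
#'   one point per row.
#' @return scaled coordinates, same shape as `x`.
#' @export
setGeneric("toScaled", function(space, x) standardGeneric("toScaled"))

#' Map scaled coordinates back to physical parameter values
#'
#' @param space a [ParameterSpace-class].
#' @param s scaled vector or matrix of rows.
#' @param round round the physical result to each parameter's device
#'   precision (default TRUE; the rounded point is what gets logged).
#' @return physical coordinates, same shape as `s`.
#' @export
setGeneric("fromScaled", function(space, s, round = TRUE) standardGeneric("fromScaled"))

#' @rdname parameterTable
#' @export
setGeneric("parameterTable", function(space) standardGeneric("parameterTable"))

#' @rdname hyperParams
#' @export
setGeneric("hyperParams", function(object) standardGeneric("hyperParams"))

#' Parameter definition table of a space
#'
#' @param space a [ParameterSpace-class].
#' @return the underlying data.frame of parameter definitions.
#' @export
setMethod("parameterTable", "ParameterSpace", function(space) space@params)

#' Fitted kernel hyperparameters
#'
#' @param object a [GPFit-class].
#' @return named numeric vector `c(alpha, rho, sigma2)`.
#' @export
setMethod("hyperParams", "GPFit", function(object)
  c(alpha = object@alpha, rho = object@rho, sigma2 = object@sigma2))

#' @export
setMethod("show", "ParameterSpace", function(object) {
  p <- object@params
  cat(sprintf("ParameterSpace with %d parameters:\n", nrow(p)))
  print(p, row.names = FALSE)
})

#' @export
setMethod("show", "GerminationCount", function(object) {
  cat(sprintf("GerminationCount: N = %d, germinated = %d, well-germinated = %d (y = %.4g)\n",
              object@N, object@Ng, object@Nwg,
              (object@Ng + object@Nwg) / object@N))
})

#' @export
setMethod("show", "GPFit", function(object) {
  cat(sprintf(
    "GPFit: n = %d, d = %d, noise mode '%s'\n  alpha = %.4g, rho = %.4g, sigma2 = %.4g, mean = %.4g, logLik = %.4g\n",
    nrow(object@X), ncol(object@X), object@noiseMode,
    object@alpha, object@rho, object@sigma2, object@mean, object@logLik))
})

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", object@description, "\n")
  if (length(object@optimumHint))
    cat("  optimum hint (scaled):", paste(signif(object@optimumHint, 4), collapse = ", "), "\n")
})

#' @export
setMethod("show", "Suggestion", function(object) {
  cat(sprintf("Suggestion (kappa = %.3g, UCB = %.4g, %s)\n",
              object@kappaUsed, object@acquisitionValue,
              if (object@feasible) "feasible" else "INFEASIBLE"))
  cat("  physical:", paste(signif(object@x, 6), collapse = ", "), "\n")
  cat(sprintf("  slacks: exploit = %.4g (>=1), explore = %.4g (<=1)\n",
              object@exploitSlack, object@exploreSlack))
})

#' @export
setMethod("show", "GermSession", function(object) {
  real <- object@ledger
  cat(sprintf("GermSession: %d ledger rows, N = %d seeds/run, batch = %d\n",
              nrow(real), object@config$N, object@config$batchSize))
  if (!is.null(object@fit)) show(object@fit) else cat("  (no current fit)\n")
})

#' Number of training observations of a GP fit
#'
#' @param object a [GPFit-class].
#' @param ... ignored.
#' @return integer count.
#' @importFrom stats nobs
#' @export
setMethod("nobs", "GPFit", function(object, ...) nrow(object@X))
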