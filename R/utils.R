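## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats optim rbinom runif setNames predict
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for percentages and improvement figures: decimal
#' half-up rounding (95.15 -> 95.2), with a tiny guard against binary
#' representation error so that values that are exact decimals round the
#' way they read.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

## Deterministic child-stream seeds: one session seed fans out into
## per-trial / per-chamber / per-restart streams so that concurrent
## simulations are order-independent. Kept below 2^31 - 1.
childSeed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1000003 * as.numeric(i)
  as.integer(s %% 2147483647) + 1L
}

## Euclidean cross-distance matrix between row sets.
pairwiseDist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  M <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(M, 0))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
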