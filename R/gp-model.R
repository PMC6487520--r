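## Gaussian-process regression: constant mean, amplitude x Matern-5/2 +
## white-noise kernel, MLE with restarts, predictive equations.

#' Matern-5/2 covariance between two scaled points
#'
#' `alpha * (1 + sqrt(5) r + 5 r^2 / 3) * exp(-sqrt(5) r)` with
#' `r = ||a - b|| / rho`. The white-noise term `sigma2` applies only when
#' the two arguments are the same \emph{training index}
#' (`sameIndex = TRUE`), never merely at zero distance.
#'
#' @param a,b scaled vectors of equal dimension.
#' @param alpha amplitude.
#' @param rho isotropic length-scale.
#' @param sigma2 white-noise variance.
#' @param sameIndex is this a diagonal (i == j) kernel-matrix entry?
#' @return covariance value.
#' @export
maternKernel <- function(a, b, alpha, rho, sigma2 = 0, sameIndex = FALSE) {
  stopIfNot(length(a) == length(b), "dimension mismatch")
  r <- sqrt(sum((a - b)^2)) / rho
  s5 <- sqrt(5)
  alpha * (1 + s5 * r + 5 * r^2 / 3) * exp(-s5 * r) +
    if (sameIndex) sigma2 else 0
}

## Dense Matern-5/2 cross-covariance from a distance matrix.
matern52Mat <- function(D, alpha, rho) {
  r <- D / rho
  s5 <- sqrt(5)
  alpha * (1 + s5 * r + 5 * r^2 / 3) * exp(-s5 * r)
}

#' Default kernel hyperparameter bounds
#'
#' Amplitude and length-scale in \[1e-5, 1e5\]; white-noise variance
#' bounded below by the global noise floor `1/N` (0.01 for N = 100).
#'
#' @param N seeds per run used to set the noise lower bound; `NULL` for an
#'   unconstrained 1e-5 lower bound.
#' @return 3 x 2 matrix, rows `alpha`, `rho`, `sigma2`.
#' @export
defaultHyperBounds <- function(N = 100) {
  lowS2 <- if (is.null(N)) 1e-5 else varianceFloorGlobal(N)
  matrix(c(1e-5, 1e5, 1e-5, 1e5, lowS2, 1e5), nrow = 3, byrow = TRUE,
         dimnames = list(c("alpha", "rho", "sigma2"), c("low", "high")))
}

## Effective noise diagonal: sigma2 everywhere (global mode) or
## max(sigma2, floor_i) (per-obs mode).
noiseDiag <- function(sigma2, floors, noiseMode) {
  if (noiseMode == "per-obs") pmax(sigma2, floors) else rep(sigma2, length(floors))
}

## Negative log marginal likelihood in log-hyperparameter coordinates.
negLogLik <- function(logh, D, y, m, floors, noiseMode) {
  a <- exp(logh[1]); rho <- exp(logh[2]); s2 <- exp(logh[3])
  K <- matern52Mat(D, a, rho)
  diag(K) <- diag(K) + noiseDiag(s2, floors, noiseMode) + 1e-10
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  r <- y - m
  v <- backsolve(ch, forwardsolve(t(ch), r))
  as.numeric(0.5 * sum(r * v) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

#' Fit the GP by maximum marginal likelihood with restarts
#'
#' The constant mean is fixed to `mean(y)` before fitting. The three
#' log-hyperparameters are optimized by L-BFGS-B within their box bounds
#' from `nRestarts` log-uniform initializations; the best restart wins.
#' A 1e-10 jitter stabilizes the Cholesky factorization.
#'
#' @param X matrix of scaled inputs, one row per observation (n >= 2).
#' @param y numeric targets.
#' @param floors per-observation noise-variance floors (recycled;
#'   only active in `"per-obs"` mode).
#' @param bounds 3 x 2 hyperparameter bounds, see [defaultHyperBounds()].
#' @param nRestarts number of multi-start initializations (default 30).
#' @param seed RNG seed for the restart draws.
#' @param noiseMode `"global"` (noise = fitted sigma2 everywhere) or
#'   `"per-obs"` (diagonal `max(sigma2, floor_i)`).
#' @param hyper optional named vector `c(alpha, rho, sigma2)`: skip the
#'   MLE and factorize at these fixed hyperparameters (used for fantasy
#'   updates within a batch).
#' @return a [GPFit-class].
#' @export
fitGP <- function(X, y, floors = 0, bounds = defaultHyperBounds(),
                  nRestarts = 30, seed = 1L,
                  noiseMode = c("global", "per-obs"), hyper = NULL) {
  noiseMode <- match.arg(noiseMode)
  X <- as.matrix(X)
  stopIfNot(all(is.finite(y)), "targets must be finite")
  stopIfNot(nrow(X) == length(y), "X rows must match y length")
  stopIfNot(nrow(X) >= 2, "need at least 2 observations")
  floors <- rep_len(floors, length(y))
  m <- mean(y)
  D <- pairwiseDist(X, X)
  if (is.null(hyper)) {
    lb <- log(bounds[, 1]); ub <- log(bounds[, 2])
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    starts <- matrix(runif(3 * nRestarts, rep(lb, nRestarts), rep(ub, nRestarts)),
                     ncol = 3, byrow = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    best <- NULL
    for (k in seq_len(nRestarts)) {
      fit <- tryCatch(
        optim(starts[k, ], negLogLik, method = "L-BFGS-B",
              lower = lb, upper = ub, control = list(maxit = 200),
              D = D, y = y, m = m, floors = floors, noiseMode = noiseMode),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("all MLE restarts failed", call. = FALSE)
    hyper <- exp(best$par)
  } else {
    if (!is.null(names(hyper)) && all(c("alpha", "rho", "sigma2") %in% names(hyper)))
      hyper <- hyper[c("alpha", "rho", "sigma2")]
    hyper <- unname(hyper)
  }
  a <- hyper[1]; rho <- hyper[2]; s2 <- hyper[3]
  K <- matern52Mat(D, a, rho)
  diag(K) <- diag(K) + noiseDiag(s2, floors, noiseMode) + 1e-10
  L <- chol(K)
  av <- backsolve(L, forwardsolve(t(L), y - m))
  ll <- -(0.5 * sum((y - m) * av) + sum(log(diag(L))) +
            0.5 * length(y) * log(2 * pi))
  new("GPFit", alpha = a, rho = rho, sigma2 = s2, bounds = bounds,
      mean = m, X = X, y = as.numeric(y), floors = floors,
      noiseMode = noiseMode, L = L, alphaVec = as.numeric(av), logLik = ll)
}

#' Predictive distribution of a fitted GP
#'
#' Standard GP predictive equations at query points `newdata`:
#' mean `m + K(x*, X) (K + D)^{-1} (y - m)` and variance
#' `k(x*, x*) - K(x*, X) (K + D)^{-1} K(X, x*)`, clipped at 0 against
#' round-off; `sd` is its square root. The white-noise variance is not
#' added at the query (noise-free latent prediction).
#'
#' @param object a [GPFit-class].
#' @param newdata scaled vector, or matrix with one query point per row.
#' @param ... ignored.
#' @return data.frame with columns `mean` and `sd`, one row per query.
#' @export
setMethod("predict", "GPFit", function(object, newdata, ...) {
  Xs <- rbind(newdata)
  stopIfNot(ncol(Xs) == ncol(object@X), "dimension mismatch")
  Ks <- matern52Mat(pairwiseDist(Xs, object@X), object@alpha, object@rho)
  mu <- object@mean + as.numeric(Ks %*% object@alphaVec)
  V <- backsolve(object@L, t(Ks), transpose = TRUE)   # solves t(L) %*% Z = t(Ks)
  var <- pmax(object@alpha - colSums(V^2), 0)
  data.frame(mean = mu, sd = sqrt(var))
})

#' Add observations at fixed hyperparameters
#'
#' Refactorizes the kernel matrix with extra rows without re-optimizing
#' hyperparameters; the constant mean is recomputed over the augmented
#' targets. Used for fantasy observations within a batch, where the
#' hyperparameters stay frozen until real data arrive.
#'
#' @param fit a [GPFit-class].
#' @param xNew scaled vector or matrix of rows.
#' @param yNew target(s).
#' @param floorNew noise floor(s) for the new rows.
#' @return a new [GPFit-class]; `fit` itself is untouched.
#' @export
updateGP <- function(fit, xNew, yNew, floorNew) {
  Xa <- rbind(fit@X, rbind(xNew))
  fitGP(Xa, c(fit@y, yNew), c(fit@floors, rep_len(floorNew, length(yNew))),
        bounds = fit@bounds, noiseMode = fit@noiseMode,
        hyper = c(alpha = fit@alpha, rho = fit@rho, sigma2 = fit@sigma2))
}

#' Log marginal likelihood of a GP fit
#' @param object a [GPFit-class].
#' @param ... ignored.
#' @return numeric.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "GPFit", function(object, ...) object@logLik)
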