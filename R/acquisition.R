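## UCB acquisition, exploitation/exploration distance constraints,
## constrained maximization, automatic kappa selection and batch
## suggestion via predictive-mean fantasies.

#' Upper confidence bound acquisition
#'
#' `a(x) = mean(x) + kappa * sd(x)` under the current GP fit. Small kappa
#' prefers high predicted scores (exploitation); large kappa prefers high
#' predictive uncertainty (exploration).
#'
#' @param fit a [GPFit-class].
#' @param x scaled vector or matrix of query rows.
#' @param kappa exploration weight, >= 0.
#' @return UCB value(s).
#' @export
ucb <- function(fit, x, kappa) {
  stopIfNot(kappa >= 0, "kappa must be nonnegative")
  pr <- predict(fit, x)
  pr$mean + kappa * pr$sd
}

#' Normalized exploitation metric
#'
#' For a candidate x and the set of already-tested conditions, computes
#' `min over points i of max over dims d of |x_d - x_{i,d}| / eps_d`
#' with per-dimension thresholds `eps` in scaled units. The exploitation
#' constraint — at least one parameter differs from every tested condition
#' by at least its eps — holds iff the metric is >= 1. An empty observed
#' set yields `Inf` (vacuously feasible).
#'
#' @param x scaled candidate vector.
#' @param observed matrix of scaled tested conditions, one per row.
#' @param eps per-dimension exploitation thresholds, scaled units.
#' @return the metric (nonnegative, possibly `Inf`).
#' @export
exploitMetric <- function(x, observed, eps) {
  if (is.null(observed) || NROW(observed) == 0) return(Inf)
  A <- abs(sweep(rbind(observed), 2, x)) / rep(eps, each = NROW(rbind(observed)))
  min(apply(A, 1, max))
}

#' Normalized exploration metric
#'
#' `min over subset points i of sum over dims d of |x_d - x_{i,d}| / eps_d`:
#' the exploration constraint — stay within a total (weighted L1) distance
#' eps of the nearest trusted tested condition — holds iff the metric
#' is <= 1. The subset typically excludes corner-initialization
#' pseudo-points so exploration concentrates around conditions known to
#' germinate.
#'
#' @param x scaled candidate vector.
#' @param subset matrix of scaled trusted conditions, one per row.
#' @param eps per-dimension exploration thresholds, scaled units.
#' @return the metric (nonnegative).
#' @export
exploreMetric <- function(x, subset, eps) {
  if (is.null(subset) || NROW(subset) == 0)
    stop("empty exploration subset: widen the subset rule", call. = FALSE)
  A <- abs(sweep(rbind(subset), 2, x)) / rep(eps, each = NROW(rbind(subset)))
  min(rowSums(A))
}

## Vectorized metrics over candidate rows (screening): accumulate the
## min over reference points with pmin/pmax, O(n_ref * n_cand * d).
exploitMetricRows <- function(Xc, observed, eps) {
  if (is.null(observed) || NROW(observed) == 0) return(rep(Inf, nrow(Xc)))
  O <- rbind(observed)
  E <- rep(eps, each = nrow(Xc))
  acc <- NULL
  for (i in seq_len(nrow(O))) {
    A <- abs(Xc - rep(O[i, ], each = nrow(Xc))) / E
    m <- A[, 1]
    for (d in seq_len(ncol(A))[-1]) m <- pmax(m, A[, d])
    acc <- if (is.null(acc)) m else pmin(acc, m)
  }
  acc
}
exploreMetricRows <- function(Xc, subset, eps) {
  S <- rbind(subset)
  E <- rep(eps, each = nrow(Xc))
  acc <- NULL
  for (i in seq_len(nrow(S))) {
    m <- rowSums(abs(Xc - rep(S[i, ], each = nrow(Xc))) / E)
    acc <- if (is.null(acc)) m else pmin(acc, m)
  }
  acc
}

## Lean single-point evaluators for the inner optimization loop: work on
## transposed (d x n) matrices so a length-d candidate recycles down
## columns without sweep/rbind allocations.
makeLeanUCB <- function(fit, kappa) {
  tX <- t(fit@X); av <- fit@alphaVec; L <- fit@L
  m <- fit@mean; alpha <- fit@alpha; rho <- fit@rho
  s5 <- sqrt(5)
  function(x) {
    dif <- tX - x
    r <- sqrt(.colSums(dif * dif, nrow(tX), ncol(tX))) / rho
    ks <- alpha * (1 + s5 * r + 5 * r * r / 3) * exp(-s5 * r)
    mu <- m + sum(ks * av)
    if (kappa == 0) return(mu)
    v <- backsolve(L, ks, transpose = TRUE)
    mu + kappa * sqrt(max(alpha - sum(v * v), 0))
  }
}
makeLeanExploit <- function(observed, eps) {
  if (is.null(observed) || NROW(observed) == 0) return(function(x) Inf)
  tO <- t(rbind(observed))
  function(x) {
    A <- abs(tO - x) / eps
    m <- A[1, ]
    for (r in seq_len(nrow(A))[-1]) m <- pmax.int(m, A[r, ])
    min(m)
  }
}
makeLeanExplore <- function(subset, eps) {
  if (is.null(subset) || NROW(subset) == 0) return(function(x) 0)
  tS <- t(rbind(subset))
  function(x) min(.colSums(abs(tS - x) / eps, nrow(tS), ncol(tS)))
}

## Deterministic feasibility repair. Exploit violations are fixed by
## pushing the blocking coordinate just past eps away from the nearest
## tested point; explore violations by contracting toward the nearest
## subset point. A few alternating passes suffice in practice; failure
## leaves the point for the infeasible branch.
repairFeasibility <- function(x, observed, subset, epsXt, epsXr, lower, upper,
                              maxPass = 25) {
  for (pass in seq_len(maxPass)) {
    em <- exploitMetric(x, observed, epsXt)
    if (em < 1) {
      O <- rbind(observed)
      A <- abs(sweep(O, 2, x)) / rep(epsXt, each = nrow(O))
      i <- which.min(apply(A, 1, max))
      moved <- FALSE
      for (d in order(A[i, ], decreasing = TRUE)) {
        target <- O[i, d] + sign(x[d] - O[i, d] + 1e-12) * epsXt[d] * (1 + 1e-7)
        if (target >= lower[d] && target <= upper[d]) {
          x[d] <- target; moved <- TRUE; break
        }
        target <- O[i, d] - sign(x[d] - O[i, d] + 1e-12) * epsXt[d] * (1 + 1e-7)
        if (target >= lower[d] && target <= upper[d]) {
          x[d] <- target; moved <- TRUE; break
        }
      }
      if (!moved) return(x)
      next
    }
    if (!is.null(subset) && NROW(subset) > 0) {
      xm <- exploreMetric(x, subset, epsXr)
      if (xm > 1) {
        S <- rbind(subset)
        A <- abs(sweep(S, 2, x)) / rep(epsXr, each = nrow(S))
        i <- which.min(rowSums(A))
        x <- S[i, ] + (x - S[i, ]) * (1 - 1e-7) / xm
        next
      }
    }
    return(x)
  }
  x
}

## One penalized local search from a start point: gradient-based L-BFGS-B
## on -UCB plus quadratic hinge penalties for the two distance
## constraints, within the scaled box.
penalizedSearch <- function(start, leanUCB, leanXt, leanXr,
                            lower, upper, constrained) {
  obj <- function(x, w) {
    val <- -leanUCB(x)
    if (constrained) {
      g1 <- 1 - leanXt(x)
      if (g1 > 0) val <- val + w * g1 * g1
      g2 <- leanXr(x) - 1
      if (g2 > 0) val <- val + w * g2 * g2
    }
    val
  }
  x <- start
  for (w in if (constrained) c(1e2, 1e4) else 1) {
    r <- tryCatch(
      optim(x, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 80), w = w),
      error = function(e) NULL)
    if (!is.null(r)) x <- r$par
  }
  x
}

#' Maximize the UCB acquisition over the parameter box
#'
#' Multi-start constrained maximization in scaled coordinates: a
#' vectorized random screening pass picks promising starts (plus the
#' incumbent best observation), each start is refined by a penalized
#' gradient-based local search (L-BFGS-B with quadratic constraint
#' penalties), candidates are repaired onto the feasible set, and the
#' best feasible local maximum wins. The winner is converted to physical
#' units, rounded to device precision, and its feasibility re-checked
#' after rounding. If no candidate is feasible the best infeasible point
#' is returned with `feasible = FALSE` and its slacks reported.
#'
#' @param fit a [GPFit-class] trained on scaled inputs.
#' @param space the [ParameterSpace-class].
#' @param kappa exploration weight.
#' @param observed matrix of scaled tested conditions for the exploitation
#'   constraint (default: the fit's training inputs).
#' @param subset matrix of scaled trusted conditions for the exploration
#'   constraint; `NULL` disables that constraint.
#' @param constrained apply the distance constraints?
#' @param nMultistarts number of local searches.
#' @param nScreen size of the random screening sample.
#' @param seed RNG seed for screening/start draws.
#' @return a [Suggestion-class].
#' @export
maximizeUCB <- function(fit, space, kappa, observed = fit@X, subset = NULL,
                        constrained = TRUE, nMultistarts = 8,
                        nScreen = 512, seed = 1L) {
  p <- space@params
  d <- nrow(p)
  lower <- rep(0, d); upper <- p$scaled_high
  epsXt <- scaledEps(space, "exploit")
  epsXr <- scaledEps(space, "explore")
  useExplore <- constrained && !is.null(subset) && NROW(subset) > 0

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  Xc <- matrix(runif(nScreen * d, rep(lower, nScreen), rep(upper, nScreen)),
               ncol = d, byrow = TRUE)
  if (useExplore) {
    ## bias half the screen toward the trusted subset, where the explore
    ## constraint is satisfiable
    S <- rbind(subset)
    idx <- sample(nrow(S), nScreen %/% 2, replace = TRUE)
    jit <- matrix(runif((nScreen %/% 2) * d, -1, 1), ncol = d) *
      rep(epsXr / d, each = nScreen %/% 2)
    near <- pmin(pmax(S[idx, , drop = FALSE] + jit,
                      rep(lower, each = nScreen %/% 2)),
                 rep(upper, each = nScreen %/% 2))
    Xc[seq_len(nScreen %/% 2), ] <- near
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  acq <- ucb(fit, Xc, kappa)
  pen <- rep(0, nScreen)
  if (constrained) {
    g1 <- 1 - exploitMetricRows(Xc, observed, epsXt)
    pen <- pen + 10 * pmax(g1, 0)^2
    if (useExplore) {
      g2 <- exploreMetricRows(Xc, subset, epsXr) - 1
      pen <- pen + 10 * pmax(g2, 0)^2
    }
  }
  ord <- order(acq - pen, decreasing = TRUE)
  starts <- Xc[ord[seq_len(min(nMultistarts, nScreen))], , drop = FALSE]
  if (nrow(fit@X) > 0) {
    inc <- fit@X[which.max(fit@y), ]
    starts <- rbind(starts, pmin(pmax(inc, lower), upper))
  }

  leanUCB <- makeLeanUCB(fit, kappa)
  leanXt <- makeLeanExploit(observed, epsXt)
  leanXr <- if (useExplore) makeLeanExplore(subset, epsXr) else function(x) 0
  cand <- list()
  for (k in seq_len(nrow(starts))) {
    x <- penalizedSearch(starts[k, ], leanUCB, leanXt, leanXr,
                         lower, upper, constrained)
    if (constrained)
      x <- repairFeasibility(x, observed, if (useExplore) subset else NULL,
                             epsXt, epsXr, lower, upper)
    cand[[k]] <- pmin(pmax(x, lower), upper)
  }
  Xcand <- unique(do.call(rbind, cand))

  finalize <- function(xs) {
    xPhys <- fromScaled(space, xs, round = TRUE)
    xr <- toScaled(space, xPhys)
    em <- exploitMetric(xr, observed, epsXt)
    xm <- if (useExplore) exploreMetric(xr, subset, epsXr) else 0
    ## rounding may push the point back onto a tested condition; repair in
    ## the rounded grid by at most a few precision steps
    tries <- 0
    while (constrained && (em < 1 - 1e-6 || (useExplore && xm > 1 + 1e-6)) &&
           tries < 5) {
      xr <- repairFeasibility(xr, if (constrained) observed else NULL,
                              if (useExplore) subset else NULL,
                              epsXt, epsXr, rep(0, d), p$scaled_high)
      xPhys <- fromScaled(space, xr, round = TRUE)
      xr <- toScaled(space, xPhys)
      em <- exploitMetric(xr, observed, epsXt)
      xm <- if (useExplore) exploreMetric(xr, subset, epsXr) else 0
      tries <- tries + 1
    }
    feas <- !constrained ||
      (em >= 1 - 1e-6 && (!useExplore || xm <= 1 + 1e-6))
    new("Suggestion", x = as.numeric(xPhys), xScaled = as.numeric(xr),
        acquisitionValue = ucb(fit, xr, kappa), kappaUsed = kappa,
        exploitSlack = em, exploreSlack = xm, feasible = feas)
  }

  sugg <- lapply(seq_len(nrow(Xcand)), function(i) finalize(Xcand[i, ]))
  feasIdx <- which(vapply(sugg, function(s) s@feasible, logical(1)))
  pickBest <- function(idx) {
    vals <- vapply(sugg[idx], function(s) s@acquisitionValue, numeric(1))
    best <- idx[vals >= max(vals) - 1e-12]
    if (length(best) > 1) {   # tie-break: lexicographically smallest scaled
      M <- do.call(rbind, lapply(sugg[best], function(s) s@xScaled))
      best <- best[do.call(order, as.data.frame(M))[1]]
    }
    sugg[[best]]
  }
  if (length(feasIdx) > 0) return(pickBest(feasIdx))
  viol <- vapply(sugg, function(s)
    max(1 - s@exploitSlack, 0) + max(s@exploreSlack - 1, 0), numeric(1))
  sugg[[which.min(viol)]]
}

#' Automatic selection of the exploration weight kappa
#'
#' Scans an ascending kappa grid; for each kappa the UCB is maximized
#' under both distance constraints, and the first kappa whose maximizer is
#' feasible is returned together with its suggestion. Small kappa is
#' preferred, so the procedure exploits as much as the exploitation
#' constraint allows. If no grid value yields a feasible point, the kappa
#' with the smallest total constraint violation is returned, flagged
#' infeasible.
#'
#' @inheritParams maximizeUCB
#' @param kappaGrid strictly ascending nonnegative kappa values
#'   (default 0 to 10 in steps of 0.25).
#' @return list with elements `kappa` and `suggestion`.
#' @export
selectKappa <- function(fit, space, kappaGrid = seq(0, 10, by = 0.25),
                        observed = fit@X, subset = NULL,
                        nMultistarts = 8, nScreen = 512, seed = 1L) {
  stopIfNot(length(kappaGrid) > 0, "kappa grid must be nonempty")
  stopIfNot(all(diff(kappaGrid) > 0) && all(kappaGrid >= 0),
            "kappa grid must be nonnegative and strictly ascending")
  bestViol <- Inf; bestOut <- NULL
  for (i in seq_along(kappaGrid)) {
    k <- kappaGrid[i]
    s <- maximizeUCB(fit, space, k, observed = observed, subset = subset,
                     constrained = TRUE, nMultistarts = nMultistarts,
                     nScreen = nScreen, seed = childSeed(seed, i))
    if (s@feasible) return(list(kappa = k, suggestion = s))
    v <- max(1 - s@exploitSlack, 0) + max(s@exploreSlack - 1, 0)
    if (v < bestViol) { bestViol <- v; bestOut <- list(kappa = k, suggestion = s) }
  }
  bestOut
}

#' Suggest a batch of concurrent experimental conditions
#'
#' Sequential fantasy strategy for choosing B conditions to run at once:
#' repeatedly maximize the (constrained, optionally kappa-automatic)
#' acquisition, then "observe" the chosen point at its current GP
#' predictive mean — a fantasy observation — and refactorize the posterior
#' at frozen hyperparameters so the next pick avoids the same region.
#' Fantasies receive the global noise floor `1/N` as noise variance. All
#' fantasy state is discarded on return: the input fit is never modified,
#' and fantasy points must never enter the real trial ledger.
#'
#' @inheritParams maximizeUCB
#' @param B batch size (>= 1).
#' @param kappa fixed exploration weight, or `"auto"` for per-pick
#'   selection via [selectKappa()].
#' @param kappaGrid grid for `"auto"` mode.
#' @param N seeds per run (sets the fantasy noise floor `1/N`).
#' @return list of B [Suggestion-class] objects.
#' @export
suggestBatch <- function(fit, space, B, kappa = "auto",
                         kappaGrid = seq(0, 10, by = 0.25),
                         observed = fit@X, subset = NULL, N = 100,
                         nMultistarts = 8, nScreen = 512, seed = 1L) {
  stopIfNot(B >= 1, "batch size must be >= 1")
  curFit <- fit
  obs <- rbind(observed)
  sub <- if (!is.null(subset)) rbind(subset) else NULL
  out <- vector("list", B)
  for (b in seq_len(B)) {
    if (identical(kappa, "auto")) {
      sel <- selectKappa(curFit, space, kappaGrid, observed = obs,
                         subset = sub, nMultistarts = nMultistarts,
                         nScreen = nScreen, seed = childSeed(seed, b))
      s <- sel$suggestion
    } else {
      s <- maximizeUCB(curFit, space, kappa, observed = obs, subset = sub,
                       constrained = TRUE, nMultistarts = nMultistarts,
                       nScreen = nScreen, seed = childSeed(seed, b))
    }
    out[[b]] <- s
    if (b < B) {
      fantasyY <- predict(curFit, s@xScaled)$mean
      curFit <- updateGP(curFit, s@xScaled, fantasyY, varianceFloorGlobal(N))
      obs <- rbind(obs, s@xScaled)
      if (!is.null(sub)) sub <- rbind(sub, s@xScaled)
    }
  }
  out
}
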