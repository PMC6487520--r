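## Synthetic germination ground truth and the closed-loop driver.
##
## The built-in response surfaces are declared fixtures: smooth logistic/
## Gaussian compositions with constants fixed in code, shaped so that
## mid-20s temperature schedules and moderate cumulative water do well and
## box-corner extremes germinate nothing. They exercise the optimizer; they
## make no claim to reproduce pea or radish biology.

#' Built-in simulator ground-truth surfaces
#'
#' * `"pea7d"`: 7-dim (4 temperatures scaled to \[0,1\] + 3 water amounts
#'   scaled to \[0,0.5\]). Germination probability p peaks when each daily
#'   temperature is near its preferred mid-20s degC value (scaled centers
#'   0.645, 0.590, 0.740, 0.630; Gaussian width 0.25) and total scaled
#'   water is near 0.74 (i.e. 370 ml cumulative; width 0.40), with
#'   amplitude 0.85. q is the same shape with amplitude 0.60. Maximum mean
#'   score 0.85 * 1.6 = 1.36.
#' * `"radish4d"`: 4-dim temperature-only. p = 0.98 and q = 0.94 Gaussian
#'   bumps centered at scaled (0.575, 0.6925, 0.5575, 0.640) with widths
#'   0.5 and 0.6; optimum mean score 0.98 * 1.94 = 1.9012.
#' * `"unimodal_1d"`: single coordinate; p = 0.9 exp(-(s-0.6)^2 / (2 0.15^2)),
#'   q = 0.7 exp(-(s-0.6)^2 / (2 0.2^2)). Optimum at s = 0.6 with mean
#'   score 0.9 * 1.7 = 1.53; used for closed-form oracle tests.
#'
#' @param name one of `"pea7d"`, `"radish4d"`, `"unimodal_1d"`.
#' @return a [GroundTruth-class] over scaled coordinates.
#' @export
builtinSurface <- function(name) {
  rows <- function(s) rbind(s)
  gauss <- function(u, c, w) exp(-((u - c) / w)^2)
  switch(name,
    pea7d = {
      ct <- c(0.645, 0.590, 0.740, 0.630)
      shape <- function(s) {
        S <- rows(s)
        gT <- rowMeans(gauss(S[, 1:4, drop = FALSE],
                             rep(ct, each = nrow(S)), 0.25))
        gW <- gauss(rowSums(S[, 5:7, drop = FALSE]), 0.74, 0.40)
        gT * gW
      }
      new("GroundTruth",
          p = function(s) 0.85 * shape(s),
          q = function(s) 0.60 * shape(s),
          description = "pea7d: 4 temperatures + 3 water amounts, mid-20s schedule with moderate cumulative water optimal",
          optimumHint = c(ct, 0.346, 0.078, 0.316))
    },
    radish4d = {
      ct <- c(0.575, 0.6925, 0.5575, 0.640)
      dev2 <- function(s, w) {
        S <- rows(s)
        rowSums(((S - rep(ct, each = nrow(S))) / w)^2)
      }
      new("GroundTruth",
          p = function(s) 0.98 * exp(-dev2(s, 0.5)),
          q = function(s) 0.94 * exp(-dev2(s, 0.6)),
          description = "radish4d: 4 temperatures, broad optimum near a mixed mid-20s schedule, mean score ~1.9",
          optimumHint = ct)
    },
    unimodal_1d = new("GroundTruth",
        p = function(s) 0.9 * exp(-(rows(s)[, 1] - 0.6)^2 / (2 * 0.15^2)),
        q = function(s) 0.7 * exp(-(rows(s)[, 1] - 0.6)^2 / (2 * 0.2^2)),
        description = "unimodal_1d: single Gaussian bump, optimum at s = 0.6, mean score 1.53",
        optimumHint = 0.6),
    stop("unknown surface '", name,
         "'; available: pea7d, radish4d, unimodal_1d", call. = FALSE))
}

#' True mean score of a ground truth at scaled points
#'
#' `p(s) * (1 + q(s))`, the quantity the optimizer is chasing.
#'
#' @param gt a [GroundTruth-class].
#' @param s scaled vector or matrix of rows.
#' @return numeric mean score(s).
#' @export
trueScore <- function(gt, s) {
  p <- gt@p(s); q <- gt@q(s)
  p * (1 + q)
}

#' Simulate one germination run
#'
#' Two-stage Bernoulli sampling at physical condition `x`: germinated
#' `G ~ Binomial(N, p(s))`, then well-germinated `W ~ Binomial(G, q(s))`.
#' Reproducible: the same seed and condition give identical counts.
#'
#' @param gt a [GroundTruth-class].
#' @param space the [ParameterSpace-class] used for scaling.
#' @param x physical-unit condition vector.
#' @param N seeds placed.
#' @param seed RNG seed for this run.
#' @return list with elements `count` ([GerminationCount-class]), `x`, and
#'   `seed`.
#' @export
simulateTrial <- function(gt, space, x, N, seed) {
  s <- toScaled(space, x)
  p <- as.numeric(gt@p(s)); q <- as.numeric(gt@q(s))
  stopIfNot(p >= 0 && p <= 1 && q >= 0 && q <= 1,
            "surface probabilities left [0, 1]")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  G <- rbinom(1, N, p)
  W <- rbinom(1, G, q)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(count = germinationCount(N, G, W), x = x, seed = seed)
}

#' Run the full closed optimization loop against a simulator
#'
#' Emulates the laboratory protocol end to end: corner initialization
#' (extreme temperatures, zero water, score 0), an expert starting
#' condition measured by simulation, then `nTrials` rounds of fit ->
#' constrained batch suggestion -> simulated germination (optionally with
#' repeated runs per condition) -> ledger ingestion. Hyperparameters are
#' re-optimized once per round, when the round's real results arrive.
#'
#' @param gt a [GroundTruth-class] matching the space's dimension.
#' @param space the [ParameterSpace-class].
#' @param expert physical-unit expert starting condition.
#' @param nTrials number of suggestion rounds.
#' @param batchSize conditions suggested per round (concurrent chambers).
#' @param repetitions simulated runs per suggested condition.
#' @param N seeds per run.
#' @param seed session RNG seed; all child streams derive from it.
#' @param binaryDims,fixedZeroDims corner-initialization split, passed to
#'   [cornerInitPoints()].
#' @param kappa fixed kappa or `"auto"`. The default 2 emulates an
#'   operator holding a moderate exploration weight: with the very small
#'   exploitation threshold (0.1 degC / 1 ml), the ascending first-feasible
#'   kappa rule almost always accepts kappa = 0 and the loop degenerates to
#'   pure local exploitation — the behavior a human operator steers away
#'   from when picking kappa by hand.
#' @param kappaGrid grid for `"auto"` mode.
#' @param noiseMode `"global"` or `"per-obs"` noise floors.
#' @param nRestarts MLE restarts per round.
#' @param nMultistarts,nScreen acquisition optimizer effort.
#' @return list with `ledger` (data.frame of all observations), `summary`
#'   (per-trial best/mean score and running best), `expertScore`, and
#'   `bestScore`.
#' @export
runClosedLoop <- function(gt, space, expert, nTrials = 11, batchSize = 3,
                          repetitions = 1, N = 100, seed = 1L,
                          binaryDims = grep("^t", parameterNames(space), value = TRUE),
                          fixedZeroDims = grep("^w", parameterNames(space), value = TRUE),
                          kappa = 2, kappaGrid = seq(0, 10, by = 0.25),
                          noiseMode = "global", nRestarts = 30,
                          nMultistarts = 6, nScreen = 384) {
  session <- newSession(space, N = N, batchSize = batchSize, kappa = kappa,
                        kappaGrid = kappaGrid, noiseMode = noiseMode,
                        nRestarts = nRestarts, nMultistarts = nMultistarts,
                        nScreen = nScreen, seed = seed)
  session <- addInitPoints(session, binaryDims = binaryDims,
                           fixedZeroDims = fixedZeroDims)
  expert <- roundToPrecision(space, expert)
  expTrial <- simulateTrial(gt, space, expert, N, childSeed(seed, 1))
  session <- ingestObservation(session, trialId = "expert", chamberId = "c1",
                               x = expert, count = expTrial$count,
                               provenance = "expert", timestamp = "")
  expertScore <- targetScore(expTrial$count)

  for (tr in seq_len(nTrials)) {
    session <- fitSession(session)
    sugg <- suggest(session, B = batchSize,
                    seed = childSeed(seed, 100 + tr))
    for (b in seq_along(sugg)) {
      xb <- sugg[[b]]@x
      for (rep in seq_len(repetitions)) {
        st <- simulateTrial(gt, space, xb, N,
                            childSeed(seed, 10000 + 100 * tr + 10 * b + rep))
        session <- ingestObservation(
          session, trialId = sprintf("trial%02d", tr),
          chamberId = sprintf("c%d_r%d", b, rep), x = xb, count = st$count,
          provenance = "bo", timestamp = "")
      }
    }
  }

  led <- session@ledger
  real <- led[led$provenance != "init", ]
  byTrial <- split(real$y, real$trial_id)
  ord <- unique(real$trial_id)
  summary <- data.frame(
    trial_id = ord,
    best = vapply(byTrial[ord], max, numeric(1)),
    mean = vapply(byTrial[ord], mean, numeric(1)),
    row.names = NULL)
  summary$runningBest <- cummax(summary$best)
  list(ledger = led, summary = summary, expertScore = expertScore,
       bestScore = max(real$y))
}
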