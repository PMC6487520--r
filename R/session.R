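## Session management: configuration, trial ledger, the observe/suggest/
## report cycle, and CSV/YAML persistence.

LEDGER_FIXED <- c("trial_id", "chamber_id", "provenance")
LEDGER_TAIL <- c("N", "N_g", "N_wg", "y", "noise_floor", "timestamp")

#' Start a new optimization session
#'
#' @param space the [ParameterSpace-class].
#' @param N seeds per germination run.
#' @param batchSize conditions suggested per round (concurrent chambers).
#' @param kappa fixed exploration weight or `"auto"`.
#' @param kappaGrid ascending grid for auto mode.
#' @param exploreSubsetRule which tested conditions anchor the exploration
#'   constraint: `"exclude_init"` (default; corner pseudo-points are not
#'   trusted anchors), `"all"`, or `"top_k"` with `k`.
#' @param k subset size for `"top_k"`.
#' @param noiseMode `"global"` (fitted sigma2, lower-bounded at 1/N) or
#'   `"per-obs"` (diagonal `max(sigma2, y(2-y)/N)`).
#' @param bounds kernel hyperparameter bounds; default couples the
#'   white-noise lower bound to `1/N`.
#' @param nRestarts MLE restarts per refit.
#' @param nMultistarts,nScreen acquisition optimizer effort.
#' @param seed session RNG seed.
#' @return a [GermSession-class] with an empty ledger.
#' @export
newSession <- function(space, N = 100, batchSize = 3, kappa = "auto",
                       kappaGrid = seq(0, 10, by = 0.25),
                       exploreSubsetRule = c("exclude_init", "all", "top_k"),
                       k = 5, noiseMode = c("global", "per-obs"),
                       bounds = defaultHyperBounds(N), nRestarts = 30,
                       nMultistarts = 8, nScreen = 512, seed = 1L) {
  exploreSubsetRule <- match.arg(exploreSubsetRule)
  noiseMode <- match.arg(noiseMode)
  cfg <- list(space = space, N = N, batchSize = batchSize, kappa = kappa,
              kappaGrid = kappaGrid, exploreSubsetRule = exploreSubsetRule,
              k = k, noiseMode = noiseMode, bounds = bounds,
              nRestarts = nRestarts, nMultistarts = nMultistarts,
              nScreen = nScreen, seed = seed)
  led <- emptyLedger(space)
  new("GermSession", config = cfg, ledger = led, fit = NULL)
}

emptyLedger <- function(space) {
  cols <- c(LEDGER_FIXED, parameterNames(space), LEDGER_TAIL)
  led <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  for (nm in c(parameterNames(space), "N", "N_g", "N_wg", "y", "noise_floor"))
    led[[nm]] <- numeric(0)
  led
}

#' Add corner-initialization pseudo-observations
#'
#' Appends the zero-score box-vertex points of [cornerInitPoints()] to the
#' session ledger with provenance `"init"` (counts are NA: no seeds were
#' actually placed).
#'
#' @param session a [GermSession-class].
#' @param binaryDims,fixedZeroDims passed to [cornerInitPoints()].
#' @return the updated session.
#' @export
addInitPoints <- function(session, binaryDims, fixedZeroDims) {
  space <- session@config$space
  pts <- cornerInitPoints(space, binaryDims, fixedZeroDims)
  for (i in seq_len(nrow(pts))) {
    row <- data.frame(trial_id = "init", chamber_id = sprintf("v%02d", i),
                      provenance = "init", stringsAsFactors = FALSE)
    for (nm in parameterNames(space)) row[[nm]] <- pts[[nm]][i]
    row$N <- NA_real_; row$N_g <- NA_real_; row$N_wg <- NA_real_
    row$y <- 0
    row$noise_floor <- noiseFloorFor(session, 0)
    row$timestamp <- ""
    session@ledger <- rbind(session@ledger, row)
  }
  session@fit <- NULL
  session
}

noiseFloorFor <- function(session, y) {
  if (session@config$noiseMode == "per-obs")
    varianceFloorPerObs(y, session@config$N)
  else varianceFloorGlobal(session@config$N)
}

#' Record a real germination outcome
#'
#' Validates the condition and counts, computes the target score and its
#' noise floor, and appends a ledger row. The current GP fit is marked
#' stale. Duplicate (trial, chamber) pairs are rejected.
#'
#' @param session a [GermSession-class].
#' @param trialId,chamberId identifiers of the run.
#' @param x physical-unit condition vector.
#' @param count a [GerminationCount-class].
#' @param provenance `"expert"` or `"bo"`.
#' @param timestamp ledger timestamp (defaults to the current time).
#' @return the updated session.
#' @export
ingestObservation <- function(session, trialId, chamberId, x, count,
                              provenance = c("bo", "expert"),
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  provenance <- match.arg(provenance)
  space <- session@config$space
  checkPhysical(space, x)
  validObject(count)
  stopIfNot(count@N == session@config$N,
            sprintf("count N = %d but session N = %d", count@N, session@config$N))
  led <- session@ledger
  if (any(led$trial_id == trialId & led$chamber_id == chamberId))
    stop(sprintf("duplicate observation for trial '%s' chamber '%s'",
                 trialId, chamberId), call. = FALSE)
  y <- targetScore(count)
  row <- data.frame(trial_id = trialId, chamber_id = chamberId,
                    provenance = provenance, stringsAsFactors = FALSE)
  for (d in seq_along(parameterNames(space))) row[[parameterNames(space)[d]]] <- x[d]
  row$N <- count@N; row$N_g <- count@Ng; row$N_wg <- count@Nwg
  row$y <- y
  row$noise_floor <- noiseFloorFor(session, y)
  row$timestamp <- timestamp
  session@ledger <- rbind(led, row)
  session@fit <- NULL
  session
}

ledgerMatrix <- function(session, rows = TRUE) {
  led <- session@ledger[rows, , drop = FALSE]
  as.matrix(led[, parameterNames(session@config$space), drop = FALSE])
}

#' Refit the GP on the current ledger
#'
#' Trains on every ledger row (real observations plus corner
#' pseudo-points) in scaled coordinates, re-optimizing hyperparameters by
#' multi-start MLE.
#'
#' @param session a [GermSession-class].
#' @return the session with a fresh fit.
#' @export
fitSession <- function(session) {
  led <- session@ledger
  stopIfNot(nrow(led) >= 2, "need at least 2 ledger rows to fit")
  Xs <- toScaled(session@config$space, ledgerMatrix(session))
  session@fit <- fitGP(Xs, led$y, floors = led$noise_floor,
                       bounds = session@config$bounds,
                       nRestarts = session@config$nRestarts,
                       seed = childSeed(session@config$seed, nrow(led)),
                       noiseMode = session@config$noiseMode)
  session
}

exploreSubset <- function(session) {
  led <- session@ledger
  keep <- switch(session@config$exploreSubsetRule,
    all = rep(TRUE, nrow(led)),
    exclude_init = led$provenance != "init",
    top_k = {
      real <- which(led$provenance != "init")
      real[order(led$y[real], decreasing = TRUE)][
        seq_len(min(session@config$k, length(real)))]
    })
  Xs <- ledgerMatrix(session, keep)
  if (nrow(Xs) == 0) return(NULL)
  toScaled(session@config$space, Xs)
}

#' Suggest the next batch of conditions for a session
#'
#' Wraps [suggestBatch()] with the session's configuration: the
#' exploitation constraint sees every ledger row, the exploration
#' constraint the configured trusted subset.
#'
#' @param session a [GermSession-class] with a current fit (see
#'   [fitSession()]).
#' @param B batch size (default the session's).
#' @param seed RNG seed for this suggestion round (default derived from
#'   the session seed and ledger length).
#' @return list of [Suggestion-class] objects.
#' @export
suggest <- function(session, B = session@config$batchSize,
                    seed = childSeed(session@config$seed,
                                     50000 + nrow(session@ledger))) {
  stopIfNot(!is.null(session@fit), "no current fit: call fitSession() first")
  cfg <- session@config
  observed <- toScaled(cfg$space, ledgerMatrix(session))
  suggestBatch(session@fit, cfg$space, B = B, kappa = cfg$kappa,
               kappaGrid = cfg$kappaGrid, observed = observed,
               subset = exploreSubset(session), N = cfg$N,
               nMultistarts = cfg$nMultistarts, nScreen = cfg$nScreen,
               seed = seed)
}

#' Summarize a session ledger
#'
#' Per-trial best and mean scores, the running best, and the headline
#' figures: efficiency (percent of the metric maximum 2, one decimal) of
#' the initial expert condition and of the best condition found, plus the
#' relative improvement percent, rounded to the nearest integer.
#'
#' @param session a [GermSession-class] with a nonempty ledger.
#' @return list with `perTrial`, `initScore`, `bestScore`,
#'   `initEfficiency`, `bestEfficiency`, `improvementPercent`.
#' @export
sessionReport <- function(session) {
  led <- session@ledger
  stopIfNot(nrow(led) > 0, "ledger is empty")
  real <- led[led$provenance != "init", , drop = FALSE]
  if (nrow(real) == 0) {
    warning("no real observations yet: partial summary")
    return(list(perTrial = NULL, initScore = NA_real_, bestScore = NA_real_,
                initEfficiency = NA_real_, bestEfficiency = NA_real_,
                improvementPercent = NA_real_))
  }
  ord <- unique(real$trial_id)
  byTrial <- split(real$y, real$trial_id)[ord]
  perTrial <- data.frame(trial_id = ord,
                         best = vapply(byTrial, max, numeric(1)),
                         mean = vapply(byTrial, mean, numeric(1)),
                         row.names = NULL)
  perTrial$runningBest <- cummax(perTrial$best)
  initScore <- real$y[1]
  bestScore <- max(real$y)
  list(perTrial = perTrial,
       initScore = initScore,
       bestScore = bestScore,
       initEfficiency = efficiencyPercent(initScore, digits = 1),
       bestEfficiency = efficiencyPercent(bestScore, digits = 1),
       improvementPercent = roundHalfUp((bestScore - initScore) / initScore * 100))
}

#' Write / read the trial ledger as CSV
#'
#' The on-disk format has one row per germination run: identifiers,
#' provenance, physical parameter values, counts, score, noise floor,
#' timestamp. Reading validates count invariants and score consistency.
#'
#' @param ledger a ledger data.frame.
#' @param path CSV file path.
#' @return `writeLedger`: the path, invisibly. `readLedger`: the ledger
#'   data.frame.
#' @export
writeLedger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLedger
#' @param space the [ParameterSpace-class] the ledger must match.
#' @export
readLedger <- function(path, space) {
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(LEDGER_FIXED, parameterNames(space), LEDGER_TAIL)
  stopIfNot(all(need %in% names(led)),
            paste("ledger missing columns:",
                  paste(setdiff(need, names(led)), collapse = ", ")))
  led$timestamp <- as.character(led$timestamp)
  led$timestamp[is.na(led$timestamp)] <- ""
  real <- !is.na(led$N_g)
  stopIfNot(all(led$N_wg[real] <= led$N_g[real] & led$N_g[real] <= led$N[real]),
            "count invariants violated in ledger")
  stopIfNot(all(abs(led$y[real] -
                      (led$N_g[real] + led$N_wg[real]) / led$N[real]) < 1e-9),
            "ledger scores inconsistent with counts")
  led[, need]
}

#' Read an experiment configuration file
#'
#' YAML or JSON document with a `parameters:` list (name, unit, low, high,
#' scaled_high, eps_exploit, eps_explore, precision) and scalar fields
#' `seeds_per_trial`, `batch_size`, optional `kappa`, `kappa_grid`,
#' `explore_subset_rule`, `noise_mode`, `n_restarts`, `seed`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [GermSession-class] built from the configuration.
#' @export
sessionFromConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  pars <- cfg$parameters
  if (is.data.frame(pars)) pars <- split(pars, seq_len(nrow(pars)))
  defs <- lapply(pars, function(p)
    parameterDef(p$name, p$unit, p$low, p$high, p$scaled_high %||% 1,
                 p$eps_exploit, p$eps_explore, p$precision %||% 0.1))
  space <- do.call(parameterSpace, defs)
  newSession(space,
             N = cfg$seeds_per_trial %||% 100,
             batchSize = cfg$batch_size %||% 3,
             kappa = cfg$kappa %||% "auto",
             kappaGrid = cfg$kappa_grid %||% seq(0, 10, by = 0.25),
             exploreSubsetRule = cfg$explore_subset_rule %||% "exclude_init",
             noiseMode = cfg$noise_mode %||% "global",
             nRestarts = cfg$n_restarts %||% 30,
             seed = cfg$seed %||% 1L)
}

#' Plot per-trial target scores
#'
#' Scores of every run against trial index, with the per-trial maximum and
#' the running best overlaid — the standard progress view of a closed-loop
#' session.
#'
#' @param ledger a ledger data.frame (real rows are plotted).
#' @param main plot title.
#' @return invisibly, the per-trial summary data.frame.
#' @importFrom graphics axis legend lines points
#' @export
plotTrialScores <- function(ledger, main = "Germination score by trial") {
  real <- ledger[ledger$provenance != "init", , drop = FALSE]
  stopIfNot(nrow(real) > 0, "no real observations to plot")
  ord <- unique(real$trial_id)
  idx <- match(real$trial_id, ord)
  byTrial <- split(real$y, real$trial_id)[ord]
  best <- vapply(byTrial, max, numeric(1))
  plot(idx, real$y, pch = 16, col = "steelblue",
       xlab = "trial", ylab = "target score y", ylim = c(0, 2),
       main = main, xaxt = "n")
  axis(1, at = seq_along(ord), labels = ord, las = 2, cex.axis = 0.7)
  lines(seq_along(ord), best, col = "darkgreen", lty = 3, lwd = 2)
  lines(seq_along(ord), cummax(best), col = "black", lty = 2)
  legend("bottomright", c("runs", "trial best", "running best"),
         col = c("steelblue", "darkgreen", "black"),
         pch = c(16, NA, NA), lty = c(NA, 3, 2), bty = "n", cex = 0.8)
  invisible(data.frame(trial_id = ord, best = best,
                       runningBest = cummax(best)))
}
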