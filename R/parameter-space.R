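## Parameter-space definition, physical <-> scaled transforms and corner
## initialization.

#' Define one controllable parameter
#'
#' @param name parameter name (e.g. `"t1"`, `"w2"`).
#' @param unit physical unit, `"degC"` or `"ml"`.
#' @param low,high physical bounds.
#' @param scaledHigh upper end of the linear scaling target (the lower end
#'   is always 0): 1 for temperatures, 0.5 for water supply.
#' @param epsExploit minimum per-parameter distance of a new suggestion
#'   from every tested condition, physical units.
#' @param epsExplore maximum total distance of a new suggestion from the
#'   nearest trusted tested condition, physical units.
#' @param precision device rounding step, physical units.
#' @return one-row data.frame suitable for [parameterSpace()].
#' @export
parameterDef <- function(name, unit, low, high, scaledHigh = 1,
                         epsExploit, epsExplore, precision) {
  data.frame(name = name, unit = unit, low = low, high = high,
             scaled_high = scaledHigh, eps_exploit = epsExploit,
             eps_explore = epsExplore, precision = precision,
             stringsAsFactors = FALSE)
}

#' Build a ParameterSpace
#'
#' @param ... one-row data.frames from [parameterDef()], or a single
#'   data.frame holding all rows.
#' @return a validated [ParameterSpace-class].
#' @examples
#' sp <- parameterSpace(
#'   parameterDef("t1", "degC", 0, 40, 1,   0.1, 10, 0.1),
#'   parameterDef("w1", "ml",   0, 250, 0.5, 1, 100, 1))
#' toScaled(sp, c(40, 250))
#' @export
parameterSpace <- function(...) {
  parts <- list(...)
  df <- if (length(parts) == 1 && is.data.frame(parts[[1]]) &&
            nrow(parts[[1]]) > 1) parts[[1]] else do.call(rbind, parts)
  rownames(df) <- NULL
  new("ParameterSpace", params = df)
}

#' Number of dimensions of a space
#' @param space a [ParameterSpace-class].
#' @return integer.
#' @export
nParams <- function(space) nrow(space@params)

#' Parameter names, in positional order
#' @param space a [ParameterSpace-class].
#' @return character vector.
#' @export
parameterNames <- function(space) space@params$name

checkPhysical <- function(space, x) {
  p <- space@params
  x <- rbind(x)
  stopIfNot(ncol(x) == nrow(p),
            sprintf("expected %d coordinates, got %d", nrow(p), ncol(x)))
  for (d in seq_len(nrow(p))) {
    bad <- x[, d] < p$low[d] - 1e-9 | x[, d] > p$high[d] + 1e-9
    if (any(bad))
      stop(sprintf("parameter '%s' out of bounds [%g, %g]: %g",
                   p$name[d], p$low[d], p$high[d], x[which(bad)[1], d]),
           call. = FALSE)
  }
  invisible(x)
}

#' @describeIn toScaled linear map: coordinate d goes to
#'   `(x - low) / (high - low) * scaled_high`.
#' @export
setMethod("toScaled", "ParameterSpace", function(space, x) {
  vec <- is.null(dim(x))
  X <- checkPhysical(space, x)
  p <- space@params
  S <- sweep(sweep(X, 2, p$low), 2, (p$high - p$low) / p$scaled_high, "/")
  if (vec) drop(S) else S
})

#' @describeIn fromScaled exact inverse of `toScaled`, then rounded to each
#'   parameter's device precision (disable with `round = FALSE`).
#' @export
setMethod("fromScaled", "ParameterSpace", function(space, s, round = TRUE) {
  vec <- is.null(dim(s))
  S <- rbind(s)
  p <- space@params
  stopIfNot(ncol(S) == nrow(p),
            sprintf("expected %d coordinates, got %d", nrow(p), ncol(S)))
  for (d in seq_len(nrow(p))) {
    bad <- S[, d] < -1e-9 | S[, d] > p$scaled_high[d] + 1e-9
    if (any(bad))
      stop(sprintf("scaled coordinate for '%s' outside [0, %g]: %g",
                   p$name[d], p$scaled_high[d], S[which(bad)[1], d]),
           call. = FALSE)
  }
  X <- sweep(sweep(S, 2, (p$high - p$low) / p$scaled_high, "*"), 2, p$low, "+")
  if (round) X <- roundToPrecision(space, X)
  X[] <- pmin(pmax(X, rep(p$low, each = nrow(X))), rep(p$high, each = nrow(X)))
  if (vec) drop(X) else X
})

#' Round physical coordinates to device precision
#'
#' @param space a [ParameterSpace-class].
#' @param x physical vector or matrix of rows.
#' @return rounded coordinates, same shape.
#' @export
roundToPrecision <- function(space, x) {
  vec <- is.null(dim(x))
  X <- rbind(x)
  prec <- space@params$precision
  X <- sweep(round(sweep(X, 2, prec, "/")), 2, prec, "*")
  if (vec) drop(X) else X
}

## eps thresholds converted to scaled units, per dimension.
scaledEps <- function(space, which = c("exploit", "explore")) {
  which <- match.arg(which)
  p <- space@params
  eps <- if (which == "exploit") p$eps_exploit else p$eps_explore
  eps / (p$high - p$low) * p$scaled_high
}

#' Corner initialization points
#'
#' Zero-score pseudo-observations at the extreme box vertices, encoding
#' that extreme conditions germinate nothing: the full \{low, high\}
#' Cartesian product over `binaryDims` with `fixedZeroDims` pinned at their
#' lower bound. For the pea setup this is all combinations of 0/40 degC
#' over the four daily temperatures with 0 water, 2^4 = 16 points.
#'
#' @param space a [ParameterSpace-class].
#' @param binaryDims names (or indices) of parameters taking both bounds.
#' @param fixedZeroDims names (or indices) pinned at their lower bound;
#'   together with `binaryDims` this must partition the space.
#' @return data.frame with one physical coordinate column per parameter,
#'   plus `y = 0` and `provenance = "init"`.
#' @export
cornerInitPoints <- function(space, binaryDims = parameterNames(space),
                             fixedZeroDims = character(0)) {
  p <- space@params
  asIdx <- function(v) if (is.character(v)) match(v, p$name) else as.integer(v)
  bi <- asIdx(binaryDims); fi <- asIdx(fixedZeroDims)
  stopIfNot(!anyNA(c(bi, fi)), "unknown parameter name in dims")
  stopIfNot(length(intersect(bi, fi)) == 0 &&
              setequal(c(bi, fi), seq_len(nrow(p))),
            "binaryDims and fixedZeroDims must partition the space")
  if (length(bi) == 0) {
    warning("no binary dims: single all-low init point")
    X <- matrix(p$low, nrow = 1)
  } else {
    grids <- lapply(bi, function(d) c(p$low[d], p$high[d]))
    G <- as.matrix(expand.grid(grids))
    X <- matrix(rep(p$low, each = nrow(G)), nrow = nrow(G))
    X[, bi] <- G
  }
  colnames(X) <- p$name
  out <- as.data.frame(X)
  out$y <- 0
  out$provenance <- "init"
  out
}

#' The pea-experiment parameter space
#'
#' Seven controllable parameters: chamber temperatures at 0, 24, 48, 72 h
#' (`t1..t4`, 0-40 degC, scaled to \[0, 1\]) and water supplied at 0, 24,
#' 48 h (`w1..w3`, 0-250 ml, scaled to \[0, 0.5\], so a 1 degC step and a
#' 12.5 ml step are scale-equivalent). Exploitation thresholds 0.1 degC /
#' 1 ml, exploration thresholds 10 degC / 100 ml, device precision
#' 0.1 degC / 1 ml.
#'
#' @return a [ParameterSpace-class].
#' @export
peaParameterSpace <- function() {
  defs <- c(
    lapply(paste0("t", 1:4), function(nm)
      parameterDef(nm, "degC", 0, 40, 1, 0.1, 10, 0.1)),
    lapply(paste0("w", 1:3), function(nm)
      parameterDef(nm, "ml", 0, 250, 0.5, 1, 100, 1)))
  do.call(parameterSpace, defs)
}

#' The radish-experiment parameter space
#'
#' Four chamber temperatures at 0, 12, 24, 36 h (`t1..t4`, 0-40 degC,
#' scaled to \[0, 1\]); water is fixed by protocol and not a coordinate.
#'
#' @return a [ParameterSpace-class].
#' @export
radishParameterSpace <- function() {
  defs <- lapply(paste0("t", 1:4), function(nm)
    parameterDef(nm, "degC", 0, 40, 1, 0.1, 10, 0.1))
  do.call(parameterSpace, defs)
}
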