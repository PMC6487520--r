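# Shared fixtures: small spaces and a deterministic 1-d toy fit.

oneTempSpace <- function() {
  parameterSpace(parameterDef("t1", "degC", 0, 40, 1, 0.1, 10, 0.1))
}

twoParamSpace <- function() {
  parameterSpace(
    parameterDef("t1", "degC", 0, 40, 1, 0.1, 10, 0.1),
    parameterDef("w1", "ml", 0, 250, 0.5, 1, 100, 1))
}

# 1-d GP fit with a single interior bump, for acquisition tests.
toyBumpFit <- function(n = 15, seed = 4, noise = 0.05) {
  set.seed(seed)
  X <- matrix(seq(0, 1, length.out = n), ncol = 1)
  y <- exp(-((X[, 1] - 0.55) / 0.18)^2) + rnorm(n, 0, noise)
  fitGP(X, y, nRestarts = 10, seed = seed + 1,
        bounds = defaultHyperBounds(NULL))
}
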