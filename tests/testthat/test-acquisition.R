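# Brute-force loop oracles for the distance metrics, a dense-grid oracle
# for the 1-d maximizer, and an exhaustive-scan oracle for kappa.

bruteExploit <- function(x, obs, eps) {
  best <- Inf
  for (i in seq_len(nrow(obs))) {
    m <- max(abs(x - obs[i, ]) / eps)
    if (m < best) best <- m
  }
  best
}
bruteExplore <- function(x, sub, eps) {
  best <- Inf
  for (i in seq_len(nrow(sub))) {
    m <- sum(abs(x - sub[i, ]) / eps)
    if (m < best) best <- m
  }
  best
}

test_that("ucb is mean plus kappa times sd", {
  fit <- toyBumpFit()
  x <- matrix(0.31, 1, 1)
  pr <- predict(fit, x)
  expect_equal(ucb(fit, x, 0), pr$mean)               # exploitation limit
  expect_equal(ucb(fit, x, 2), pr$mean + 2 * pr$sd)
  ks <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(ks, function(k) ucb(fit, x, k), numeric(1))
  expect_true(all(diff(vals) >= 0))                   # nondecreasing in kappa
  expect_error(ucb(fit, x, -1), "nonnegative")
})

test_that("distance metrics match brute-force loops and their boundary cases", {
  eps2 <- c(0.0025, 0.002)
  obs <- rbind(c(0.5, 0.2), c(0.1, 0.4))
  # exact hit on an observed point
  expect_equal(exploitMetric(c(0.5, 0.2), obs, eps2), 0)
  expect_equal(exploreMetric(c(0.5, 0.2), obs, c(0.25, 0.2)), 0)
  # boundary-feasible: one coordinate exactly at eps, others equal
  expect_equal(exploitMetric(c(0.5 + 0.0025, 0.2), rbind(c(0.5, 0.2)), eps2), 1)
  expect_equal(exploreMetric(c(0.5 + 0.25, 0.2), rbind(c(0.5, 0.2)),
                             c(0.25, 0.2)), 1)
  expect_equal(exploitMetric(c(0.9, 0.9), NULL, eps2), Inf)
  expect_error(exploreMetric(c(0.9, 0.9), NULL, c(0.25, 0.2)), "subset")
  set.seed(12)
  for (i in 1:25) {
    x <- runif(2); obs <- matrix(runif(10), ncol = 2)
    expect_equal(exploitMetric(x, obs, eps2), bruteExploit(x, obs, eps2))
    expect_equal(exploreMetric(x, obs, c(0.25, 0.2)),
                 bruteExplore(x, obs, c(0.25, 0.2)))
  }
})

test_that("unconstrained 1-d maximizer matches a dense-grid argmax", {
  fit <- toyBumpFit()
  sp <- oneTempSpace()
  for (kappa in c(0, 1, 2.5)) {
    s <- maximizeUCB(fit, sp, kappa, constrained = FALSE, seed = 31)
    grid <- matrix(seq(0, 1, length.out = 10001), ncol = 1)
    gv <- ucb(fit, grid, kappa)
    expect_lt(abs(s@xScaled - grid[which.max(gv), 1]), 2e-3)
    expect_gte(s@acquisitionValue, max(gv) - 1e-4)
  }
})

test_that("constraints bind: suggestions keep their distance promises", {
  fit <- toyBumpFit()
  sp <- oneTempSpace()
  # place an observed point exactly at the unconstrained argmax
  free <- maximizeUCB(fit, sp, 1, constrained = FALSE, seed = 5)
  obs <- rbind(fit@X, free@xScaled)
  s <- maximizeUCB(fit, sp, 1, observed = obs, subset = matrix(0.5, 1, 1),
                   seed = 6)
  expect_true(s@feasible)
  expect_gte(s@exploitSlack, 1 - 1e-6)
  expect_lte(s@exploreSlack, 1 + 1e-6)
  expect_gte(exploitMetric(s@xScaled, obs, 0.1 / 40), 1 - 1e-6)
  # large kappa with a flat mean drives the choice into the data gap
  X <- matrix(c(0.05, 0.1, 0.15, 0.9, 0.95), ncol = 1)
  flat <- fitGP(X, rep(1, 5), hyper = c(alpha = 1, rho = 0.1, sigma2 = 0.01))
  sE <- maximizeUCB(flat, sp, kappa = 50, constrained = FALSE, seed = 7)
  expect_gt(sE@xScaled, 0.3); expect_lt(sE@xScaled, 0.8)
})

test_that("automatic kappa selection is first-feasible on the grid", {
  fit <- toyBumpFit()
  sp <- oneTempSpace()
  grid <- seq(0, 3, by = 0.5)
  subset <- matrix(0.5, 1, 1)

  # scenario A: the kappa = 0 argmax is free -> smallest grid value wins
  selA <- selectKappa(fit, sp, grid, observed = fit@X, subset = subset,
                      seed = 41)
  expect_equal(selA$kappa, 0)
  expect_true(selA$suggestion@feasible)

  # scenario B: blocking out the kappa = 0 argmax forces kappa upward
  block0 <- maximizeUCB(fit, sp, 0, constrained = FALSE, seed = 42)@xScaled
  obsB <- rbind(fit@X, matrix(seq(block0 - 0.004, block0 + 0.004,
                                  by = 0.0008), ncol = 1))
  selB <- selectKappa(fit, sp, grid, observed = obsB, subset = subset,
                      seed = 43)
  expect_true(selB$suggestion@feasible)

  # exhaustive oracle: selB's kappa is the smallest feasible grid value
  feas <- vapply(seq_along(grid), function(i) {
    s <- maximizeUCB(fit, sp, grid[i], observed = obsB, subset = subset,
                     seed = germBO:::childSeed(43, i))
    s@feasible
  }, logical(1))
  expect_equal(selB$kappa, grid[which(feas)[1]])
  expect_error(selectKappa(fit, sp, numeric(0)), "nonempty")
})

test_that("batch suggestions are distinct, fantasy-consistent, and retract", {
  fit <- toyBumpFit()
  sp <- oneTempSpace()
  snapshot <- fit
  subset <- matrix(0.55, 1, 1)

  b1 <- suggestBatch(fit, sp, B = 1, kappa = 1, subset = subset, seed = 3)
  s1 <- maximizeUCB(fit, sp, 1, observed = fit@X, subset = subset,
                    seed = germBO:::childSeed(3, 1))
  expect_equal(b1[[1]]@x, s1@x)          # B = 1 degenerates to a single call

  b3 <- suggestBatch(fit, sp, B = 3, kappa = 1, subset = subset, seed = 3)
  eps <- germBO:::scaledEps(sp, "exploit")
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(exploitMetric(b3[[i]]@xScaled,
                             rbind(b3[[j]]@xScaled), eps), 1 - 1e-6)

  # the fantasy target at step j equals the current predictive mean
  fitJ <- fit
  for (j in 1:2) {
    expected <- predict(fitJ, b3[[j]]@xScaled)$mean
    fitJ <- updateGP(fitJ, b3[[j]]@xScaled, expected,
                     varianceFloorGlobal(100))
    expect_equal(fitJ@y[length(fitJ@y)], expected, tolerance = 1e-12)
  }

  # the input fit is bit-identical after the batch: fantasies fully retracted
  expect_identical(fit, snapshot)
  expect_equal(nobs(fit), nobs(toyBumpFit()))
})
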