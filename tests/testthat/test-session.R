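test_that("observations are validated, scored and deduplicated on ingest", {
  sess <- newSession(peaParameterSpace(), N = 100)
  x <- c(24.7, 21.5, 24.2, 22.6, 200, 200, 200)
  sess <- ingestObservation(sess, "t01", "c1", x, germinationCount(100, 73, 0),
                            provenance = "expert")
  expect_equal(tail(sess@ledger$y, 1), 0.73)
  sess <- ingestObservation(sess, "t01", "c2", x, germinationCount(100, 80, 33))
  expect_equal(tail(sess@ledger$y, 1), 1.13)
  expect_error(
    ingestObservation(sess, "t01", "c1", x, germinationCount(100, 50, 0)),
    "duplicate")
  expect_equal(nrow(sess@ledger), 2)     # rejected ingest left it unchanged
  expect_error(
    ingestObservation(sess, "t02", "c1", c(45, 21, 24, 22, 200, 200, 200),
                      germinationCount(100, 10, 0)), "t1")
  # per-obs mode stores y(2-y)/N floors
  s2 <- newSession(peaParameterSpace(), N = 100, noiseMode = "per-obs")
  s2 <- ingestObservation(s2, "a", "c1", x, germinationCount(100, 73, 0))
  expect_equal(s2@ledger$noise_floor, 0.73 * 1.27 / 100)
})

test_that("the session report reproduces the headline pea figures", {
  sess <- newSession(peaParameterSpace(), N = 100)
  pea <- peaTrials()
  counts <- round(pea$target * 100)       # reconstruct Ng + Nwg of 100 seeds
  for (i in seq_len(nrow(pea))) {
    ng <- min(counts[i], 100)
    sess <- ingestObservation(
      sess, sprintf("trial%02d", (i - 1) %/% 3 + 1), sprintf("c%d", (i - 1) %% 3 + 1),
      as.numeric(pea[i, 1:7]), germinationCount(100, ng, counts[i] - ng),
      provenance = if (i == 1) "expert" else "bo")
  }
  rep <- sessionReport(sess)
  expect_equal(rep$initScore, 0.73)
  expect_equal(rep$bestScore, 1.13)
  expect_equal(rep$initEfficiency, 36.5)
  expect_equal(rep$bestEfficiency, 56.5)
  expect_equal(rep$improvementPercent, 55)     # (1.13 - 0.73) / 0.73
  expect_equal(nrow(rep$perTrial), 11)
  # best-so-far equals a brute-force running maximum over ledger order
  expect_equal(rep$perTrial$runningBest,
               Reduce(max, rep$perTrial$best, accumulate = TRUE))
})

test_that("single-row and empty-real ledgers degrade gracefully", {
  sp <- oneTempSpace()
  sess <- newSession(sp, N = 100)
  expect_error(sessionReport(sess), "empty")
  sess <- addInitPoints(sess, "t1", character(0))
  expect_warning(repp <- sessionReport(sess), "partial")
  expect_true(is.na(repp$bestScore))
  sess <- ingestObservation(sess, "t", "c", 22, germinationCount(100, 40, 10))
  rep1 <- sessionReport(sess)
  expect_equal(rep1$bestScore, 0.5)
  expect_equal(rep1$perTrial$mean, 0.5)
})

test_that("ledger CSV round-trips losslessly", {
  sp <- twoParamSpace()
  sess <- newSession(sp, N = 100, noiseMode = "per-obs")
  sess <- addInitPoints(sess, "t1", "w1")
  sess <- ingestObservation(sess, "t01", "c1", c(22.5, 120),
                            germinationCount(100, 70, 20), timestamp = "tstamp")
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeLedger(sess@ledger, p1)
  led <- readLedger(p1, sp)
  writeLedger(led, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(led$y, sess@ledger$y)
  # corrupted score column is rejected
  bad <- led; bad$y[nrow(bad)] <- 0.2
  p3 <- tempfile(fileext = ".csv"); writeLedger(bad, p3)
  expect_error(readLedger(p3, sp), "inconsistent")
})

test_that("sessions build from a YAML configuration document", {
  cfg <- system.file("extdata", "config_pea.yaml", package = "germBO")
  sess <- sessionFromConfig(cfg)
  expect_equal(nParams(sess@config$space), 7)
  expect_equal(sess@config$N, 100)
  expect_equal(sess@config$batchSize, 3)
  expect_identical(sess@config$kappa, "auto")
  expect_equal(parameterTable(sess@config$space)$scaled_high,
               c(1, 1, 1, 1, 0.5, 0.5, 0.5))
  expect_equal(sess@config$bounds["sigma2", "low"], 0.01)
})

test_that("fit/suggest on a session honors constraints and provenance", {
  sp <- oneTempSpace()
  gt <- builtinSurface("unimodal_1d")
  sess <- newSession(sp, N = 100, kappa = 2, nRestarts = 5,
                     nMultistarts = 3, nScreen = 128, seed = 2)
  sess <- addInitPoints(sess, "t1", character(0))
  sess <- ingestObservation(sess, "e", "c1", 20,
                            simulateTrial(gt, sp, 20, 100, 4)$count,
                            provenance = "expert")
  sess <- fitSession(sess)
  sug <- suggest(sess, B = 2)
  expect_length(sug, 2)
  obs <- toScaled(sp, matrix(c(0, 40, 20), ncol = 1))
  eps <- germBO:::scaledEps(sp, "exploit")
  for (s in sug) {
    expect_true(s@feasible)
    expect_gte(exploitMetric(s@xScaled, obs, eps), 1 - 1e-6)
    # exploration anchored on the expert point, not the corner pseudo-points
    expect_lte(sum(abs(s@xScaled - 0.5) / germBO:::scaledEps(sp, "explore")),
               1 + 1e-6)
  }
})
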