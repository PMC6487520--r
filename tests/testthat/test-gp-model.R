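# Oracles: an independent textbook Matern-5/2 evaluation and a dense
# solve() implementation of the GP predictive equations, both written
# here without reference to the package internals.

oracleMatern52 <- function(a, b, alpha, rho) {
  r <- sqrt(sum((a - b)^2)) / rho
  alpha * (1 + sqrt(5) * r + (5 / 3) * r^2) * exp(-sqrt(5) * r)
}

oraclePredict <- function(X, y, m, alpha, rho, noiseDiag, xs) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- oracleMatern52(X[i, ], X[j, ], alpha, rho)
  K <- K + diag(noiseDiag + 1e-10, n)
  ks <- vapply(1:n, function(i) oracleMatern52(xs, X[i, ], alpha, rho),
               numeric(1))
  Ki <- solve(K)
  mu <- m + sum(ks * (Ki %*% (y - m)))
  v <- oracleMatern52(xs, xs, alpha, rho) - drop(t(ks) %*% Ki %*% ks)
  c(mu, max(v, 0))
}

test_that("kernel evaluation matches a direct textbook formula", {
  expect_equal(maternKernel(c(0.2, 0.3), c(0.2, 0.3), alpha = 1.7, rho = 0.4),
               1.7)                                   # r = 0 -> alpha
  expect_equal(maternKernel(c(0.2), c(0.2), 2, 0.3, sigma2 = 0.5,
                            sameIndex = TRUE), 2.5)   # white noise on diagonal
  expect_lt(maternKernel(c(0), c(1e4), 1, 0.1), 1e-12)  # r -> Inf -> 0
  set.seed(21)
  for (i in 1:50) {
    a <- runif(3); b <- runif(3); al <- runif(1, 0.1, 5); rh <- runif(1, 0.05, 2)
    expect_equal(maternKernel(a, b, al, rh), oracleMatern52(a, b, al, rh),
                 tolerance = 1e-12)
  }
  expect_error(maternKernel(c(1, 2), c(1), 1, 1), "dimension")
})

test_that("predictive mean and sd agree with a dense-formula oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:30, 1); d <- sample(1:3, 1)
    X <- matrix(runif(n * d), n, d)
    y <- rnorm(n)
    floors <- runif(n, 0, 0.02)
    hyper <- c(alpha = runif(1, 0.3, 3), rho = runif(1, 0.2, 1.5),
               sigma2 = runif(1, 0.01, 0.2))
    mode <- sample(c("global", "per-obs"), 1)
    fit <- fitGP(X, y, floors = floors, noiseMode = mode, hyper = hyper)
    xs <- runif(d)
    pr <- predict(fit, xs)
    nd <- if (mode == "per-obs") pmax(hyper["sigma2"], floors)
          else rep(hyper["sigma2"], n)
    or <- oraclePredict(X, y, mean(y), hyper["alpha"], hyper["rho"], nd, xs)
    expect_equal(pr$mean, or[1], tolerance = 1e-8)
    expect_equal(pr$sd^2, or[2], tolerance = 1e-8)
  }
})

test_that("prediction reverts to the prior far from data and interpolates at it", {
  fit <- fitGP(matrix(c(0.4, 0.5), ncol = 1), c(1, 2),
               hyper = c(alpha = 2, rho = 0.05, sigma2 = 1e-9))
  far <- predict(fit, matrix(300, 1, 1))
  expect_equal(far$mean, fit@mean, tolerance = 1e-9)
  expect_equal(far$sd^2, 2, tolerance = 1e-6)       # prior amplitude alpha
  # near-noiseless interpolation at a training input
  atX <- predict(fit, matrix(0.4, 1, 1))
  expect_equal(atX$mean, 1, tolerance = 1e-3)
  # replicate disagreement is absorbed by noise: mean between the targets
  f2 <- fitGP(matrix(c(0.5, 0.5), ncol = 1), c(0, 1), nRestarts = 5, seed = 2,
              bounds = defaultHyperBounds(NULL))
  pm <- predict(f2, matrix(0.5, 1, 1))$mean
  expect_gt(pm, 0); expect_lt(pm, 1)
})

test_that("MLE recovers known hyperparameters within a factor-of-2 bracket", {
  set.seed(42)
  n <- 40; d <- 2
  X <- matrix(runif(n * d), n, d)
  Dm <- as.matrix(dist(X))
  r <- Dm / 0.3
  K <- (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r) + diag(0.05, n)
  y <- drop(crossprod(chol(K), rnorm(n)))
  fit <- fitGP(X, y, nRestarts = 30, seed = 7, bounds = defaultHyperBounds(NULL))
  h <- hyperParams(fit)
  truth <- c(alpha = 1, rho = 0.3, sigma2 = 0.05)
  expect_true(all(h >= truth / 2 & h <= truth * 2))
  # optimizer contract: the returned fit beats every restart's initialization
  set.seed(7)
  lb <- log(rep(1e-5, 3)); ub <- log(rep(1e5, 3))
  starts <- matrix(runif(90, rep(lb, 30), rep(ub, 30)), ncol = 3, byrow = TRUE)
  for (k in 1:30) {
    h0 <- exp(starts[k, ])
    f0 <- fitGP(X, y, hyper = c(alpha = h0[1], rho = h0[2], sigma2 = h0[3]))
    expect_gte(logLik(fit) + 1e-8, logLik(f0))
  }
})

test_that("fitted noise respects the coupled global floor", {
  set.seed(5)
  X <- matrix(runif(24), ncol = 2)
  y <- runif(12, 0, 2)
  fit <- fitGP(X, y, nRestarts = 10, seed = 3, bounds = defaultHyperBounds(100))
  expect_gte(fit@sigma2, varianceFloorGlobal(100))
})

test_that("posterior mean shifts with a constant added to all targets", {
  set.seed(14)
  X <- matrix(runif(20), ncol = 1)
  y <- sin(4 * X[, 1])
  hyper <- c(alpha = 1, rho = 0.3, sigma2 = 0.05)
  xq <- matrix(seq(0, 1, 0.1), ncol = 1)
  p1 <- predict(fitGP(X, y, hyper = hyper), xq)
  p2 <- predict(fitGP(X, y + 5, hyper = hyper), xq)
  expect_equal(p2$mean, p1$mean + 5, tolerance = 1e-9)
  expect_equal(p2$sd, p1$sd, tolerance = 1e-12)
})

test_that("adding a noiseless observation shrinks predictive variance there", {
  set.seed(9)
  X <- matrix(runif(10), ncol = 1)
  y <- cos(3 * X[, 1])
  hyper <- c(alpha = 1, rho = 0.3, sigma2 = 0.01)
  fit <- fitGP(X, y, hyper = hyper)
  xq <- 0.37
  before <- predict(fit, xq)$sd
  fit2 <- updateGP(fit, xq, predict(fit, xq)$mean, 0)
  after <- predict(fit2, xq)$sd
  expect_lt(after, before + 1e-12)
  expect_error(fitGP(X, c(y[-1], NA), nRestarts = 2), "finite")
})
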