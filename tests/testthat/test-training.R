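test_that("euclidean loss follows its 1/(2n) definition", {
  y <- rnorm(10)
  expect_equal(euclideanLoss(y, y), 0)
  expect_equal(euclideanLoss(c(0, 2), c(0, 0)), 1)
  e <- rnorm(10)
  expect_equal(euclideanLoss(y, y + 3 * e), 9 * euclideanLoss(y, y + e))
  expect_error(euclideanLoss(1:3, 1:2), "length mismatch")
})

test_that("penalized cost adds per-group squared norms", {
  p <- initParams(netArchitecture(1L, "linear"), 1L, seed = 1)
  p@weights[[1L]] <- matrix(2, 1, 1)
  y <- c(1, 2)
  expect_equal(penalizedCost(p, y, y, penaltyConfig(0)), 0)
  expect_equal(penalizedCost(p, y, y, penaltyConfig(1.4)), 1.4 * 4)
  # lambda = 0 reduces to the loss
  yh <- y + c(1, -1)
  expect_equal(penalizedCost(p, y, yh, penaltyConfig(0)),
               euclideanLoss(y, yh))
})

test_that("backprop gives the hand-derived single-layer gradient", {
  p <- initParams(netArchitecture(1L, "linear"), 1L, seed = 1)
  p@weights[[1L]] <- matrix(1, 1, 1)
  p@biases[[1L]] <- 0
  g <- backprop(p, matrix(1, 1, 1), 0)
  expect_equal(as.numeric(g$W[[1L]]), 1)  # (1/n)(yhat - y) x = 1
  expect_equal(g$b[[1L]], 1)
})

test_that("backprop matches central finite differences on random nets", {
  set.seed(42)
  for (act in c("linear", "tanh", "relu")) {
    arch <- netArchitecture(c(2L, 1L), act)
    n <- 5L; p <- 3L
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    pars <- initParams(arch, p, seed = 7)
    pars@biases <- lapply(pars@biases, function(b) rnorm(length(b), 0, 0.3))
    ga <- flatGrads(backprop(pars, X, y))
    gn <- fdGradient(pars, X, y)
    expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-5)
  }
})

test_that("masked-out weights receive zero gradient", {
  set.seed(8)
  arch <- netArchitecture(1L, "linear")
  spec <- dropoutSpec(0.5, 0.5)
  pars <- initParams(arch, 6L, seed = 9)
  X <- matrix(rnorm(24), 4, 6)
  masks <- list(c(1, 0, 1, 0, 1, 1))
  g <- backprop(pars, X, rnorm(4), masks = masks, spec = spec)
  expect_equal(as.numeric(g$W[[1L]])[c(2, 4)], c(0, 0))
  expect_true(all(as.numeric(g$W[[1L]])[c(1, 3, 5, 6)] != 0))
})

test_that("plain gradient-descent step updates against the gradient", {
  p <- initParams(netArchitecture(1L, "linear"), 1L, seed = 1)
  p@weights[[1L]] <- matrix(1, 1, 1)
  g0 <- list(W = list(matrix(0, 1, 1)), b = list(0))
  expect_equal(gdStep(p, g0, 0.1)@weights[[1L]], p@weights[[1L]])
  g2 <- list(W = list(matrix(2, 1, 1)), b = list(0))
  expect_equal(as.numeric(gdStep(p, g2, 0.1)@weights[[1L]]), 0.8)
})

test_that("one full-batch gd iteration equals a manual coupled step", {
  set.seed(10)
  X <- matrix(rnorm(20), 5, 4)
  y <- rnorm(5)
  pen <- penaltyConfig(0.3)
  p0 <- initParams(netArchitecture(1L, "linear"), 4L, seed = 11)
  manual <- gdStep(p0, backprop(p0, X, y, penalty = pen, coupled = TRUE),
                   eta = 0.05)
  auto <- gdTrain(p0, X, y, pen, eta = 0.05, iterations = 1L)
  expect_equal(auto@weights, manual@weights, tolerance = 1e-12)
  expect_equal(auto@biases, manual@biases, tolerance = 1e-12)
})

test_that("adam first step moves by about -eta * sign(gradient)", {
  p <- initParams(netArchitecture(1L, "linear"), 2L, seed = 2)
  st <- adamInit(p, eta = 0.01)
  g <- list(W = list(matrix(c(2, -3), 2, 1)), b = list(0.5))
  out <- adamStep(st, p, g, penaltyConfig(0), batchSize = 1L)
  step <- as.numeric(out$params@weights[[1L]] - p@weights[[1L]])
  expect_equal(step, c(-0.01, 0.01), tolerance = 1e-6)
  expect_equal(out$state$t, 1L)
})

test_that("adam with zero gradient applies pure decoupled decay", {
  p <- initParams(netArchitecture(1L, "linear"), 3L, seed = 3)
  st <- adamInit(p, eta = 0.1)
  g0 <- list(W = list(matrix(0, 3, 1)), b = list(0))
  # lambda = 0: parameters unchanged
  out <- adamStep(st, p, g0, penaltyConfig(0), batchSize = 4L)
  expect_equal(out$params@weights, p@weights)
  # lambda > 0: theta <- (1 - eta*lambda/b) * theta exactly
  out2 <- adamStep(st, p, g0, penaltyConfig(2), batchSize = 4L)
  expect_equal(out2$params@weights[[1L]],
               (1 - 0.1 * 2 / 4) * p@weights[[1L]])
  # parameter norm strictly decreasing across repeated decay steps
  norms <- numeric(5)
  cur <- list(params = p, state = st)
  for (i in 1:5) {
    cur <- adamStep(cur$state, cur$params, g0, penaltyConfig(2),
                    batchSize = 4L)
    norms[i] <- sqrt(sum(paramVector(cur$params)^2))
  }
  expect_true(all(diff(c(sqrt(sum(paramVector(p)^2)), norms)) < 0))
  # sign-flipping decay is rejected
  expect_error(adamStep(st, p, g0, penaltyConfig(50), batchSize = 1L),
               "not positive")
})

test_that("full-batch gd on the coupled objective reaches the ridge solution", {
  set.seed(7)
  n <- 40L; p <- 3L; lam <- 0.7
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  y <- as.numeric(X %*% c(1, -2, 0.5) + rnorm(n))
  y <- y - mean(y)
  ridge <- solve(crossprod(X) + 2 * n * lam * diag(p), crossprod(X, y))
  p0 <- initParams(netArchitecture(1L, "linear"), p, seed = 1)
  tr <- gdTrain(p0, X, y, penaltyConfig(lam), eta = 0.05,
                iterations = 40000L)
  expect_lt(max(abs(as.numeric(tr@weights[[1L]]) - as.numeric(ridge))), 1e-6)
})
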