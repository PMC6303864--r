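chainFixture <- function(iterations = 50L, burnIn = 10L, seed = 9,
                         keepSnapshots = TRUE, dropout = dropoutSpec(0.5, 0.5),
                         penalty = penaltyConfig(0.05)) {
  set.seed(1)
  n <- 60L; p <- 5L
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n) * 0.5)
  Xte <- matrix(rnorm(20L * p), 20L, p)
  yte <- as.numeric(Xte %*% rep(0.3, p) + rnorm(20L))
  params <- initParams(netArchitecture(1L, "linear"), p, seed = 2)
  cfg <- trainConfig(penalty = penalty, dropout = dropout, batchSize = 16L)
  list(chain = runChain(X, y, Xte, yte, params, cfg,
                        iterations = iterations, burnIn = burnIn,
                        keepSnapshots = keepSnapshots, seed = seed),
       X = X, y = y, Xte = Xte, yte = yte, params = params, cfg = cfg)
}

test_that("per-iteration test MSE follows its definition", {
  expect_equal(mseT(c(1, 2), c(1, 2)), 0)
  expect_equal(mseT(c(1, 3), c(0, 0)), 5)
  y <- rnorm(8)
  expect_equal(mseT(y + 2, y), 4)
  expect_error(mseT(1:3, 1:2), "length mismatch")
})

test_that("a chain records one mse/mae/prediction set per iteration", {
  fx <- chainFixture(iterations = 1L, burnIn = 0L)
  expect_length(mseTrace(fx$chain), 1L)
  expect_equal(dim(fx$chain@predictions), c(1L, 20L))
  fx2 <- chainFixture(iterations = 30L, burnIn = 5L)
  expect_length(mseTrace(fx2$chain), 30L)
  expect_true(all(is.finite(mseTrace(fx2$chain))))
})

test_that("identical seeds give bitwise-identical chains", {
  a <- chainFixture(seed = 33)$chain
  b <- chainFixture(seed = 33)$chain
  expect_identical(mseTrace(a), mseTrace(b))
  expect_identical(a@predictions, b@predictions)
  expect_identical(a@finalParams@weights, b@finalParams@weights)
})

test_that("a resumed chain reproduces the unbroken trace exactly", {
  fx <- chainFixture(iterations = 2L, burnIn = 0L)  # just to reuse the data
  set.seed(77)
  full <- runChain(fx$X, fx$y, fx$Xte, fx$yte, fx$params, fx$cfg,
                   iterations = 30L, burnIn = 5L)
  set.seed(77)
  part1 <- runChain(fx$X, fx$y, fx$Xte, fx$yte, fx$params, fx$cfg,
                    iterations = 12L, burnIn = 5L)
  part2 <- runChain(fx$X, fx$y, fx$Xte, fx$yte, part1@finalParams, fx$cfg,
                    iterations = 18L, burnIn = 0L,
                    optimizerState = part1@optState)
  expect_equal(c(mseTrace(part1), mseTrace(part2)), mseTrace(full),
               tolerance = 1e-12)
})

test_that("summary moments equal a two-pass oracle over snapshots", {
  fx <- chainFixture()
  s <- summarizeChain(fx$chain)
  keep <- 11:50
  # model-averaged MSE is exactly the mean of the retained MSE_t values
  expect_identical(s@mseModelAveraged, mean(mseTrace(fx$chain)[keep]))
  expect_identical(s@maeModelAveraged, mean(maeTrace(fx$chain)[keep]))
  # two-pass mean/variance over the stored omega snapshots (1/(T - t_s))
  snaps <- sapply(fx$chain@snapshots[keep], function(x) as.numeric(x$W[[1L]]))
  mu <- rowMeans(snaps)
  v <- rowMeans((snaps - mu)^2)
  expect_equal(as.numeric(s@meanParams$W[[1L]]), mu, tolerance = 1e-12)
  expect_equal(as.numeric(s@varParams$W[[1L]]), v, tolerance = 1e-12)
  expect_true(all(as.numeric(s@varParams$W[[1L]]) >= 0))
})

test_that("model-averaged MSE dominates the MSE of the mean prediction", {
  for (seed in c(5, 6, 7)) {
    fx <- chainFixture(seed = seed, keepSnapshots = FALSE)
    s <- summarizeChain(fx$chain)
    expect_gte(s@mseModelAveraged, mseT(s@meanPrediction, fx$yte))
  }
})

test_that("recomputing moments for a different burn-in needs snapshots", {
  fx <- chainFixture(keepSnapshots = TRUE)
  s2 <- summarizeChain(fx$chain, t_s = 25L)
  expect_identical(s2@mseModelAveraged, mean(mseTrace(fx$chain)[26:50]))
  snaps <- sapply(fx$chain@snapshots[26:50], function(x) as.numeric(x$W[[1L]]))
  expect_equal(as.numeric(s2@meanParams$W[[1L]]), rowMeans(snaps),
               tolerance = 1e-12)
  bare <- chainFixture(keepSnapshots = FALSE)$chain
  expect_error(summarizeChain(bare, t_s = 25L), "keepSnapshots")
  expect_error(summarizeChain(bare, t_s = 50L), "smaller than the chain")
})

test_that("without dropout and decay the chain converges to least squares", {
  set.seed(4)
  n <- 50L; p <- 2L
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(0.8, -0.5) + rnorm(n) * 0.3)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  pr <- initParams(netArchitecture(1L, "linear"), p, seed = 5)
  cfg <- trainConfig(penalty = penaltyConfig(0),
                     dropout = dropoutSpec(1, 1), batchSize = n, eta = 0.01)
  ch <- runChain(X, y, X, y, pr, cfg, iterations = 2000L, burnIn = 1500L,
                 seed = 6)
  pred <- summarizeChain(ch)@meanPrediction
  olsPred <- as.numeric(cbind(1, X) %*% ols)
  expect_lt(max(abs(pred - olsPred)), 0.02)
})

test_that("trace report writes (t, mse, mae) and the plot renders", {
  fx <- chainFixture(iterations = 3L, burnIn = 1L)
  f <- tempfile(fileext = ".csv")
  traceReport(fx$chain, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(names(tab), c("t", "mse", "mae"))
  expect_equal(tab$mse, mseTrace(fx$chain))
  expect_s3_class(plotTrace(fx$chain), "ggplot")
})

test_that("plateau detection flags a constructed changepoint", {
  set.seed(12)
  trace <- c(seq(50, 10, length.out = 120), rep(10, 180)) + rnorm(300, 0, 0.01)
  t0 <- detectPlateau(trace, window = 40L, tol = 0.5)
  expect_true(is.finite(t0))
  expect_gt(t0, 80L)
  expect_lt(t0, 220L)
  # a steadily decreasing trace has no plateau at a tight tolerance
  expect_true(is.na(detectPlateau(seq(100, 1, length.out = 200),
                                  window = 40L, tol = 1e-6)))
})

test_that("the default-scenario fit beats the mean predictor", {
  # desk-scale spot check of the predictive sanity property on the full
  # simulated architecture
  for (seed in c(101, 102)) {
    sim <- simulateDataset(simConfig(n = 800L, p = 200L), seed = seed)
    fit <- abnnFit(sim$genotypes, sim$phenotypes, sim$split,
                   config = trainConfig(penalty = penaltyConfig(0.01)),
                   iterations = 600L, burnIn = 200L, seed = seed + 1L)
    vy <- var(sim$phenotypes[testIds(sim$split)])
    expect_lt(fit@summary@mseModelAveraged, vy)
  }
})
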