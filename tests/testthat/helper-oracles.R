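# Shared oracles and fixture builders (everything is generated in code).

flatGrads <- function(g) c(unlist(g$W), unlist(g$b))

paramVector <- function(p) c(unlist(p@weights), unlist(p@biases))

withParamVector <- function(p, v) {
  i <- 0
  for (l in seq_along(p@weights)) {
    nw <- length(p@weights[[l]])
    p@weights[[l]][] <- v[i + seq_len(nw)]
    i <- i + nw
  }
  for (l in seq_along(p@biases)) {
    nb <- length(p@biases[[l]])
    p@biases[[l]][] <- v[i + seq_len(nb)]
    i <- i + nb
  }
  p
}

# independent oracle: central finite differences of the Euclidean loss
fdGradient <- function(params, X, y, eps = 1e-6) {
  v0 <- paramVector(params)
  g <- numeric(length(v0))
  for (i in seq_along(v0)) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    lp <- euclideanLoss(y, forwardPass(withParamVector(params, vp), X)$pred)
    lm <- euclideanLoss(y, forwardPass(withParamVector(params, vm), X)$pred)
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}

# small GenotypeData built in code
toyGenotypes <- function(n = 6, p = 4, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("m", seq_len(p))))
  GenotypeData(G)
}

writeToyCsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# single-QTL recovery scenario configs used by the acceptance-style tests
scenarioConfig <- function(scenario) {
  switch(scenario,
    controlled = simConfig(nControlled = 1L, nRandom = 0L,
                           nEpistaticPairs = 0L, dominance = FALSE,
                           overdominance = FALSE, underdominance = FALSE),
    dominance = simConfig(nControlled = 0L, nRandom = 0L,
                          nEpistaticPairs = 0L, dominance = TRUE,
                          overdominance = FALSE, underdominance = FALSE),
    overdominance = simConfig(nControlled = 0L, nRandom = 0L,
                              nEpistaticPairs = 0L, dominance = FALSE,
                              overdominance = TRUE, underdominance = FALSE))
}

# one recovery replicate: simulate, fit the k=1 linear one-hot model with
# small input decay, return effect estimates at the causal marker
recoveryReplicate <- function(scenario, seed, iterations = 2000L,
                              burnIn = 500L) {
  cfg <- scenarioConfig(scenario)
  sim <- simulateDataset(cfg, seed = seed)
  fit <- abnnFit(sim$genotypes, sim$phenotypes, sim$split,
                 arch = netArchitecture(1L, "linear"),
                 config = trainConfig(penalty = penaltyConfig(0.01),
                                      dropout = dropoutSpec(0.5, 0.5)),
                 iterations = iterations, burnIn = burnIn,
                 seed = seed + 10000L)
  tb <- effectTable(fit)
  ci <- sim$truth@table$marker[1L]
  list(a = tb$a[ci], d = tb$d[ci], truth = sim$truth@table[1L, ],
       mse = fit@summary@mseModelAveraged,
       varYtest = var(sim$phenotypes[testIds(sim$split)]),
       topA = rankEffects(tb, "a", 1L)$marker_id,
       topD = rankEffects(tb, "d", 1L)$marker_id,
       causal = sim$truth@table$marker_id[1L])
}
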