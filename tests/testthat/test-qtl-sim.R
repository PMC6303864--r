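test_that("genotype simulation is seeded and Hardy-Weinberg consistent", {
  cfg <- simConfig(n = 1200L, p = 60L)
  g1 <- simulateGenotypes(cfg, seed = 3)
  g2 <- simulateGenotypes(cfg, seed = 3)
  expect_identical(dosageMatrix(g1), dosageMatrix(g2))

  # per-marker chi-square against HWE proportions from the allele frequency
  G <- dosageMatrix(g1)
  pvals <- apply(G, 2L, function(g) {
    q <- mean(g) / 2
    expd <- length(g) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(g + 1L, 3L)
    stat <- sum((obs - expd)^2 / pmax(expd, 1e-9))
    pchisq(stat, df = 1L, lower.tail = FALSE)
  })
  # aggregated: about alpha of markers rejected at alpha = 0.01
  expect_lt(mean(pvals < 0.01), 0.05)
})

test_that("rho = 0 gives independent adjacent markers", {
  g <- simulateGenotypes(simConfig(n = 2000L, p = 60L, rho = 0), seed = 4)
  expect_lt(adjacentR2(g), 0.005)  # E[r^2] = 1/n under independence
})

test_that("truncated-normal effects match the rejection-sampling law", {
  set.seed(11)
  draws <- rTruncatedEffect(4000L, sd = sqrt(10), limit = 2)
  expect_true(all(abs(draws) < 2))
  # inverse-CDF oracle for N(0, 10) truncated to (-2, 2)
  sdv <- sqrt(10)
  trunccdf <- function(x) {
    (pnorm(x / sdv) - pnorm(-2 / sdv)) /
      (pnorm(2 / sdv) - pnorm(-2 / sdv))
  }
  ks <- suppressWarnings(ks.test(draws, trunccdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("QTL assignment uses the configured classes and effect values", {
  cfg <- simConfig(n = 500L, p = 120L)
  g <- simulateGenotypes(cfg, seed = 5)
  set.seed(6)
  truth <- assignQtlEffects(cfg, g)
  tb <- truth@table
  expect_equal(sum(tb$class %in% c("controlled", "epistatic")), 9L)
  expect_equal(sum(tb$class == "epistatic"), 4L)
  expect_equal(sum(tb$class == "random"), 28L)
  # every controlled/epistatic QTL has the fixed +3 additive effect
  expect_true(all(tb$a[tb$class %in% c("controlled", "epistatic")] == 3))
  # controlled QTL sit at highly polymorphic markers
  expect_true(all(maf(g)[tb$marker[tb$class %in%
                                     c("controlled", "epistatic")]] >= 0.35))
  # random effects truncated at |a| < 2
  expect_true(all(abs(tb$a[tb$class == "random"]) < 2))
  # epistatic partners are mutual
  epi <- tb[tb$class == "epistatic", ]
  expect_equal(sort(epi$partner), sort(epi$marker))
  for (i in seq_len(nrow(epi)))
    expect_equal(epi$partner[epi$marker == epi$partner[i]], epi$marker[i])
  # dominance-class value maps as configured
  dom <- tb[tb$class == "dominance", ]
  expect_equal(c(dom$v0, dom$v1, dom$v2), c(0, 5, 5.01))
  expect_equal(dom$d, 5)
  od <- tb[tb$class == "overdominance", ]
  expect_equal(c(od$v0, od$v1, od$v2), c(-0.01, 5, 0.01))
  ud <- tb[tb$class == "underdominance", ]
  expect_equal(ud$d, -5)
  expect_true(!anyDuplicated(tb$marker))
})

test_that("noise-free phenotypes follow the stated composition rule", {
  # one controlled QTL, no residual: y takes exactly the values -3, 0, +3
  cfg <- simConfig(n = 300L, p = 30L, nControlled = 1L, nRandom = 0L,
                   nEpistaticPairs = 0L, dominance = FALSE,
                   overdominance = FALSE, underdominance = FALSE)
  g <- simulateGenotypes(cfg, seed = 7)
  set.seed(8)
  truth <- assignQtlEffects(cfg, g)
  ph <- simulatePhenotypes(g, truth, residSd = 1e-12, seed = 9)
  expect_true(all(abs(ph$phenotypes - round(ph$phenotypes)) < 1e-6))
  expect_true(all(round(ph$phenotypes) %in% c(-3, 0, 3)))
  # additive coding identity: homozygote means differ by exactly 2a
  gi <- dosageMatrix(g)[, truth@table$marker[1L]]
  expect_equal(mean(ph$phenotypes[gi == 2]) - mean(ph$phenotypes[gi == 0]), 6)

  # full architecture, recomputed by an independent R oracle
  cfg2 <- simConfig(n = 200L, p = 80L, nControlled = 4L, nRandom = 3L,
                    nEpistaticPairs = 2L)
  g2 <- simulateGenotypes(cfg2, seed = 10)
  set.seed(11)
  truth2 <- assignQtlEffects(cfg2, g2)
  ph2 <- simulatePhenotypes(g2, truth2, residSd = 1e-12, seed = 12)
  G2 <- dosageMatrix(g2)
  tb <- truth2@table
  oracle <- numeric(nrow(G2))
  for (i in seq_len(nrow(tb))) {
    gi <- G2[, tb$marker[i]]
    oracle <- oracle + if (is.na(tb$v1[i])) {
      tb$a[i] * (gi - 1)
    } else c(tb$v0[i], tb$v1[i], tb$v2[i])[gi + 1L]
  }
  epi <- tb[tb$class == "epistatic", ]
  seen <- c()
  for (i in seq_len(nrow(epi))) {
    key <- paste(sort(c(epi$marker[i], epi$partner[i])), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    oracle <- oracle +
      4 * (G2[, epi$marker[i]] == 0 & G2[, epi$partner[i]] == 0)
  }
  expect_equal(unname(ph2$phenotypes), unname(oracle), tolerance = 1e-6)
  # the epistatic bonus actually fires for some pair
  expect_gt(sum(G2[, epi$marker[1L]] == 0 & G2[, epi$partner[1L]] == 0), 0)
})

test_that("residual SD helper hits the target heritability", {
  sim <- simulateDataset(simConfig(n = 3000L, p = 150L, h2 = 0.38), seed = 13)
  expect_lt(abs(sim$h2 - 0.38), 0.03)
  g <- rnorm(5000, 0, 2)
  se <- residualSdForH2(g, 0.5)
  expect_equal(se, sd(g), tolerance = 1e-12)
})

test_that("simulated datasets are reproducible end to end and filtered", {
  cfg <- simConfig(n = 150L, p = 40L, nControlled = 2L, nRandom = 2L,
                   nEpistaticPairs = 1L)
  s1 <- simulateDataset(cfg, seed = 14)
  s2 <- simulateDataset(cfg, seed = 14)
  expect_identical(dosageMatrix(s1$genotypes), dosageMatrix(s2$genotypes))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth@table, s2$truth@table)
  # all causal markers survive the MAF filter and indices stay aligned
  expect_true(all(maf(s1$genotypes)[s1$truth@table$marker] >= 0.05))
  expect_equal(markerIds(s1$genotypes)[s1$truth@table$marker],
               s1$truth@table$marker_id)
  # pseudo-generation holdout: last fifth is the test set
  expect_equal(length(testIds(s1$split)), 30L)
  d <- tempfile()
  writeSimData(s1, d)
  expect_true(all(file.exists(file.path(d, c("genotypes.csv",
                                             "phenotypes.csv", "split.csv",
                                             "truth.json")))))
  rt <- readGenotypes(file.path(d, "genotypes.csv"))
  expect_equal(dosageMatrix(rt), dosageMatrix(s1$genotypes))
})
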