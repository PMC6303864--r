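#' Simulation configuration
#'
#' Desk-scale emulation of a livestock-style quantitative trait: a panel of
#' biallelic SNPs on several chromosomes with tunable adjacent-marker LD,
#' and a trait built from controlled additive QTL (fixed effect +3, placed
#' at highly polymorphic markers), random additive QTL (effects from a
#' truncated normal N(0, 10) accepted when |a| < 2), additive-by-additive
#' epistatic pairs (+4 when both members are lower homozygotes), and one
#' locus each of full dominance (genotype values 0, 5, 5.01), over-dominance
#' (-0.01, 5, 0.01) and under-dominance (-0.01, -5, 0.01).  Genotype-value
#' contributions of additive QTL are coded `a * (g - 1)` so that `a` is
#' half the difference between the homozygote means.
#'
#' @param n individuals.
#' @param p markers.
#' @param chromosomes number of chromosomes (markers split evenly).
#' @param rho latent adjacent-marker haplotype correlation in `[0, 1)`; the
#'   default is calibrated so the mean adjacent-marker genotype r^2 (at
#'   MAF > 0.05) is about 0.10 (see [calibrateRho()]).
#' @param mafRange range the per-marker allele frequencies are drawn from.
#' @param nControlled,nRandom,nEpistaticPairs QTL counts; the first
#'   `2 * nEpistaticPairs` controlled QTL form the epistatic pairs.
#' @param dominance,overdominance,underdominance include one locus of the
#'   class.
#' @param controlledEffect,epistaticBonus,randomSd,randomTrunc effect-size
#'   parameters (defaults +3, +4, sqrt(10), 2).
#' @param domValues,overdomValues,underdomValues genotype-value triples
#'   (value for g = 0, 1, 2).
#' @param h2 target heritability used to set the residual SD.
#' @param epiRule `"joint"`: the +4 bonus applies when both pair members
#'   are homozygous for the lower allele; `"perlocus"`: each lower
#'   homozygote locus of a pair contributes +4 on its own.
#' @param mafThreshold MAF filter applied after trait construction.
#' @return A list with class `"SimConfig"`.
#' @export
simConfig <- function(n = 2000L, p = 500L, chromosomes = 5L, rho = 0.53,
                      mafRange = c(0.05, 0.5), nControlled = 9L,
                      nRandom = 28L, nEpistaticPairs = 2L,
                      dominance = TRUE, overdominance = TRUE,
                      underdominance = TRUE, controlledEffect = 3,
                      epistaticBonus = 4, randomSd = sqrt(10),
                      randomTrunc = 2, domValues = c(0, 5, 5.01),
                      overdomValues = c(-0.01, 5, 0.01),
                      underdomValues = c(-0.01, -5, 0.01), h2 = 0.4,
                      epiRule = c("joint", "perlocus"),
                      mafThreshold = 0.01) {
  epiRule <- match.arg(epiRule)
  nqtl <- nControlled + nRandom + dominance + overdominance + underdominance
  stopifnot(n >= 2L, p >= 1L, rho >= 0, rho < 1, nqtl <= p,
            2L * nEpistaticPairs <= nControlled, h2 > 0, h2 < 1)
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate linked SNP genotypes
#'
#' Two haplotypes per individual; along each chromosome a haplotype is a
#' thresholded first-order Gaussian autoregression, i.e. marker j carries
#' the minor allele when a latent AR(1) variable with lag correlation
#' `rho` falls below `qnorm(q_j)`, so the allele frequencies `q_j` (drawn
#' from `mafRange`) are matched exactly and adjacent markers are
#' correlated.  Dosage = haplotype sum, so genotype frequencies are
#' Hardy-Weinberg consistent by construction.
#'
#' @param config a [simConfig()].
#' @param seed optional integer seed.
#' @return A [GenotypeData] with chrom/pos metadata.
#' @export
simulateGenotypes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n; p <- config$p; nc <- config$chromosomes
  sizes <- rep(p %/% nc, nc) + c(rep(1L, p %% nc), rep(0L, nc - p %% nc))
  q <- runif(p, config$mafRange[1L], config$mafRange[2L])
  G <- matrix(0L, n, p)
  col0 <- 0L
  for (chr in seq_len(nc)) {
    m <- sizes[chr]
    if (m == 0L) next
    thr <- qnorm(q[col0 + seq_len(m)])
    for (hap in 1:2) {
      u <- matrix(0, n, m)
      u[, 1L] <- rnorm(n)
      if (m > 1L) {
        s <- sqrt(1 - config$rho^2)
        for (j in 2:m) u[, j] <- config$rho * u[, j - 1L] + s * rnorm(n)
      }
      G[, col0 + seq_len(m)] <- G[, col0 + seq_len(m)] +
        (sweep(u, 2L, thr, `<`)) * 1L
    }
    col0 <- col0 + m
  }
  chrom <- rep(paste0("chr", seq_len(nc)), times = sizes)
  within <- unlist(lapply(sizes, seq_len))
  ids <- paste0(chrom, "_m", within)
  dimnames(G) <- list(paste0("ind", seq_len(n)), ids)
  GenotypeData(G, chrom = chrom, pos = as.integer(within * 100000L))
}

#' Mean adjacent-marker LD (r^2)
#'
#' Mean squared correlation between the dosages of adjacent markers on the
#' same chromosome, restricted to pairs where both markers have
#' MAF > `mafMin` (the usual LD summary for SNP panels).
#'
#' @param x a [GenotypeData].
#' @param mafMin MAF restriction.
#' @return Scalar mean r^2.
#' @export
adjacentR2 <- function(x, mafMin = 0.05) {
  G <- dosageMatrix(x)
  chrom <- as.character(SummarizedExperiment::rowData(x)$chrom)
  m <- maf(x)
  r2 <- c()
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    if (length(j) < 2L) next
    for (k in seq_len(length(j) - 1L)) {
      a <- j[k]; b <- j[k + 1L]
      if (m[a] > mafMin && m[b] > mafMin) {
        r <- suppressWarnings(stats::cor(G[, a], G[, b]))
        if (is.finite(r)) r2 <- c(r2, r^2)
      }
    }
  }
  mean(r2)
}

#' Calibrate the haplotype correlation to a target adjacent-marker r^2
#'
#' Bisection on `rho`, measuring the mean adjacent r^2 by simulation at
#' each step.  Used once to fix the [simConfig()] default.
#'
#' @param targetR2 target mean adjacent r^2 (default 0.10).
#' @param n,p simulation size per evaluation.
#' @param seed seed for the evaluation simulations.
#' @param tol bisection tolerance on r^2.
#' @return List with `rho` and the achieved `r2`.
#' @export
calibrateRho <- function(targetR2 = 0.10, n = 1500L, p = 300L, seed = 1L,
                         tol = 0.005) {
  lo <- 0; hi <- 0.95
  eval_rho <- function(rho, s) {
    cfg <- simConfig(n = n, p = p, rho = rho)
    adjacentR2(simulateGenotypes(cfg, seed = s))
  }
  rho <- NA_real_; achieved <- NA_real_
  for (i in 1:12) {
    rho <- (lo + hi) / 2
    achieved <- eval_rho(rho, seed + i)
    if (abs(achieved - targetR2) < tol) break
    if (achieved > targetR2) hi <- rho else lo <- rho
  }
  list(rho = rho, r2 = achieved)
}

#' Ground-truth QTL assignment
#'
#' Holds, per QTL: marker index and id, class, effect parameters (additive
#' `a` for controlled/random/epistatic loci; the genotype-value triple
#' `v0, v1, v2` for dominance-class loci, with `d` the heterozygote value
#' `v1`), and the epistatic partner where applicable.
#'
#' @slot table data.frame with one row per QTL.
#' @slot config the generating [simConfig()].
#' @export
setClass("SimTruth", representation(table = "data.frame", config = "list"))

setValidity("SimTruth", function(object) {
  tb <- object@table
  need <- c("marker", "marker_id", "class", "a", "d", "v0", "v1", "v2",
            "partner")
  if (!all(need %in% names(tb))) return("truth table columns missing")
  if (anyDuplicated(tb$marker)) return("QTL marker indices must be unique")
  ok <- tb$class %in% c("controlled", "random", "epistatic", "dominance",
                        "overdominance", "underdominance")
  if (!all(ok)) return("unknown QTL class")
  TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@table), "QTL (",
      paste(names(table(object@table$class)),
            table(object@table$class), collapse = ", "), ")\n")
})

#' Sample truncated-normal additive effects
#'
#' Rejection sampling from N(0, sd^2) accepting |a| < limit -- the scheme
#' used for the random QTL.
#'
#' @param n number of draws.
#' @param sd normal SD before truncation (default sqrt(10)).
#' @param limit truncation bound (default 2).
#' @return Numeric vector of accepted draws.
#' @export
rTruncatedEffect <- function(n, sd = sqrt(10), limit = 2) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 8L, 0, sd)
    out <- c(out, draw[abs(draw) < limit])
  }
  out[seq_len(n)]
}

#' Assign QTL classes and effects to simulated markers
#'
#' Controlled (and epistatic) QTL are placed at highly polymorphic markers
#' (MAF >= 0.35, falling back to the most polymorphic available); random
#' and dominance-class QTL at any marker with MAF >= 0.05.  Effects are
#' exactly the configured values; random-QTL effects come from
#' [rTruncatedEffect()].
#'
#' @param config a [simConfig()].
#' @param genotypes the [GenotypeData] the trait will be built on.
#' @param seed optional integer seed.
#' @return A [SimTruth-class].
#' @export
assignQtlEffects <- function(config, genotypes, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- maf(genotypes)
  p <- length(m)
  nCtl <- config$nControlled
  highPoly <- which(m >= 0.35)
  if (length(highPoly) < nCtl)
    highPoly <- order(m, decreasing = TRUE)[seq_len(min(p, max(nCtl, 1L)))]
  if (length(highPoly) < nCtl)
    stop("not enough polymorphic markers for the controlled QTL")
  ctl <- sort(sample(highPoly, nCtl))
  used <- ctl
  eligible <- setdiff(which(m >= 0.05), used)
  nDom <- config$dominance + config$overdominance + config$underdominance
  if (length(eligible) < config$nRandom + nDom)
    stop("not enough eligible markers for random/dominance QTL")
  rnd <- sort(sample(eligible, config$nRandom))
  used <- c(used, rnd)
  eligible <- setdiff(eligible, rnd)
  rows <- list()
  nEpi <- 2L * config$nEpistaticPairs
  partner <- rep(NA_integer_, nCtl)
  if (nEpi > 0L) {
    pairIdx <- seq_len(nEpi)
    partner[pairIdx] <- ctl[pairIdx + c(1L, -1L)]  # swap within consecutive pairs
  }
  if (nCtl > 0L) {
    rows$ctl <- data.frame(
      marker = ctl,
      class = ifelse(seq_len(nCtl) <= nEpi, "epistatic", "controlled"),
      a = config$controlledEffect, d = 0,
      v0 = NA_real_, v1 = NA_real_, v2 = NA_real_, partner = partner)
  }
  if (config$nRandom > 0L) {
    rows$rnd <- data.frame(
      marker = rnd, class = "random",
      a = rTruncatedEffect(config$nRandom, config$randomSd,
                           config$randomTrunc),
      d = 0, v0 = NA_real_, v1 = NA_real_, v2 = NA_real_,
      partner = NA_integer_)
  }
  domClass <- c("dominance", "overdominance", "underdominance")
  domOn <- c(config$dominance, config$overdominance, config$underdominance)
  vals <- list(config$domValues, config$overdomValues, config$underdomValues)
  if (any(domOn)) {
    pick <- sample(eligible, sum(domOn))
    k <- 0L
    for (i in which(domOn)) {
      k <- k + 1L
      v <- vals[[i]]
      rows[[domClass[i]]] <- data.frame(
        marker = pick[k], class = domClass[i],
        a = (v[3L] - v[1L]) / 2, d = v[2L],
        v0 = v[1L], v1 = v[2L], v2 = v[3L], partner = NA_integer_)
    }
  }
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  tb$marker_id <- markerIds(genotypes)[tb$marker]
  tb <- tb[, c("marker", "marker_id", "class", "a", "d", "v0", "v1", "v2",
               "partner")]
  methods::new("SimTruth", table = tb, config = unclass(config))
}

#' Residual SD that hits a target heritability
#'
#' `sd_e = sd(g) * sqrt((1 - h2) / h2)` for genetic values `g`.
#'
#' @param geneticValues numeric vector of total genetic values.
#' @param h2 target heritability in (0, 1).
#' @return Scalar residual SD.
#' @export
residualSdForH2 <- function(geneticValues, h2) {
  stopifnot(h2 > 0, h2 < 1)
  sd(geneticValues) * sqrt((1 - h2) / h2)
}

#' Simulate phenotypes from a genotype matrix and QTL truth
#'
#' The phenotype is the sum of: `a * (g - 1)` over additive loci
#' (controlled, random, epistatic), the genotype value `v[g]` over
#' dominance-class loci, the epistatic bonus over pairs, and Gaussian
#' residual noise.  The residual SD defaults to the value that hits the
#' configured target heritability.
#'
#' @param genotypes a [GenotypeData].
#' @param truth a [SimTruth-class].
#' @param residSd residual SD; `NULL` uses [residualSdForH2()] with the
#'   config target.
#' @param seed optional integer seed.
#' @return List with `phenotypes` (named numeric), `h2` (realized
#'   heritability var(g)/var(y)), `geneticValues`, and `residSd`.
#' @export
simulatePhenotypes <- function(genotypes, truth, residSd = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  G <- dosageMatrix(genotypes)
  tb <- truth@table
  cfg <- truth@config
  g <- numeric(nrow(G))
  for (i in seq_len(nrow(tb))) {
    gi <- G[, tb$marker[i]]
    if (tb$class[i] %in% c("controlled", "random", "epistatic")) {
      g <- g + tb$a[i] * (gi - 1)
    } else {
      v <- c(tb$v0[i], tb$v1[i], tb$v2[i])
      g <- g + v[gi + 1L]
    }
  }
  epi <- tb[tb$class == "epistatic" & !is.na(tb$partner), , drop = FALSE]
  if (nrow(epi) > 0L) {
    done <- c()
    for (i in seq_len(nrow(epi))) {
      a <- epi$marker[i]; b <- epi$partner[i]
      key <- paste(sort(c(a, b)), collapse = "-")
      if (cfg$epiRule == "joint") {
        if (key %in% done) next
        done <- c(done, key)
        g <- g + cfg$epistaticBonus * (G[, a] == 0L & G[, b] == 0L)
      } else {
        g <- g + cfg$epistaticBonus * (G[, a] == 0L)
      }
    }
  }
  if (is.null(residSd)) residSd <- residualSdForH2(g, cfg$h2)
  e <- rnorm(length(g), 0, residSd)
  y <- g + e
  names(y) <- sampleIds(genotypes)
  list(phenotypes = y, h2 = var(g) / var(y), geneticValues = g,
       residSd = residSd)
}

#' Simulate a complete dataset
#'
#' Genotypes, QTL truth, phenotypes, and a holdout split by pseudo-
#' generation: samples are labelled into five sequential "generations" and
#' the last one is the test set, mirroring the forward-prediction workflow
#' of breeding programs (no pedigree is simulated; the labels only support
#' the holdout workflow).  The
#' MAF filter is applied after trait construction; causal markers always
#' have MAF >= 0.05 and survive it.
#'
#' @param config a [simConfig()].
#' @param seed integer master seed.
#' @return List with `genotypes`, `phenotypes`, `truth`, `split`, `h2`,
#'   `residSd`, and `groups` (the generation labels).
#' @export
simulateDataset <- function(config = simConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  G <- simulateGenotypes(config)
  truth <- assignQtlEffects(config, G)
  ph <- simulatePhenotypes(G, truth)
  Gf <- mafFilter(G, config$mafThreshold)
  if (nrow(Gf) != nrow(G)) {
    keep <- markerIds(Gf)
    tb <- truth@table
    tb$marker <- match(tb$marker_id, keep)
    tb$partner <- match(markerIds(G)[tb$partner], keep)
    stopifnot(!anyNA(tb$marker))
    truth@table <- tb
    G <- Gf
  }
  gen <- cut(seq_len(config$n), breaks = 5L, labels = paste0("gen", 1:5))
  split <- makeSplit(sampleIds(G), groups = as.character(gen),
                     testGroups = "gen5")
  list(genotypes = G, phenotypes = ph$phenotypes, truth = truth,
       split = split, h2 = ph$h2, residSd = ph$residSd,
       groups = as.character(gen))
}

#' Write a simulated dataset to disk
#'
#' Genotype CSV, phenotype CSV, split CSV and ground-truth JSON.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGenotypes(sim$genotypes, file.path(dir, "genotypes.csv"))
  writePhenotypes(sim$phenotypes, file.path(dir, "phenotypes.csv"))
  writeSplit(sim$split, file.path(dir, "split.csv"))
  jsonlite::write_json(
    list(qtl = sim$truth@table, h2 = sim$h2, residSd = sim$residSd),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
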