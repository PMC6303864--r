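test_that("csv genotypes parse, validate and reject bad coding", {
  m <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("m1", "m2")))
  f <- writeToyCsv(m, tempfile(fileext = ".csv"))
  g <- readGenotypes(f, "csv")
  expect_s4_class(g, "GenotypeData")
  expect_equal(dim(dosageMatrix(g)), c(3L, 2L))
  expect_equal(unname(dosageMatrix(g)), unname(m) + 0L)
  expect_equal(sampleIds(g), c("s1", "s2", "s3"))

  bad <- m; bad[2, 2] <- 3
  fb <- writeToyCsv(bad, tempfile(fileext = ".csv"))
  expect_error(readGenotypes(fb, "csv"), "s2.*m2")
})

test_that("plink .raw dialect strips allele suffixes and uses IID", {
  lines <- c("FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_T",
             "f1 i1 0 0 1 -9 0 2",
             "f2 i2 0 0 2 -9 1 1")
  f <- tempfile(fileext = ".raw")
  writeLines(lines, f)
  g <- readGenotypes(f, "plink_raw")
  expect_equal(markerIds(g), c("snp1", "snp2"))
  expect_equal(sampleIds(g), c("i1", "i2"))
  expect_equal(unname(dosageMatrix(g)[, "snp1"]), c(0L, 1L))
})

test_that("missing dosages are mean-imputed with a logged count", {
  m <- matrix(c(0, 2, 2, 2, 1, 0, 1, 2), 4, 2,
              dimnames = list(paste0("s", 1:4), c("m1", "m2")))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  df[2, "m1"] <- NA
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  suppressWarnings(
    expect_message(g <- readGenotypes(f, "csv"), "imputed 1 missing"))
  # remaining m1 dosages 0,2,2 -> mean 4/3 -> rounds to 1
  expect_equal(unname(dosageMatrix(g)[2, "m1"]), 1L)

  # one missing out of 4 samples = 25% > 10% threshold
  expect_warning(
    expect_message(readGenotypes(f, "csv"), "imputed"),
    ">10% missing")
})

test_that("maf uses min(f, 1-f) with f = mean(dosage)/2", {
  g <- GenotypeData(matrix(c(0L, 0L, 0L, 2L, 1L, 1L), 3, 2,
                    dimnames = list(paste0("s", 1:3), c("mono", "poly"))))
  expect_equal(unname(maf(g)), c(0, min(4 / 6 / 1, 1 - 4 / 6)))
})

test_that("mafFilter drops rare markers, keeps order, is idempotent", {
  # marker A: 22 carriers among 1000 -> f = 0.011, kept at threshold 0.01
  # marker B: monomorphic -> removed
  n <- 1000L
  A <- c(rep(1L, 22L), rep(0L, n - 22L))
  B <- rep(0L, n)
  C <- sample(0:2, n, replace = TRUE)
  g <- GenotypeData(cbind(A = A, B = B, C = C),
                    sampleIds = paste0("s", seq_len(n)))
  gf <- mafFilter(g, 0.01)
  expect_equal(markerIds(gf), c("A", "C"))
  expect_equal(markerIds(mafFilter(gf, 0.01)), markerIds(gf))  # idempotent
  expect_equal(markerIds(mafFilter(g, 0)), c("A", "B", "C"))   # identity
  expect_error(mafFilter(g, 0.5), "all markers removed")
})

test_that("one-hot encoding maps each dosage to its triple and inverts", {
  g <- GenotypeData(matrix(c(0L, 1L, 2L), 3, 1,
                    dimnames = list(paste0("s", 1:3), "m1")))
  d <- oneHotEncode(g)
  expect_equal(unname(indicators(d)),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  # p markers -> 3p columns; every row sums to p; argmax round-trip
  for (seed in 1:5) {
    gt <- toyGenotypes(n = 7, p = 5, seed = seed)
    dd <- oneHotEncode(gt)
    expect_equal(ncol(indicators(dd)), 3L * 5L)
    expect_true(all(rowSums(indicators(dd)) == 5L))
    expect_equal(oneHotDecode(dd), dosageMatrix(gt))
  }
})

test_that("dosage codes point at the 1-column of each triple", {
  gt <- toyGenotypes(n = 8, p = 6, seed = 3)
  codes <- dosageCodes(gt)
  X <- indicators(oneHotEncode(gt))
  for (i in seq_len(nrow(codes))) {
    hit <- rep(0, ncol(X))
    hit[codes[i, ]] <- 1
    expect_equal(unname(X[i, ]), hit)
  }
})

test_that("k-fold split sizes differ by at most one and seeds reproduce", {
  plan <- makeSplit(paste0("s", 1:3141), k = 5, seed = 11)
  expect_equal(sort(as.integer(table(plan@fold)), decreasing = TRUE),
               c(629L, 628L, 628L, 628L, 628L))
  plan2 <- makeSplit(paste0("s", 1:3141), k = 5, seed = 11)
  expect_identical(plan@fold, plan2@fold)
  expect_equal(length(intersect(trainIds(plan, 1), testIds(plan, 1))), 0L)

  grp <- rep(paste0("gen", 1:5), each = 10)
  hp <- makeSplit(paste0("s", 1:50), groups = grp, testGroups = "gen5")
  expect_equal(testIds(hp), paste0("s", 41:50))
  expect_error(makeSplit(paste0("s", 1:10), testIds = paste0("s", 1:10)),
               "non-empty")
})

test_that("phenotype and split files round-trip and alignment is checked", {
  y <- setNames(rnorm(5), paste0("s", 1:5))
  f <- tempfile(fileext = ".csv")
  writePhenotypes(y, f)
  expect_equal(readPhenotypes(f), y, tolerance = 1e-12)

  g <- toyGenotypes(n = 5, p = 2, seed = 2)
  names(y) <- paste0("s", 1:5)
  expect_equal(names(alignPhenotypes(g, rev(y))), sampleIds(g))
  names(y)[1] <- "other"
  expect_error(alignPhenotypes(g, y), "do not match")

  sp <- makeSplit(paste0("s", 1:10), k = 2, seed = 1)
  fs <- tempfile(fileext = ".csv")
  writeSplit(sp, fs)
  expect_equal(readSplit(fs)@fold, sp@fold)
})
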