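#' Genotype dosage container
#'
#' `GenotypeData` holds an n x p matrix of biallelic SNP dosages coded
#' 0/1/2 (count of the alternate allele), with unique sample and marker
#' identifiers and optional chromosome/position metadata.  It extends
#' [SummarizedExperiment::SummarizedExperiment] with markers as rows and
#' samples as columns (the Bioconductor convention); [dosageMatrix()]
#' returns the samples x markers orientation used by the models.
#'
#' Missing dosages must be resolved before construction; [readGenotypes()]
#' imputes them to the rounded per-marker mean dosage.
#'
#' @param dosages integer-like matrix, samples in rows, markers in columns,
#'   entries in `{0, 1, 2}`.
#' @param sampleIds,markerIds character vectors of unique identifiers;
#'   default to the dimnames of `dosages`.
#' @param chrom,pos optional per-marker chromosome labels and 1-based
#'   integer coordinates (metadata only, never used in computation).
#' @return A `GenotypeData` object.
#' @examples
#' g <- GenotypeData(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                   dimnames = list(c("s1", "s2", "s3"), c("m1", "m2"))))
#' dosageMatrix(g)
#' maf(g)
#' @export
GenotypeData <- function(dosages, sampleIds = rownames(dosages),
                         markerIds = colnames(dosages),
                         chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(dosages)))
  if (is.null(markerIds)) markerIds <- paste0("marker", seq_len(ncol(dosages)))
  if (anyNA(dosages) || !all(dosages == 0L | dosages == 1L | dosages == 2L))
    stop("dosages must all be 0, 1 or 2 (resolve missing values first)")
  storage.mode(dosages) <- "integer"
  m <- t(dosages)
  dimnames(m) <- list(as.character(markerIds), as.character(sampleIds))
  rd <- S4Vectors::DataFrame(
    chrom = if (is.null(chrom)) rep(NA_character_, nrow(m)) else as.character(chrom),
    pos = if (is.null(pos)) rep(NA_integer_, nrow(m)) else as.integer(pos)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = m), rowData = rd
  )
  methods::new("GenotypeData", se)
}

#' @rdname GenotypeData
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is missing")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (nrow(d) < 1L || ncol(d) < 1L)
    return("need at least one marker and one sample")
  if (anyNA(d) || min(d) < 0L || max(d) > 2L)
    return("dosages must all be 0, 1 or 2 (resolve missing values first)")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    return("marker ids must be present and unique")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    return("sample ids must be present and unique")
  TRUE
})

#' @describeIn GenotypeData samples x markers dosage matrix.
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @describeIn GenotypeData marker identifiers.
#' @export
setMethod("markerIds", "GenotypeData", function(x) rownames(x))

#' @describeIn GenotypeData sample identifiers.
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' @describeIn GenotypeData per-marker minor allele frequency
#'   `min(f, 1 - f)` with `f = mean(dosage) / 2`.
#' @export
setMethod("maf", "GenotypeData", function(x) {
  f <- rowMeans(SummarizedExperiment::assay(x, "dosage")) / 2
  stats::setNames(pmin(f, 1 - f), rownames(x))
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "samples x", nrow(object), "markers\n")
  m <- maf(object)
  cat(sprintf("  MAF range %.3f-%.3f, %d monomorphic\n",
              min(m), max(m), sum(m == 0)))
})

#' Remove markers below a minor-allele-frequency threshold
#'
#' MAF is computed as `min(f, 1 - f)` with `f = mean(dosage) / 2`; markers
#' with MAF strictly below `threshold` are dropped, preserving marker order.
#' The operation is idempotent.
#'
#' @param x a [GenotypeData] object.
#' @param threshold MAF cutoff in `[0, 0.5]` (default 0.01, the usual
#'   pre-analysis screen for genome-wide SNP panels).
#' @return A filtered `GenotypeData`.
#' @export
setMethod("mafFilter", "GenotypeData", function(x, threshold = 0.01) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 0.5)
  keep <- maf(x) >= threshold
  if (!any(keep)) stop("mafFilter: all markers removed at threshold ", threshold)
  x[keep, ]
})

#' Read a genotype matrix from disk
#'
#' Two dialects are supported: `"csv"` (header row of marker ids, first
#' column the sample id, one dosage column per marker) and `"plink_raw"`
#' (whitespace-delimited PLINK `--recode A` layout: columns FID IID PAT MAT
#' SEX PHENOTYPE then one allele-suffixed dosage column per marker, e.g.
#' `snp1_A`; the suffix is stripped and IID is used as the sample id).
#'
#' Missing dosages (the `missing` token or empty fields) are imputed to the
#' rounded per-marker mean dosage and the number of imputations is reported
#' via `message()`.  Markers with more than 10\% missing values trigger a
#' warning.  Any value other than 0/1/2/missing is an error naming the
#' offending cell.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @param missing token(s) treated as missing (default `"NA"`).
#' @return A [GenotypeData] object.
#' @export
readGenotypes <- function(path, dialect = c("csv", "plink_raw"),
                          missing = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else " "
  dt <- tryCatch(
    data.table::fread(path, sep = if (dialect == "csv") "," else "auto",
                      header = TRUE, na.strings = missing,
                      colClasses = list(character = 1L), data.table = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (dialect == "plink_raw") {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(dt)[seq_len(6)]))
      stop("plink_raw header must start with: ", paste(need, collapse = " "))
    ids <- as.character(dt[["IID"]])
    geno <- dt[, -(1:6), drop = FALSE]
    names(geno) <- sub("_[ACGT0-9]+$", "", names(geno))
  } else {
    ids <- as.character(dt[[1L]])
    geno <- dt[, -1L, drop = FALSE]
  }
  if (ncol(geno) < 1L) stop("no marker columns found in ", path)
  m <- as.matrix(geno)
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-biallelic dosage coding: value '%s' at sample '%s', marker '%s'",
      m[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
      colnames(m)[bad[1L, 2L]]
    ))
  }
  nmiss <- colSums(is.na(m))
  highmiss <- nmiss / nrow(m) > 0.1
  if (any(highmiss)) {
    warning(sum(highmiss), " marker(s) with >10% missing dosages: ",
            paste(head(colnames(m)[highmiss], 5L), collapse = ", "))
  }
  if (sum(nmiss) > 0L) {
    for (j in which(nmiss > 0L)) {
      fill <- round(mean(m[, j], na.rm = TRUE))
      m[is.na(m[, j]), j] <- fill
    }
    message("imputed ", sum(nmiss),
            " missing dosage(s) to rounded per-marker mean")
  }
  GenotypeData(m, sampleIds = ids, markerIds = colnames(m))
}

#' Read or write a phenotype vector
#'
#' Phenotypes are stored as a 2-column CSV (`sample_id,value`) and
#' represented in R as a named numeric vector.
#'
#' @param path file path.
#' @return `readPhenotypes()`: named numeric vector of finite trait values.
#' @export
readPhenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  y <- as.numeric(dt[[2L]])
  names(y) <- as.character(dt[[1L]])
  if (anyNA(y) || any(!is.finite(y))) stop("phenotypes must be finite")
  if (anyDuplicated(names(y))) stop("duplicated sample ids in ", path)
  y
}

#' @rdname readPhenotypes
#' @param y named numeric vector.
#' @export
writePhenotypes <- function(y, path) {
  data.table::fwrite(data.frame(sample_id = names(y), value = unname(y)), path)
  invisible(path)
}

#' @rdname readGenotypes
#' @param x a [GenotypeData] object.
#' @export
writeGenotypes <- function(x, path) {
  d <- dosageMatrix(x)
  out <- data.frame(sample_id = rownames(d), check.names = FALSE)
  out <- cbind(out, as.data.frame(d, check.names = FALSE))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Align a phenotype vector with a genotype matrix
#'
#' Checks (never assumes) that the two share identical sample sets and
#' returns `y` reordered to the genotype sample order.
#'
#' @param x a [GenotypeData] object.
#' @param y named numeric phenotype vector.
#' @return Named numeric vector ordered like `sampleIds(x)`.
#' @export
alignPhenotypes <- function(x, y) {
  ids <- sampleIds(x)
  if (!setequal(ids, names(y)))
    stop("phenotype sample ids do not match genotype sample ids")
  y[ids]
}
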