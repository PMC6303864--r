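#' Fitted MC-dropout network on genotype data
#'
#' End-to-end convenience wrapper: one-hot encodes (or dose-codes) the
#' genotypes, splits samples per the plan, runs the sampling chain and
#' summarizes it.  The result carries everything needed for effect
#' extraction and reporting.
#'
#' @slot chain the [AbnnChain-class].
#' @slot summary the [AbnnSummary-class].
#' @slot tripleMap marker-to-column map (one-hot encoding only).
#' @slot markerMeta data.frame of marker_id, chrom, pos.
#' @slot arch the [netArchitecture()] used.
#' @slot encoding `"onehot"` or `"dosage"`.
#' @slot ytest named test phenotypes.
#' @export
setClass("AbnnFit",
  representation(chain = "AbnnChain", summary = "AbnnSummary",
                 tripleMap = "data.frame", markerMeta = "data.frame",
                 arch = "list", encoding = "character", ytest = "numeric"))

setMethod("show", "AbnnFit", function(object) {
  cat("AbnnFit (", object@encoding, " encoding, widths ",
      paste(object@arch$layerWidths, collapse = "-"), ", ",
      object@arch$activation, ")\n", sep = "")
  show(object@summary)
})

#' Fit the approximate Bayesian network to genotype/phenotype data
#'
#' @param genotypes a [GenotypeData] object.
#' @param phenotypes named numeric vector covering all samples.
#' @param split a [SplitPlan]; for k-fold plans give `fold`.
#' @param fold test fold for k-fold plans.
#' @param arch a [netArchitecture()].
#' @param config a [trainConfig()].
#' @param encoding `"onehot"` (indicator triples; required for effect
#'   extraction) or `"dosage"` (raw 0/1/2 columns).
#' @param iterations,burnIn chain length and burn-in.
#' @param keepSnapshots forwarded to [runChain()].
#' @param seed integer seed controlling initialization and the chain.
#' @return An [AbnnFit-class] object.
#' @export
abnnFit <- function(genotypes, phenotypes, split, fold = NULL,
                    arch = netArchitecture(1L, "linear"),
                    config = trainConfig(), encoding = c("onehot", "dosage"),
                    iterations = 2000L, burnIn = 500L,
                    keepSnapshots = FALSE, seed = 1L) {
  encoding <- match.arg(encoding)
  phenotypes <- alignPhenotypes(genotypes, phenotypes)
  tr <- trainIds(split, fold)
  te <- testIds(split, fold)
  stopifnot(all(c(tr, te) %in% sampleIds(genotypes)))
  set.seed(as.integer(seed))
  if (encoding == "onehot") {
    codes <- dosageCodes(genotypes)
    tm <- oneHotTripleMap(markerIds(genotypes))
    params <- initParams(arch, 3L * ncol(codes))
    chain <- runChain(NULL, phenotypes[tr], NULL, phenotypes[te],
                      params, config = config, iterations = iterations,
                      burnIn = burnIn, keepSnapshots = keepSnapshots,
                      trainCodes = codes[tr, , drop = FALSE],
                      testCodes = codes[te, , drop = FALSE])
  } else {
    X <- dosageMatrix(genotypes)
    tm <- data.frame()
    params <- initParams(arch, ncol(X))
    chain <- runChain(X[tr, , drop = FALSE], phenotypes[tr],
                      X[te, , drop = FALSE], phenotypes[te],
                      params, config = config, iterations = iterations,
                      burnIn = burnIn, keepSnapshots = keepSnapshots)
  }
  meta <- data.frame(marker_id = markerIds(genotypes),
                     chrom = as.character(SummarizedExperiment::rowData(genotypes)$chrom),
                     pos = as.integer(SummarizedExperiment::rowData(genotypes)$pos),
                     stringsAsFactors = FALSE)
  methods::new("AbnnFit", chain = chain, summary = summarizeChain(chain),
               tripleMap = tm, markerMeta = meta, arch = unclass(arch),
               encoding = encoding, ytest = phenotypes[te])
}
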