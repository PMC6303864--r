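#' Additive and dominance SNP effects from posterior input weights
#'
#' For the one-layer, one-unit, linear network on a one-hot design the
#' posterior mean input weights are interpretable as genotype-class
#' regression coefficients.  The additive effect of marker j contrasts its
#' two homozygote columns,
#' `a_j = -E[W1, Hom0_j] + E[W1, Hom2_j]`,
#' and the dominance effect is the heterozygote column weight,
#' `d_j = E[W1, Het1_j]`.
#'
#' These are regularized estimates: weight decay and dropout shrink the
#' fitted weights, and no un-shrinking is applied, so effect sizes are
#' useful for ranking and locus discovery rather than as unbiased effect
#' estimates (see the methods vignette for the size of the dropout
#' shrinkage).
#'
#' @param meanW1 numeric vector (or one-column matrix) of posterior mean
#'   input weights of a k = 1 one-hot network.
#' @param tripleMap marker-to-column map from [oneHotEncode()].
#' @return Named numeric vector of per-marker effects.
#' @export
additiveEffects <- function(meanW1, tripleMap) {
  w <- as.numeric(meanW1)
  if (max(tripleMap$hom2) > length(w))
    stop("tripleMap inconsistent with weight vector length")
  stats::setNames(-w[tripleMap$hom0] + w[tripleMap$hom2], tripleMap$marker_id)
}

#' @rdname additiveEffects
#' @export
dominanceEffects <- function(meanW1, tripleMap) {
  w <- as.numeric(meanW1)
  if (max(tripleMap$hom2) > length(w))
    stop("tripleMap inconsistent with weight vector length")
  stats::setNames(w[tripleMap$het1], tripleMap$marker_id)
}

#' @describeIn additiveEffects full per-marker effect table from a fitted
#'   model: additive and dominance effects with their posterior variances
#'   (sums of the relevant weight variances) and ranks by `|a|` and `|d|`.
#'   Only defined for the one-layer, one-unit, linear, one-hot model;
#'   weights of deeper or nonlinear networks are not interpretable as
#'   per-genotype regression coefficients and raise an error.
#' @param x an [AbnnFit-class] object.
#' @param ... unused.
#' @export
setMethod("effectTable", "AbnnFit", function(x, ...) {
  if (x@encoding != "onehot")
    stop("effect extraction requires one-hot encoding")
  if (length(x@arch$layerWidths) != 1L || x@arch$layerWidths[1L] != 1L ||
      x@arch$activation != "linear")
    stop("effect extraction is defined only for the one-layer, one-unit, ",
         "linear model; weights of deeper or nonlinear networks are not ",
         "interpretable as genotype effects")
  tm <- x@tripleMap
  mw <- as.numeric(x@summary@meanParams$W[[1L]])
  vw <- as.numeric(x@summary@varParams$W[[1L]])
  a <- -mw[tm$hom0] + mw[tm$hom2]
  d <- mw[tm$het1]
  tbl <- data.frame(
    marker_id = tm$marker_id,
    chrom = x@markerMeta$chrom[match(tm$marker_id, x@markerMeta$marker_id)],
    pos = x@markerMeta$pos[match(tm$marker_id, x@markerMeta$marker_id)],
    a = a, d = d,
    var_a = vw[tm$hom0] + vw[tm$hom2],
    var_d = vw[tm$het1],
    stringsAsFactors = FALSE
  )
  tbl$rank_a <- rank(-abs(tbl$a), ties.method = "first")
  tbl$rank_d <- rank(-abs(tbl$d), ties.method = "first")
  tbl
})

#' Rank an effect table
#'
#' Rows sorted by `|effect|` descending; ties keep the original marker
#' order, so the ranking is deterministic.
#'
#' @param table effect table from [effectTable()].
#' @param by `"a"` or `"d"`.
#' @param topK number of rows to return (>= the table size gives the full
#'   ranking).
#' @return The ranked subset of `table`.
#' @export
rankEffects <- function(table, by = c("a", "d"), topK = nrow(table)) {
  by <- match.arg(by)
  if (topK <= 0L) stop("topK must be positive")
  ord <- order(-abs(table[[by]]), seq_len(nrow(table)))
  table[ord[seq_len(min(topK, nrow(table)))], , drop = FALSE]
}

#' Write an effect table as TSV
#'
#' Columns marker_id, chrom, pos, a, d, var_a, var_d -- compatible with
#' standard Manhattan-plot tooling.
#'
#' @param table effect table from [effectTable()].
#' @param path output path.
#' @export
writeEffects <- function(table, path) {
  cols <- c("marker_id", "chrom", "pos", "a", "d", "var_a", "var_d")
  data.table::fwrite(table[, cols], path, sep = "\t")
  invisible(path)
}
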