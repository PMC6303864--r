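#' One-hot design matrix for genotype dosages
#'
#' Each marker is expanded into three indicator columns in the fixed order
#' (Hom0, Het1, Hom2): a dosage g maps to exactly one 1 in its triple
#' (Hom0 if g = 0, Het1 if g = 1, Hom2 if g = 2).  This encoding lets a
#' linear network model additive and dominance action at each locus; the
#' column roles anchor the effect formulas in [additiveEffects()] and
#' [dominanceEffects()].
#'
#' @slot indicators numeric n x 3p matrix of 0/1 indicators, samples in rows.
#' @slot tripleMap data.frame with one row per marker: `marker_id` and the
#'   column indices `hom0`, `het1`, `hom2` of its triple.
#' @slot sampleIds character vector of row identifiers.
#' @export
setClass("OneHotDesign",
  representation(indicators = "matrix", tripleMap = "data.frame",
                 sampleIds = "character"))

setValidity("OneHotDesign", function(object) {
  X <- object@indicators
  tm <- object@tripleMap
  if (ncol(X) != 3L * nrow(tm))
    return("column count must equal 3 x marker count")
  if (!all(X == 0 | X == 1)) return("indicators must be 0/1")
  rs <- rowSums(X)
  if (any(rs != nrow(tm)))
    return("each row must have exactly one 1 per marker triple")
  if (length(object@sampleIds) != nrow(X))
    return("sampleIds length must match row count")
  TRUE
})

#' @describeIn OneHotDesign expand a [GenotypeData] dosage matrix into
#'   indicator triples.
#' @param x a [GenotypeData] object.
#' @param ... unused.
#' @export
setMethod("oneHotEncode", "GenotypeData", function(x, ...) {
  G <- dosageMatrix(x)
  n <- nrow(G); p <- ncol(G)
  X <- matrix(0, n, 3L * p)
  for (g in 0:2) {
    idx <- which(G == g)                # column-major positions in G
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    X[cbind(i, 3L * (j - 1L) + g + 1L)] <- 1
  }
  tm <- data.frame(marker_id = colnames(G),
                   hom0 = 3L * (seq_len(p) - 1L) + 1L,
                   het1 = 3L * (seq_len(p) - 1L) + 2L,
                   hom2 = 3L * seq_len(p),
                   stringsAsFactors = FALSE)
  colnames(X) <- as.vector(t(outer(colnames(G), c("Hom0", "Het1", "Hom2"),
                                   paste, sep = ".")))
  rownames(X) <- rownames(G)
  methods::new("OneHotDesign", indicators = X, tripleMap = tm,
               sampleIds = rownames(G))
})

#' @describeIn OneHotDesign the indicator matrix.
#' @export
setMethod("indicators", "OneHotDesign", function(x) x@indicators)

#' @describeIn OneHotDesign the marker-to-column-triple map.
#' @export
setMethod("tripleMap", "OneHotDesign", function(x) x@tripleMap)

setMethod("show", "OneHotDesign", function(object) {
  cat("OneHotDesign:", nrow(object@indicators), "samples x",
      nrow(object@tripleMap), "markers (", ncol(object@indicators),
      "indicator columns )\n")
})

#' Recover the dosage matrix from a one-hot design
#'
#' Takes the argmax over each marker triple; exact inverse of
#' [oneHotEncode()].
#'
#' @param design a [OneHotDesign] object.
#' @return Integer samples x markers dosage matrix.
#' @export
oneHotDecode <- function(design) {
  X <- indicators(design)
  tm <- tripleMap(design)
  G <- sapply(seq_len(nrow(tm)), function(j) {
    cols <- c(tm$hom0[j], tm$het1[j], tm$hom2[j])
    max.col(X[, cols, drop = FALSE], ties.method = "first") - 1L
  })
  G <- matrix(as.integer(G), nrow = nrow(X),
              dimnames = list(design@sampleIds, tm$marker_id))
  G
}

#' One-hot column codes for a dosage matrix
#'
#' `dosageCodes()` returns the samples x markers matrix of 1-based one-hot
#' column indices (`3*(j-1) + g + 1` for dosage g at marker j): the
#' position of the single 1 in each marker triple of [oneHotEncode()].
#' This compact form lets the training chain evaluate the one-hot input
#' layer by table lookup; [runChain()] accepts it via
#' `trainCodes`/`testCodes`.  `oneHotTripleMap()` builds the matching
#' marker-to-column map without materializing the indicator matrix.
#'
#' @param x a [GenotypeData] object.
#' @return Integer matrix with the genotype dimnames.
#' @export
dosageCodes <- function(x) {
  G <- dosageMatrix(x)
  codes <- sweep(G + 1L, 2L, 3L * (seq_len(ncol(G)) - 1L), `+`)
  storage.mode(codes) <- "integer"
  codes
}

#' @rdname dosageCodes
#' @param markerIds character vector of marker identifiers.
#' @export
oneHotTripleMap <- function(markerIds) {
  p <- length(markerIds)
  data.frame(marker_id = as.character(markerIds),
             hom0 = 3L * (seq_len(p) - 1L) + 1L,
             het1 = 3L * (seq_len(p) - 1L) + 2L,
             hom2 = 3L * seq_len(p),
             stringsAsFactors = FALSE)
}
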