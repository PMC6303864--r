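#' Genomic relationship (kinship) matrix
#'
#' VanRaden form: `K = Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z` the
#' allele-frequency-centered dosage matrix (`z_ij = g_ij - 2 p_j`).
#' Symmetric, positive semi-definite up to rounding, with mean diagonal
#' near 1 under Hardy-Weinberg equilibrium.
#'
#' @param x a [GenotypeData] with at least two polymorphic markers.
#' @return n x n numeric matrix with sample-id dimnames.
#' @export
genomicRelationship <- function(x) {
  G <- dosageMatrix(x)
  pj <- colMeans(G) / 2
  poly <- pj > 0 & pj < 1
  if (sum(poly) < 2L) stop("need at least two polymorphic markers")
  Z <- sweep(G[, poly, drop = FALSE], 2L, 2 * pj[poly])
  K <- tcrossprod(Z) / (2 * sum(pj[poly] * (1 - pj[poly])))
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' GBLUP prediction by kernel ridge regression
#'
#' Closed-form best linear unbiased prediction with a genomic relationship
#' kernel:
#' `yhat_test = K[test, train] (K[train, train] + delta I)^{-1} (y - mean) + mean`.
#' The shrinkage `delta` (the residual-to-genetic variance ratio) is chosen
#' by inner 5-fold cross-validation over a grid.  Centering makes the
#' predictions invariant to adding a constant to the phenotypes.  This is
#' a deterministic stand-in for MCMC-based Bayesian GBLUP: it gives the
#' same family of shrinkage predictions without sampling.
#'
#' @param K kinship matrix covering all samples (from
#'   [genomicRelationship()]).
#' @param y named training phenotypes (names must index rows of `K`).
#' @param trainIds,testIds sample ids.
#' @param deltaGrid candidate shrinkage values (default log-spaced
#'   `10^(-2..3)`).
#' @param innerFolds folds of the inner CV.
#' @param seed seed for the inner fold assignment.
#' @return List with `predictions` (named numeric for `testIds`), `delta`
#'   (chosen shrinkage) and `cvMse` (inner CV MSE per grid point).
#' @export
gblupFitPredict <- function(K, y, trainIds, testIds,
                            deltaGrid = 10^seq(-2, 3, by = 0.5),
                            innerFolds = 5L, seed = 1L) {
  stopifnot(all(trainIds %in% rownames(K)), all(testIds %in% rownames(K)),
            all(trainIds %in% names(y)))
  ytr <- y[trainIds]
  ridge_pred <- function(Ktt, Kpt, yv, delta) {
    # Ktt: train kernel; Kpt: predictee x train kernel
    mu <- mean(yv)
    sol <- tryCatch(solve(Ktt + diag(delta, nrow(Ktt)), yv - mu),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    as.numeric(Kpt %*% sol) + mu
  }
  cvMse <- rep(NA_real_, length(deltaGrid))
  if (length(deltaGrid) > 1L) {
    set.seed(as.integer(seed))
    fold <- sample(rep(seq_len(innerFolds), length.out = length(trainIds)))
    for (d in seq_along(deltaGrid)) {
      errs <- c()
      ok <- TRUE
      for (f in seq_len(innerFolds)) {
        tr <- trainIds[fold != f]; ho <- trainIds[fold == f]
        pr <- ridge_pred(K[tr, tr], K[ho, tr, drop = FALSE], y[tr],
                         deltaGrid[d])
        if (is.null(pr)) { ok <- FALSE; break }
        errs <- c(errs, (pr - y[ho])^2)
      }
      if (ok) cvMse[d] <- mean(errs)
    }
    if (all(is.na(cvMse))) stop("all grid points failed (singular systems)")
    delta <- deltaGrid[which.min(cvMse)]
  } else {
    delta <- deltaGrid
  }
  pred <- ridge_pred(K[trainIds, trainIds],
                     K[testIds, trainIds, drop = FALSE], ytr, delta)
  if (is.null(pred)) stop("singular system at the chosen shrinkage")
  names(pred) <- testIds
  list(predictions = pred, delta = delta, cvMse = cvMse)
}
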