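#' Monte-Carlo dropout chain
#'
#' One chain iteration t samples fresh dropout masks, runs one optimization
#' pass over the training data continuing from the current parameters, and
#' records the thinned model `omega^t` (masked, 1/p-scaled weights plus
#' biases), its test predictions, and the test MSE/MAE.  Posterior moments
#' of `omega` are accumulated over the iterations after burn-in with
#' `1/(T - t_s)` normalization.
#'
#' @slot mse,mae numeric traces of length T (test MSE/MAE per iteration).
#' @slot predictions T x ntest matrix of per-iteration test predictions.
#' @slot burnIn number of initial iterations excluded from moments.
#' @slot meanW,varW,meanB,varB per-layer posterior moments of `omega`.
#' @slot finalParams the unmasked parameters after the last iteration.
#' @slot snapshots optional list of per-iteration `omega` snapshots.
#' @slot optState ADAM moment state at the end of the run (for exact
#'   chain continuation).
#' @slot testIds character ids of the test samples.
#' @slot config echo of the run configuration.
#' @slot diverged TRUE if the run was aborted on nonfinite values (the
#'   trace up to the abort is retained).
#' @export
setClass("AbnnChain",
  representation(mse = "numeric", mae = "numeric", predictions = "matrix",
                 burnIn = "integer", meanW = "list", varW = "list",
                 meanB = "list", varB = "list", finalParams = "NetParams",
                 snapshots = "list", optState = "list",
                 testIds = "character", config = "list",
                 diverged = "logical"))

setMethod("show", "AbnnChain", function(object) {
  T <- length(object@mse)
  cat("AbnnChain:", T, "iterations, burn-in", object@burnIn, "\n")
  if (any(is.finite(object@mse))) {
    keep <- object@mse[seq.int(object@burnIn + 1L, T)]
    cat(sprintf("  model-averaged test MSE %.4f (SD %.4f)\n",
                mean(keep), sd(keep) * sqrt((length(keep) - 1) / length(keep))))
  }
  if (object@diverged) cat("  [diverged before completing all iterations]\n")
})

#' @describeIn AbnnChain per-iteration test MSE trace.
#' @param x an `AbnnChain`.
#' @export
setMethod("mseTrace", "AbnnChain", function(x) x@mse)

#' @describeIn AbnnChain per-iteration test MAE trace.
#' @export
setMethod("maeTrace", "AbnnChain", function(x) x@mae)

#' @describeIn AbnnChain burn-in length used for the stored moments.
#' @export
setMethod("burnIn", "AbnnChain", function(x) x@burnIn)

#' Per-iteration test mean squared error
#'
#' `(1/ntest) * sum((yhat - ytest)^2)` -- the plain MSE, without the 1/2
#' factor of the training loss.
#'
#' @param yhat,y numeric vectors of equal length.
#' @return Scalar MSE.
#' @export
mseT <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  mean((yhat - y)^2)
}

#' Run the MC-dropout sampling chain
#'
#' @param Xtrain,ytrain training design matrix and response.
#' @param Xtest,ytest test design matrix and response (may be `NULL` for
#'   training-only runs; the MSE/MAE traces are then `NA`).
#' @param params starting [NetParams] (use [initParams()]); passing the
#'   `finalParams` of a previous chain continues it.
#' @param config a [trainConfig()].
#' @param iterations chain length T.
#' @param burnIn iterations discarded before computing moments (`t_s`).
#'   The reference protocol at full data scale is 6000 iterations with the
#'   first 1000 discarded; desk-scale defaults are smaller.
#' @param keepSnapshots store every per-iteration `omega` (memory-heavy;
#'   meant for diagnostics and small runs).
#' @param seed optional integer seed; all mask, shuffle and batch
#'   randomness flows from R's RNG, so equal seeds give bitwise-identical
#'   chains.
#' @param optimizerState ADAM moment state from a previous chain's
#'   `optState` slot; together with `finalParams` (and the session RNG
#'   stream) this makes a continued chain reproduce an unbroken one
#'   exactly.
#' @param trainCodes,testCodes optional samples x markers integer matrices
#'   of one-hot column indices (1-based, as from [dosageCodes()]).  When
#'   given, the input layer is evaluated by table lookup instead of a
#'   dense product -- the same model, computed faster -- and the `X`
#'   design matrices may be `NULL`.
#' @return An [AbnnChain-class] object.
#' @export
runChain <- function(Xtrain, ytrain, Xtest = NULL, ytest = NULL, params,
                     config = trainConfig(), iterations = 2000L,
                     burnIn = 500L, keepSnapshots = FALSE, seed = NULL,
                     trainCodes = NULL, testCodes = NULL,
                     optimizerState = NULL) {
  stopifnot(iterations >= 1L, burnIn >= 0L, burnIn < iterations)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fast <- !is.null(trainCodes)
  if (fast) {
    ctr <- t(trainCodes) - 1L
    cte <- if (is.null(testCodes)) {
      matrix(0L, nrow(ctr), 0L)
    } else t(testCodes) - 1L
    ntrain <- ncol(ctr)
    testIds <- rownames(testCodes)
    if (is.null(testIds)) testIds <- as.character(seq_len(ncol(cte)))
    Xtrain <- matrix(0, 0L, 0L)
    Xtest <- matrix(0, 0L, 0L)
    if (is.null(ytest)) ytest <- numeric(0)
  } else {
    ctr <- matrix(0L, 0L, 0L)
    cte <- matrix(0L, 0L, 0L)
    Xtrain <- as.matrix(Xtrain)
    ntrain <- nrow(Xtrain)
    if (is.null(Xtest)) {
      Xtest <- matrix(0, 0L, ncol(Xtrain))
      ytest <- numeric(0)
    }
    Xtest <- as.matrix(Xtest)
    testIds <- rownames(Xtest)
    if (is.null(testIds)) testIds <- as.character(seq_len(nrow(Xtest)))
  }
  opt <- switch(config$optimizer, gd = 0L, sgd = 1L, minibatch_adam = 2L)
  spi <- if (is.null(config$stepsPerIter)) 0L else as.integer(config$stepsPerIter)
  pen <- config$penalty
  dp <- config$dropout
  res <- cpp_run_chain(Xtrain, as.numeric(ytrain), Xtest, as.numeric(ytest),
                       params@weights, params@biases,
                       actCode(params@activation),
                       dp$p1, dp$p2, dp$jointTriples,
                       pen$lambda1, pen$lambda2, pen$lambda3,
                       config$eta, config$beta1, config$beta2, config$eps,
                       min(config$batchSize, ntrain),
                       as.integer(iterations), as.integer(burnIn), opt,
                       FALSE, isTRUE(keepSnapshots), spi, ctr, cte,
                       if (is.null(optimizerState)) list() else optimizerState)
  if (res$diverged)
    warning("chain diverged at iteration ", res$completed + 1L,
            "; trace retained")
  finalParams <- params
  finalParams@weights <- res$finalW
  finalParams@biases <- lapply(res$finalB, as.numeric)
  preds <- res$predictions
  if (length(preds) > 0L) colnames(preds) <- testIds
  methods::new("AbnnChain",
    mse = as.numeric(res$mse), mae = as.numeric(res$mae),
    predictions = preds, burnIn = as.integer(burnIn),
    meanW = res$meanW, varW = res$varW,
    meanB = lapply(res$meanB, function(v) if (is.null(v)) v else as.numeric(v)),
    varB = lapply(res$varB, function(v) if (is.null(v)) v else as.numeric(v)),
    finalParams = finalParams,
    snapshots = if (isTRUE(keepSnapshots)) res$snapshots else list(),
    optState = res$adam,
    testIds = testIds,
    config = list(train = config, iterations = as.integer(iterations),
                  burnIn = as.integer(burnIn)),
    diverged = isTRUE(res$diverged))
}

#' Posterior summary of a chain
#'
#' Moments over iterations `t_s + 1 .. T`: elementwise mean and variance of
#' the thinned parameters (variance normalized by `1/(T - t_s)`, i.e. the
#' biased sample variance), the model-averaged MSE (mean of the retained
#' per-iteration MSE values) and MAE, their SD over retained iterations,
#' and the mean test prediction per sample.  By Jensen's inequality the
#' model-averaged MSE is always at least the MSE of the averaged
#' prediction.
#'
#' @slot meanParams,varParams lists with per-layer `W` and `b` moments.
#' @slot mseModelAveraged,maeModelAveraged,sdMse scalars.
#' @slot meanPrediction named numeric mean test prediction.
#' @slot burnIn,iterations the window the moments were computed over.
#' @export
setClass("AbnnSummary",
  representation(meanParams = "list", varParams = "list",
                 mseModelAveraged = "numeric", maeModelAveraged = "numeric",
                 sdMse = "numeric", meanPrediction = "numeric",
                 burnIn = "integer", iterations = "integer"))

setMethod("show", "AbnnSummary", function(object) {
  cat("AbnnSummary over iterations", object@burnIn + 1L, "..",
      object@iterations, "\n")
  cat(sprintf("  MSE_M = %.4f (SD %.4f), MAE_M = %.4f\n",
              object@mseModelAveraged, object@sdMse,
              object@maeModelAveraged))
})

#' Summarize an MC-dropout chain
#'
#' @param chain an [AbnnChain-class].
#' @param t_s burn-in; defaults to the chain's own.  Recomputing parameter
#'   moments for a different `t_s` requires the chain to have been run with
#'   `keepSnapshots = TRUE` (traces and predictions are always available).
#' @return An [AbnnSummary-class].
#' @export
summarizeChain <- function(chain, t_s = NULL) {
  T <- length(chain@mse)
  if (is.null(t_s)) t_s <- chain@burnIn
  t_s <- as.integer(t_s)
  if (t_s >= T) stop("t_s must be smaller than the chain length")
  keep <- seq.int(t_s + 1L, T)
  if (t_s == chain@burnIn) {
    meanParams <- list(W = chain@meanW, b = chain@meanB)
    varParams <- list(W = chain@varW, b = chain@varB)
  } else {
    if (length(chain@snapshots) == 0L)
      stop("chain was run without keepSnapshots; cannot recompute moments ",
           "for a different burn-in")
    snaps <- chain@snapshots[keep]
    L <- length(snaps[[1L]]$W)
    mom <- function(get) {
      m <- lapply(seq_len(L), function(l) {
        arr <- lapply(snaps, function(s) get(s, l))
        mu <- Reduce(`+`, arr) / length(arr)
        v <- Reduce(`+`, lapply(arr, function(a) (a - mu)^2)) / length(arr)
        list(mean = mu, var = v)
      })
      list(mean = lapply(m, `[[`, "mean"), var = lapply(m, `[[`, "var"))
    }
    wm <- mom(function(s, l) s$W[[l]])
    bm <- mom(function(s, l) s$b[[l]])
    meanParams <- list(W = wm$mean, b = bm$mean)
    varParams <- list(W = wm$var, b = bm$var)
  }
  mse <- chain@mse[keep]
  mae <- chain@mae[keep]
  meanPred <- if (length(chain@predictions) > 0L)
    colMeans(chain@predictions[keep, , drop = FALSE]) else numeric(0)
  n <- length(mse)
  methods::new("AbnnSummary",
    meanParams = meanParams, varParams = varParams,
    mseModelAveraged = mean(mse), maeModelAveraged = mean(mae),
    sdMse = if (n > 1L) sd(mse) * sqrt((n - 1) / n) else 0,
    meanPrediction = meanPred,
    burnIn = t_s, iterations = T)
}

#' Trace table and plot
#'
#' Returns the (t, MSE_t, MAE_t) table for burn-in inspection, optionally
#' writing it as CSV; [plotTrace()] renders the trace.
#'
#' @param chain an [AbnnChain-class].
#' @param file optional CSV path.
#' @return A data.frame with columns `t`, `mse`, `mae` (invisibly when
#'   `file` is given).
#' @export
traceReport <- function(chain, file = NULL) {
  df <- data.frame(t = seq_along(chain@mse), mse = chain@mse,
                   mae = chain@mae)
  if (!is.null(file)) {
    data.table::fwrite(df, file)
    return(invisible(df))
  }
  df
}

#' @rdname traceReport
#' @export
plotTrace <- function(chain) {
  df <- traceReport(chain)
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = mse)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = chain@burnIn, linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = expression(MSE[t])) +
    ggplot2::theme_minimal()
}

#' Advisory plateau detection on an MSE trace
#'
#' Flags the first iteration at which the mean of a trailing window changes
#' by less than `tol` relative to the previous window.  Burn-in choice
#' should still be confirmed visually on the trace plot; this helper is
#' advisory only.
#'
#' @param trace numeric MSE trace.
#' @param window trailing window length.
#' @param tol absolute change tolerance between consecutive window means.
#' @return The first plateau iteration, or `NA` if none found.
#' @export
detectPlateau <- function(trace, window = 50L, tol = 0.01) {
  trace <- trace[is.finite(trace)]
  n <- length(trace)
  if (n < 2L * window) return(NA_integer_)
  for (t in seq.int(2L * window, n)) {
    m1 <- mean(trace[(t - 2L * window + 1L):(t - window)])
    m2 <- mean(trace[(t - window + 1L):t])
    if (abs(m2 - m1) < tol) return(t)
  }
  NA_integer_
}
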