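#' Squared-error loss
#'
#' `(1/(2n)) * sum((y - yhat)^2)` — the Euclidean loss used as the data
#' term of the training objective (note the 1/(2n) normalization, which
#' differs from the plain test-set MSE of [mseT()]).
#'
#' @param y,yhat numeric vectors of equal length.
#' @return Nonnegative scalar, zero iff `y == yhat`.
#' @export
euclideanLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  sum((y - yhat)^2) / (2 * length(y))
}

#' Weight-decay penalty configuration
#'
#' l2 coefficients for the three parameter groups: `lambda1` for the input
#' weights, `lambda2` for deeper weights, `lambda3` for biases.  By default
#' `lambda2 = lambda1` and `lambda3 = 0` (biases unpenalized), since in
#' practice only the input-weight decay is tuned.
#'
#' @param lambda1,lambda2,lambda3 nonnegative reals.
#' @return A list with class `"PenaltyConfig"`.
#' @export
penaltyConfig <- function(lambda1 = 0, lambda2 = lambda1, lambda3 = 0) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "PenaltyConfig")
}

#' Penalized training cost
#'
#' Euclidean loss plus `lambda1*||W_1||^2 + lambda2*||W_deeper||^2 +
#' lambda3*||b||^2` (squared Euclidean norms).  This is the coupled form of
#' the objective; the ADAM training path applies the same penalties as
#' decoupled multiplicative decay instead (see [adamStep()]).
#'
#' @param params a [NetParams] object.
#' @param y,yhat numeric vectors of equal length.
#' @param penalty a [penaltyConfig()].
#' @return Scalar cost.
#' @export
penalizedCost <- function(params, y, yhat, penalty = penaltyConfig()) {
  W <- params@weights
  pen <- penalty$lambda1 * sum(W[[1L]]^2)
  if (length(W) > 1L)
    pen <- pen + penalty$lambda2 * sum(unlist(W[-1L])^2)
  pen <- pen + penalty$lambda3 * sum(unlist(params@biases)^2)
  euclideanLoss(y, yhat) + pen
}

#' Back-propagated gradients
#'
#' Exact gradient of the Euclidean data loss with respect to every weight
#' and bias, computed layer-wise by reverse-mode differentiation.  With
#' masks, the forward graph uses the masked and 1/p-scaled weights, so
#' masked-out weights receive zero gradient.  Penalty gradients are NOT
#' included (decoupled decay is applied in the update); set
#' `coupled = TRUE` to add `2*lambda*theta` per group for the plain-GD
#' ridge path.
#'
#' @inheritParams forwardPass
#' @param y response vector for the batch.
#' @param penalty a [penaltyConfig()]; used only when `coupled = TRUE`.
#' @param coupled include l2 penalty gradients in the returned gradient.
#' @return List with `W` (gradient matrices) and `b` (gradient vectors).
#' @export
backprop <- function(params, X, y, masks = NULL, spec = NULL,
                     penalty = penaltyConfig(), coupled = FALSE) {
  X <- as.matrix(X)
  if (is.null(masks)) {
    masks <- list()
    p1 <- 1; p2 <- 1
  } else {
    stopifnot(!is.null(spec))
    p1 <- spec$p1; p2 <- spec$p2
  }
  g <- cpp_backprop(params@weights, params@biases,
                    actCode(params@activation), X, as.numeric(y), masks,
                    p1, p2, isTRUE(coupled),
                    penalty$lambda1, penalty$lambda2, penalty$lambda3)
  if (any(!vapply(g$W, function(m) all(is.finite(m)), logical(1L))))
    stop("nonfinite activations/gradients encountered")
  list(W = g$W, b = lapply(g$b, as.numeric))
}

#' Plain gradient-descent step
#'
#' `theta <- theta - eta * g`.  Stochastic and mini-batch variants differ
#' only in which rows the gradient was computed on; within an epoch batches
#' are drawn without replacement and reshuffled per epoch (see
#' [runChain()]).
#'
#' @param params a [NetParams] object.
#' @param grads gradient list from [backprop()].
#' @param eta positive learning rate.
#' @return Updated [NetParams].
#' @export
gdStep <- function(params, grads, eta) {
  stopifnot(eta > 0)
  params@weights <- Map(function(W, g) W - eta * g, params@weights, grads$W)
  params@biases <- Map(function(b, g) b - eta * g, params@biases, grads$b)
  methods::validObject(params)
  params
}

#' ADAM optimizer state
#'
#' Moment accumulators shaped like the parameters, a step counter, and the
#' hyper-parameters (defaults `beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`, learning rate `eta = 1e-3`).
#'
#' @param params a [NetParams] object.
#' @param eta learning rate.
#' @param beta1,beta2 exponential decay rates of the first/second moment.
#' @param eps stabilizer added to the square-rooted second moment.
#' @return A list with class `"AdamState"`.
#' @export
adamInit <- function(params, eta = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  zW <- lapply(params@weights, function(W) W * 0)
  zb <- lapply(params@biases, function(b) b * 0)
  structure(list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0L,
                 eta = eta, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "AdamState")
}

#' ADAM step with decoupled weight decay
#'
#' Updates the moving averages of the gradient and squared gradient,
#' bias-corrects them, and applies
#' `theta <- (1 - eta*lambda/b) * theta - eta * mhat / (sqrt(vhat) + eps)`,
#' with the decay coefficient per parameter group taken from the
#' [penaltyConfig()] (`lambda1` input weights, `lambda2` deeper weights,
#' `lambda3` biases).  Errors if `eta*lambda/b >= 1` (sign-flipping decay).
#'
#' @param state an [adamInit()] state.
#' @param params a [NetParams] object.
#' @param grads gradient list from [backprop()].
#' @param penalty a [penaltyConfig()] supplying the decay coefficients.
#' @param batchSize the batch size `b` in the decay factor.
#' @return List with updated `params` and `state`.
#' @export
adamStep <- function(state, params, grads, penalty = penaltyConfig(),
                     batchSize = 1L) {
  out <- cpp_adam_step(params@weights, params@biases, state$mW, state$vW,
                       state$mb, state$vb, state$t, grads$W, grads$b,
                       state$eta, state$beta1, state$beta2, state$eps,
                       penalty$lambda1, penalty$lambda2, penalty$lambda3,
                       as.numeric(batchSize))
  params@weights <- out$W
  params@biases <- lapply(out$b, as.numeric)
  state$mW <- out$mW; state$vW <- out$vW
  state$mb <- out$mb; state$vb <- out$vb
  state$t <- out$t
  list(params = params, state = state)
}

#' Full-batch gradient descent on the coupled (penalized) objective
#'
#' Minimizes the penalized cost of [penalizedCost()] by plain gradient
#' descent with the l2 gradients included (no dropout, no decoupled decay).
#' For a one-layer one-unit linear network this converges to the
#' closed-form ridge solution of the `1/(2n)`-normalized objective, i.e.
#' `(X'X + 2*n*lambda1*I)^{-1} X'y` when fitted without intercept -- the
#' `2n` factor follows from the loss normalization.
#'
#' @param params starting [NetParams].
#' @param X design matrix.
#' @param y response vector.
#' @param penalty a [penaltyConfig()].
#' @param eta learning rate.
#' @param iterations number of full-batch steps.
#' @return Trained [NetParams].
#' @export
gdTrain <- function(params, X, y, penalty = penaltyConfig(), eta = 0.1,
                    iterations = 10000L) {
  X <- as.matrix(X)
  res <- cpp_run_chain(X, as.numeric(y),
                       matrix(0, 0L, ncol(X)), numeric(0),
                       params@weights, params@biases,
                       actCode(params@activation),
                       1, 1, FALSE,
                       penalty$lambda1, penalty$lambda2, penalty$lambda3,
                       eta, 0.9, 0.999, 1e-8,
                       nrow(X), as.integer(iterations),
                       as.integer(iterations), 0L,
                       TRUE, FALSE, 0L,
                       matrix(0L, 0L, 0L), matrix(0L, 0L, 0L), list())
  params@weights <- res$finalW
  params@biases <- lapply(res$finalB, as.numeric)
  params
}

#' Training configuration for the sampling chain
#'
#' @param optimizer `"minibatch_adam"` (default), `"gd"` or `"sgd"`.
#' @param batchSize mini-batch size (default 128, within the usual 50-250
#'   range for a few thousand training observations).
#' @param eta learning rate (ADAM's conventional 1e-3 default).
#' @param beta1,beta2,eps ADAM hyper-parameters.
#' @param penalty a [penaltyConfig()].
#' @param dropout a [dropoutSpec()].
#' @param stepsPerIter optimizer steps per chain iteration; `NULL` means
#'   one full pass over the training data (the definition of an iteration
#'   used throughout the package).
#' @return A list with class `"TrainConfig"`.
#' @export
trainConfig <- function(optimizer = c("minibatch_adam", "gd", "sgd"),
                        batchSize = 128L, eta = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8,
                        penalty = penaltyConfig(), dropout = dropoutSpec(),
                        stepsPerIter = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(batchSize >= 1L, eta > 0)
  structure(list(optimizer = optimizer, batchSize = as.integer(batchSize),
                 eta = eta, beta1 = beta1, beta2 = beta2, eps = eps,
                 penalty = penalty, dropout = dropout,
                 stepsPerIter = stepsPerIter),
            class = "TrainConfig")
}
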