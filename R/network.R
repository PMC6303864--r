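#' Network architecture
#'
#' An ordered vector of layer widths `k_1..k_L` with `k_L = 1` (scalar
#' regression output) and one activation applied at every layer.  The
#' one-layer one-unit linear network is an affine map, i.e. a standard
#' multiple-regression model.
#'
#' @param layerWidths positive integers ending in 1, e.g. `1`, `c(2, 1)`,
#'   `c(3, 2, 1)`.
#' @param activation `"linear"`, `"tanh"` or `"relu"`.
#' @return A list with class `"NetArchitecture"`.
#' @export
netArchitecture <- function(layerWidths = 1L, activation = "linear") {
  layerWidths <- as.integer(layerWidths)
  if (length(layerWidths) < 1L || any(layerWidths < 1L))
    stop("layer widths must be positive integers")
  if (layerWidths[length(layerWidths)] != 1L)
    stop("final layer width must be 1 (scalar output)")
  activation <- match.arg(activation, c("linear", "tanh", "relu"))
  structure(list(layerWidths = layerWidths, activation = activation),
            class = "NetArchitecture")
}

actCode <- function(kind) {
  switch(kind, linear = 0L, tanh = 1L, relu = 2L,
         stop("unknown activation: ", kind))
}

#' Activation functions and their derivatives
#'
#' `linear` is the identity; `tanh(x) = 2/(1 + exp(-2x)) - 1` with range
#' (-1, 1); `relu(x) = max(0, x)`.  Derivatives: 1, `1 - tanh(x)^2`, and
#' the indicator `x > 0`.
#'
#' @param x numeric vector of finite values.
#' @param kind `"linear"`, `"tanh"` or `"relu"`.
#' @return Numeric vector of the same length.
#' @examples
#' activationEval(1, "tanh")   # 2/(1 + exp(-2)) - 1
#' activationEval(-3, "relu")  # 0
#' @export
activationEval <- function(x, kind) {
  stopifnot(all(is.finite(x)))
  switch(kind,
         linear = x,
         tanh = 2 / (1 + exp(-2 * x)) - 1,
         relu = pmax(0, x),
         stop("unknown activation: ", kind))
}

#' @rdname activationEval
#' @export
activationGrad <- function(x, kind) {
  stopifnot(all(is.finite(x)))
  switch(kind,
         linear = rep(1, length(x)),
         tanh = 1 - activationEval(x, "tanh")^2,
         relu = as.numeric(x > 0),
         stop("unknown activation: ", kind))
}

#' Dropout specification
#'
#' Retention probabilities for the two dropout sites: `p1` for the input
#' weights and `p2` for each hidden-layer output.  `p = 1` disables dropout
#' at that site.  With one-hot input, `jointTriples = TRUE` drops the three
#' indicator columns of a SNP jointly; the default masks indicator columns
#' independently.
#'
#' @param p1,p2 retention probabilities in (0, 1]; 0.5 at both sites is
#'   the standard Monte-Carlo-dropout choice and the package default.
#' @param jointTriples logical; mask SNP triples jointly.
#' @return A list with class `"DropoutSpec"`.
#' @export
dropoutSpec <- function(p1 = 0.5, p2 = 0.5, jointTriples = FALSE) {
  stopifnot(p1 > 0, p1 <= 1, p2 > 0, p2 <= 1)
  structure(list(p1 = p1, p2 = p2, jointTriples = isTRUE(jointTriples)),
            class = "DropoutSpec")
}

#' Network parameters
#'
#' Per layer `l`: a weight matrix `W_l` (fan-in x k_l) and a bias vector of
#' length `k_l`.  Shapes chain from the input dimension to the final scalar
#' output.
#'
#' @slot weights list of weight matrices.
#' @slot biases list of bias vectors.
#' @slot activation activation name applied at every layer.
#' @slot layerWidths integer layer widths.
#' @export
setClass("NetParams",
  representation(weights = "list", biases = "list", activation = "character",
                 layerWidths = "integer"))

setValidity("NetParams", function(object) {
  W <- object@weights; b <- object@biases; k <- object@layerWidths
  if (length(W) != length(k) || length(b) != length(k))
    return("one weight matrix and bias vector per layer required")
  for (l in seq_along(W)) {
    if (ncol(W[[l]]) != k[l]) return(sprintf("layer %d width mismatch", l))
    if (length(b[[l]]) != k[l]) return(sprintf("layer %d bias length mismatch", l))
    if (l > 1L && nrow(W[[l]]) != k[l - 1L])
      return(sprintf("layer %d fan-in mismatch", l))
    if (!all(is.finite(W[[l]])) || !all(is.finite(b[[l]])))
      return("parameters must be finite")
  }
  if (k[length(k)] != 1L) return("final layer width must be 1")
  TRUE
})

setMethod("show", "NetParams", function(object) {
  cat("NetParams:", nrow(object@weights[[1]]), "inputs ->",
      paste(object@layerWidths, collapse = "-"),
      paste0("(", object@activation, ")"), "\n")
})

#' Initialize network parameters
#'
#' Biases start at zero; weights are drawn from a centered uniform
#' distribution with scale `1/sqrt(fan_in)`, seeded for reproducibility.
#'
#' @param arch a [netArchitecture()].
#' @param inputDim number of input columns (3p for one-hot designs).
#' @param seed optional integer seed.
#' @return A [NetParams] object.
#' @export
initParams <- function(arch, inputDim, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- arch$layerWidths
  fan <- c(as.integer(inputDim), k[-length(k)])
  W <- lapply(seq_along(k), function(l) {
    s <- 1 / sqrt(fan[l])
    matrix(runif(fan[l] * k[l], -s, s), fan[l], k[l])
  })
  b <- lapply(k, function(kl) rep(0, kl))
  methods::new("NetParams", weights = W, biases = b,
               activation = arch$activation, layerWidths = k)
}

#' Sample dropout masks
#'
#' One Bernoulli(`p1`) mask over the input dimension plus one
#' Bernoulli(`p2`) mask per hidden-layer output.  Reproducible given the
#' R RNG state; `p = 1` yields an all-ones mask.
#'
#' @param spec a [dropoutSpec()].
#' @param arch a [netArchitecture()].
#' @param inputDim fan-in of the first layer.
#' @return A list of 0/1 mask vectors, one per layer (`NULL` where the
#'   site is undropped); element 1 masks rows of `W_1`, element `l` (> 1)
#'   masks rows of `W_l`.
#' @export
sampleMasks <- function(spec, arch, inputDim) {
  k <- arch$layerWidths
  L <- length(k)
  masks <- vector("list", L)
  if (spec$p1 < 1) {
    if (spec$jointTriples) {
      stopifnot(inputDim %% 3L == 0L)
      z <- rep(as.numeric(runif(inputDim / 3L) < spec$p1), each = 3L)
    } else {
      z <- as.numeric(runif(inputDim) < spec$p1)
    }
    masks[[1L]] <- z
  }
  if (L > 1L && spec$p2 < 1) {
    for (l in 2:L) masks[[l]] <- as.numeric(runif(k[l - 1L]) < spec$p2)
  }
  masks
}

#' Forward pass
#'
#' Computes predictions `sigma(... sigma(X W_1 + b_1) ... W_L + b_L)`.
#' With masks, each masked weight group is multiplied elementwise by its
#' 0/1 vector and rescaled by `1/p` (inverted-dropout scaling), so the
#' masked model is the thinned model used for prediction.  Biases are
#' never masked.
#'
#' @param params a [NetParams] object.
#' @param X design matrix whose column count equals the fan-in of layer 1.
#' @param masks optional mask list from [sampleMasks()].
#' @param spec the [dropoutSpec()] that generated `masks` (for the 1/p
#'   scaling); required when `masks` is given.
#' @return List with `pred` (n predictions) and `activations` (per-layer
#'   outputs, sufficient for back-propagation).
#' @export
forwardPass <- function(params, X, masks = NULL, spec = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(params@weights[[1L]]))
    stop("shape mismatch at layer 1: X has ", ncol(X),
         " columns but W1 expects ", nrow(params@weights[[1L]]))
  if (is.null(masks)) {
    masks <- list()
    p1 <- 1; p2 <- 1
  } else {
    stopifnot(!is.null(spec))
    p1 <- spec$p1; p2 <- spec$p2
  }
  out <- cpp_forward(params@weights, params@biases,
                     actCode(params@activation), X, masks, p1, p2)
  list(pred = as.numeric(out$pred), activations = out$activations,
       preact = out$preact)
}
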