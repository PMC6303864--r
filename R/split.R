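#' Train/test split plans
#'
#' A `SplitPlan` assigns every sample exactly once, either to a train/test
#' role (holdout by explicit test ids or by group label, e.g. generations
#' in a breeding pedigree) or to one of k cross-validation folds with fold
#' sizes differing by at most one.
#'
#' @slot sampleIds character vector of all samples.
#' @slot type `"holdout"` or `"kfold"`.
#' @slot role character `"train"`/`"test"` per sample (holdout only).
#' @slot fold integer fold index per sample (k-fold only).
#' @export
setClass("SplitPlan",
  representation(sampleIds = "character", type = "character",
                 role = "character", fold = "integer"))

setValidity("SplitPlan", function(object) {
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
  if (object@type == "holdout") {
    if (length(object@role) != n) return("role must cover all samples")
    if (!all(object@role %in% c("train", "test")))
      return("roles must be 'train' or 'test'")
    if (!any(object@role == "train") || !any(object@role == "test"))
      return("both train and test must be non-empty")
  } else if (object@type == "kfold") {
    if (length(object@fold) != n) return("fold must cover all samples")
    if (max(object@fold) < 2L) return("need at least 2 folds")
    sz <- table(object@fold)
    if (diff(range(sz)) > 1L) return("fold sizes must differ by at most 1")
  } else {
    return("type must be 'holdout' or 'kfold'")
  }
  TRUE
})

#' Build a split plan
#'
#' Either `k` (seeded k-fold CV), `testIds` (explicit holdout) or
#' `groups` + `testGroups` (holdout by group label) must be given.
#' Deterministic given `seed`.
#'
#' @param sampleIds character vector of samples to assign.
#' @param k number of CV folds; samples are shuffled with `seed` and dealt
#'   into folds whose sizes differ by at most one (the first
#'   `n %% k` folds take the extra sample).
#' @param testIds sample ids held out as the test set.
#' @param groups per-sample group labels (same length as `sampleIds`).
#' @param testGroups labels in `groups` whose samples form the test set.
#' @param seed integer seed for the k-fold shuffle.
#' @return A [SplitPlan].
#' @examples
#' plan <- makeSplit(paste0("s", 1:10), k = 3, seed = 1)
#' table(plan@fold)
#' @export
makeSplit <- function(sampleIds, k = NULL, testIds = NULL, groups = NULL,
                      testGroups = NULL, seed = 1L) {
  sampleIds <- as.character(sampleIds)
  n <- length(sampleIds)
  if (!is.null(k)) {
    stopifnot(k >= 2L, k <= n)
    set.seed(as.integer(seed))
    ord <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- integer(n)
    fold[ord] <- rep(seq_len(k), times = sizes)
    return(methods::new("SplitPlan", sampleIds = sampleIds, type = "kfold",
                        role = character(0), fold = fold))
  }
  if (!is.null(groups)) {
    stopifnot(length(groups) == n, !is.null(testGroups))
    testIds <- sampleIds[groups %in% testGroups]
  }
  if (is.null(testIds)) stop("one of k, testIds or groups must be given")
  role <- ifelse(sampleIds %in% testIds, "test", "train")
  methods::new("SplitPlan", sampleIds = sampleIds, type = "holdout",
               role = role, fold = integer(0))
}

#' @describeIn makeSplit training sample ids (for k-fold, all samples
#'   outside `fold`).
#' @param x a [SplitPlan].
#' @param fold fold index used as the test set (k-fold plans).
#' @export
setMethod("trainIds", "SplitPlan", function(x, fold = NULL) {
  if (x@type == "holdout") return(x@sampleIds[x@role == "train"])
  stopifnot(!is.null(fold))
  x@sampleIds[x@fold != fold]
})

#' @describeIn makeSplit test sample ids.
#' @export
setMethod("testIds", "SplitPlan", function(x, fold = NULL) {
  if (x@type == "holdout") return(x@sampleIds[x@role == "test"])
  stopifnot(!is.null(fold))
  x@sampleIds[x@fold == fold]
})

setMethod("show", "SplitPlan", function(object) {
  if (object@type == "holdout") {
    cat("SplitPlan (holdout):", sum(object@role == "train"), "train /",
        sum(object@role == "test"), "test\n")
  } else {
    cat("SplitPlan (", max(object@fold), "-fold): sizes ",
        paste(table(object@fold), collapse = ", "), "\n", sep = "")
  }
})

#' Read/write a split plan as a 2-column CSV (sample_id, role or fold)
#' @param x a [SplitPlan].
#' @param path file path.
#' @export
writeSplit <- function(x, path) {
  if (x@type == "holdout") {
    df <- data.frame(sample_id = x@sampleIds, role = x@role)
  } else {
    df <- data.frame(sample_id = x@sampleIds, role = x@fold)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  val <- dt[[2L]]
  if (all(val %in% c("train", "test"))) {
    methods::new("SplitPlan", sampleIds = as.character(dt[[1L]]),
                 type = "holdout", role = as.character(val),
                 fold = integer(0))
  } else {
    methods::new("SplitPlan", sampleIds = as.character(dt[[1L]]),
                 type = "kfold", role = character(0),
                 fold = as.integer(val))
  }
}
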