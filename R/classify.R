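#' Random-forest classifier settings
#'
#' Defaults follow standard random-forest practice: 500 trees, floor(sqrt(p))
#' candidate features per split (4 for the 22-feature vector), unlimited tree
#' depth, bootstrap resampling per tree. The seed makes training
#' deterministic and is recorded in the fitted model.
#'
#' @param nTrees number of trees. @param mtry "sqrt" or an integer.
#' @param maxNodes optional maximum number of terminal nodes per tree
#'   (\code{NULL} = unlimited depth).
#' @param seed integer RNG seed used at training time.
#' @return a list of class \code{classifierConfig}.
#' @export
classifierConfig <- function(nTrees = 500L, mtry = "sqrt", maxNodes = NULL,
                             seed = 1L) {
  stopifnot(nTrees >= 1L)
  structure(list(nTrees = as.integer(nTrees), mtry = mtry,
                 maxNodes = maxNodes, seed = as.integer(seed)),
            class = "classifierConfig")
}

.asFeatureMatrix <- function(x) {
  if (is(x, "FeatureSet")) featureMatrix(x)
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  else .err("features must be a FeatureSet, matrix or numeric vector",
            "value_error")
}

#' Train the ensemble of random decision trees
#'
#' Each tree is grown on a bootstrap resample of the training data, choosing
#' at each node the best split among a random subset of features; the fitted
#' forest classifies a feature vector by majority vote.
#'
#' @param x a \code{\link{FeatureSet-class}} (with \code{label} in colData) or
#'   an images x features matrix.
#' @param labels binary factor (ignored if \code{x} is a FeatureSet carrying
#'   labels); the second level is treated as the positive class.
#' @param config a \code{\link{classifierConfig}}.
#' @return a \code{\link{TrainedEnsemble-class}}.
#' @export
trainEnsemble <- function(x, labels = NULL, config = classifierConfig()) {
  if (is(x, "FeatureSet") && is.null(labels))
    labels <- SummarizedExperiment::colData(x)$label
  m <- .asFeatureMatrix(x)
  if (is.null(labels)) .err("training labels are required", "value_error")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    .err("training set contains a single class", "degenerate_training_error")
  if (nlevels(labels) != 2L) .err("binary classification only", "value_error")
  if (any(table(labels) < 2L))
    .err("need at least 2 training examples per class", "degenerate_training_error")
  if (any(!is.finite(m)))
    .err("missing/non-finite feature values in training set", "value_error")
  mtry <- if (identical(config$mtry, "sqrt")) max(1L, floor(sqrt(ncol(m))))
          else as.integer(config$mtry)
  set.seed(config$seed)
  forest <- if (is.null(config$maxNodes))
    randomForest::randomForest(x = m, y = labels, ntree = config$nTrees,
                               mtry = mtry)
  else
    randomForest::randomForest(x = m, y = labels, ntree = config$nTrees,
                               mtry = mtry, maxnodes = config$maxNodes)
  new("TrainedEnsemble", forest = forest, config = unclass(config),
      featureNames = colnames(m), classLevels = levels(labels),
      fingerprint = sprintf("n=%d p=%d classes=%s counts=%s seed=%d",
                            nrow(m), ncol(m),
                            paste(levels(labels), collapse = "/"),
                            paste(table(labels), collapse = "/"),
                            config$seed))
}

setMethod("show", "TrainedEnsemble", function(object) {
  cat(sprintf("TrainedEnsemble: %d trees, mtry %s, positive class '%s'\n  %s\n",
              object@config$nTrees,
              if (identical(object@config$mtry, "sqrt"))
                sprintf("sqrt -> %d", max(1L, floor(sqrt(length(object@featureNames)))))
              else object@config$mtry,
              object@classLevels[2L], object@fingerprint))
})

#' Per-feature importance of a trained ensemble (mean Gini decrease)
#' @param model a TrainedEnsemble.
#' @export
featureImportance <- function(model) {
  imp <- randomForest::importance(model@forest)
  stats::setNames(imp[, 1L], rownames(imp))
}

#' Predict class labels and vote scores
#'
#' The score of an image is the fraction of trees voting for the positive
#' class (second class level); the predicted label is positive when the score
#' is at least 0.5 (majority vote, fixed operating point).
#'
#' @param object a \code{\link{TrainedEnsemble-class}}.
#' @param newdata a FeatureSet, matrix, or single named feature vector.
#' @param ... unused.
#' @return \code{DataFrame} with columns \code{label} and \code{score}.
#' @export
setMethod("predict", "TrainedEnsemble", function(object, newdata, ...) {
  m <- .asFeatureMatrix(newdata)
  if (ncol(m) != length(object@featureNames))
    .err(sprintf("feature vector length %d does not match training length %d",
                 ncol(m), length(object@featureNames)), "dimension_error")
  colnames(m) <- object@featureNames
  votes <- predict(object@forest, m, type = "vote")  # normalized vote fractions
  score <- as.numeric(votes[, object@classLevels[2L]])
  label <- factor(ifelse(score >= 0.5, object@classLevels[2L],
                         object@classLevels[1L]),
                  levels = object@classLevels)
  S4Vectors::DataFrame(label = label, score = score)
})
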