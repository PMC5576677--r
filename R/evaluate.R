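#' Deal muscle entities to cross-validation folds without leakage
#'
#' The grouping unit is the muscle entity (subject, muscle group, side): all
#' views of one physical muscle always land in the same fold, so no image of
#' an entity in the test fold has a sibling in training. Entities are sorted,
#' shuffled with the seed and dealt round-robin within each class label
#' (stratified), so fold sizes differ by at most one entity and every fold
#' holds both classes whenever the class counts permit.
#'
#' @param x a MuscleStudy or FeatureSet whose records carry a \code{label}
#'   column (see \code{\link{filterCohort}}).
#' @param nFolds number of folds (default 5).
#' @param seed shuffle seed.
#' @param grouping "muscle" (the protocol's entity rule) or the stricter
#'   "subject" (all muscles of a subject co-fold).
#' @return a \code{\link{FoldAssignment-class}}.
#' @export
assignFolds <- function(x, nFolds = 5L, seed = 1L,
                        grouping = c("muscle", "subject")) {
  grouping <- match.arg(grouping)
  d <- if (is(x, "FeatureSet")) SummarizedExperiment::colData(x)
       else if (is(x, "MuscleStudy")) records(x)
       else S4Vectors::DataFrame(x)
  if (is.null(d$label))
    .err("records carry no 'label' column; run filterCohort() first",
         "value_error")
  key <- .entityKey(d, grouping)
  ent <- unique(data.frame(entity = key, label = as.character(d$label),
                           stringsAsFactors = FALSE))
  if (anyDuplicated(ent$entity))
    .err("an entity maps to more than one label", "value_error")
  nFolds <- as.integer(nFolds)
  if (nrow(ent) < nFolds)
    .err(sprintf("only %d entities for %d folds", nrow(ent), nFolds),
         "configuration_error")
  ent <- ent[order(ent$entity), ]  # manifest-order invariance
  set.seed(as.integer(seed))
  fold <- integer(nrow(ent))
  offset <- 0L
  for (lv in sort(unique(ent$label))) {
    idx <- which(ent$label == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
    offset <- offset + length(idx)
  }
  tab <- table(factor(fold, levels = seq_len(nFolds)), ent$label)
  if (any(tab == 0L) && all(table(ent$label) >= nFolds))
    warning("a fold lost a class despite sufficient entity counts")
  new("FoldAssignment",
      assignment = S4Vectors::DataFrame(entity = ent$entity, label = ent$label,
                                        fold = fold),
      nFolds = nFolds, seed = as.integer(seed), grouping = grouping)
}

#' @rdname FoldAssignment-class
#' @param x a FoldAssignment
#' @export
setMethod("foldAssignment", "FoldAssignment", function(x) x@assignment)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d entities -> %d folds (grouping=%s, seed=%d)\n",
              nrow(object@assignment), object@nFolds, object@grouping,
              object@seed))
  print(table(fold = object@assignment$fold, label = object@assignment$label))
})

## per-record fold lookup
.recordFolds <- function(d, fa) {
  key <- .entityKey(d, fa@grouping)
  f <- fa@assignment$fold[match(key, fa@assignment$entity)]
  if (anyNA(f)) .err("record entity missing from fold assignment", "value_error")
  f
}

#' Diagnostic metrics from confusion counts
#'
#' Computes accuracy, sensitivity (true positive rate), specificity (true
#' negative rate), positive and negative predictive values, Cohen's kappa
#' (chance-corrected agreement, with expected agreement from the marginal
#' products), and the likelihood ratios LR+ = sens/(1-spec) and
#' LR- = (1-sens)/spec. A perfect specificity yields LR+ = Inf; an empty
#' prediction margin yields an NA predictive value with a warning.
#'
#' @param tp,fp,tn,fn non-negative confusion counts; \code{tp} may also be a
#'   named vector holding all four.
#' @return named numeric of the eight metrics.
#' @export
computeMetrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4L && !is.null(names(tp))) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    .err("confusion counts must be non-negative integers", "value_error")
  n <- sum(counts)
  if (tp + fn == 0 || tn + fp == 0)
    .err("a truth class is empty; sensitivity/specificity undefined",
         "undefined_metric_error")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) { warning("no positive predictions; PPV undefined"); NA_real_ }
         else tp / (tp + fp)
  npv <- if (tn + fn == 0) { warning("no negative predictions; NPV undefined"); NA_real_ }
         else tn / (tn + fn)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) { if (po == 1) 1 else 0 } else (po - pe) / (1 - pe)
  c(accuracy = po, sensitivity = sens, specificity = spec, ppv = ppv,
    npv = npv, kappa = kappa,
    lr_pos = if (spec == 1) Inf else sens / (1 - spec),
    lr_neg = if (spec == 0) { if (sens == 1) 0 else Inf } else (1 - sens) / spec)
}

#' Muscle-grouped N-fold cross-validation with the eight-metric report
#'
#' For each fold, an ensemble is trained on the other folds' images and every
#' test-fold image is predicted; a per-fold metric set is computed from the
#' fold's confusion counts, and the across-fold mean and sample standard
#' deviation are reported (mean of per-fold values, not pooled counts, so
#' e.g. the mean LR+ differs from the LR+ of the mean sens/spec). Training
#' rows are processed in a canonical record order, so results do not depend
#' on manifest ordering.
#'
#' @param features a labelled \code{\link{FeatureSet-class}} (after
#'   \code{\link{filterCohort}}).
#' @param clfConfig a \code{\link{classifierConfig}}; each fold trains with
#'   seed \code{clfConfig$seed + fold}.
#' @param nFolds,seed,grouping passed to \code{\link{assignFolds}}.
#' @param problem id stored in the report.
#' @param verbose log per-fold accuracy.
#' @return a \code{\link{MetricReport-class}}.
#' @export
crossValidate <- function(features, clfConfig = classifierConfig(),
                          nFolds = 5L, seed = 1L,
                          grouping = c("muscle", "subject"),
                          problem = NA_character_, verbose = FALSE) {
  grouping <- match.arg(grouping)
  cd <- SummarizedExperiment::colData(features)
  if (is.null(cd$label))
    .err("FeatureSet carries no labels; run filterCohort() first", "value_error")
  fa <- assignFolds(features, nFolds = nFolds, seed = seed, grouping = grouping)
  ord <- order(.recordKey(cd))  # canonical order: manifest-order invariance
  X <- featureMatrix(features)[ord, , drop = FALSE]
  y <- cd$label[ord]
  d <- cd[ord, , drop = FALSE]
  fold <- .recordFolds(d, fa)
  nFolds <- fa@nFolds
  perFold <- matrix(NA_real_, nFolds, length(METRIC_NAMES),
                    dimnames = list(paste0("fold", seq_len(nFolds)), METRIC_NAMES))
  confusion <- matrix(NA_real_, nFolds, 4L,
                      dimnames = list(rownames(perFold), c("tp", "fp", "tn", "fn")))
  preds <- vector("list", nFolds)
  for (k in seq_len(nFolds))  # fail fast before any training
    if (length(unique(y[fold == k])) < 2L)
      .err(sprintf("fold %d holds a single truth class", k),
           "fold_degeneracy_error")
  for (k in seq_len(nFolds)) {
    test <- which(fold == k)
    train <- which(fold != k)
    cfg <- clfConfig
    cfg$seed <- clfConfig$seed + k
    model <- trainEnsemble(X[train, , drop = FALSE], y[train], cfg)
    p <- predict(model, X[test, , drop = FALSE])
    truth <- y[test]
    tp <- sum(p$label == "positive" & truth == "positive")
    fp <- sum(p$label == "positive" & truth == "negative")
    tn <- sum(p$label == "negative" & truth == "negative")
    fn <- sum(p$label == "negative" & truth == "positive")
    confusion[k, ] <- c(tp, fp, tn, fn)
    perFold[k, ] <- computeMetrics(tp, fp, tn, fn)
    preds[[k]] <- S4Vectors::DataFrame(
      d[test, c("subject_id", "muscle_group", "side", "view_index"),
        drop = FALSE],
      fold = k, truth = truth, score = p$score, label = p$label)
    .msg(verbose, "fold %d: n_test=%d accuracy=%.3f", k, length(test),
         perFold[k, "accuracy"])
  }
  new("MetricReport", perFold = perFold,
      means = apply(perFold, 2L, mean),
      sds = apply(perFold, 2L, stats::sd),
      confusion = confusion, folds = fa,
      predictions = do.call(rbind, preds),
      problem = as.character(problem))
}

#' @rdname MetricReport-class
#' @param x a MetricReport
#' @export
setMethod("metricMeans", "MetricReport", function(x) x@means)

#' @rdname MetricReport-class
#' @export
setMethod("metricSDs", "MetricReport", function(x) x@sds)

#' @rdname MetricReport-class
#' @export
setMethod("perFoldMetrics", "MetricReport", function(x) x@perFold)

#' @rdname MetricReport-class
#' @export
setMethod("confusionCounts", "MetricReport", function(x) x@confusion)

#' @rdname MetricReport-class
#' @export
setMethod("cvPredictions", "MetricReport", function(x) x@predictions)

#' @rdname MetricReport-class
#' @export
setMethod("foldAssignment", "MetricReport", function(x) x@folds)

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport%s: %d-fold cross-validation (grouping=%s)\n",
              if (is.na(object@problem)) "" else
                sprintf(" [problem %s]", object@problem),
              object@folds@nFolds, object@folds@grouping))
  for (m in METRIC_NAMES)
    cat(sprintf("  %-12s %6.3f (%.3f)\n", m, object@means[m], object@sds[m]))
})

#' Serialize a MetricReport to JSON
#' @param x a MetricReport. @param path output path.
#' @export
writeMetricReport <- function(x, path) {
  jsonlite::write_json(list(
    problem = x@problem, n_folds = x@folds@nFolds, grouping = x@folds@grouping,
    cv_seed = x@folds@seed,
    mean = as.list(x@means), sd = as.list(x@sds),
    per_fold = as.data.frame(x@perFold),
    confusion = as.data.frame(x@confusion)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
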