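#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Controlled vocabularies of the acquisition protocol
#'
#' Diagnosis codes, the seven imaged muscle groups, and body sides accepted
#' throughout the package. Diagnoses are normal (N), polymyositis (PM),
#' dermatomyositis (DM) and inclusion body myositis (IBM).
#'
#' @name vocabularies
#' @aliases DIAGNOSES MUSCLE_GROUPS SIDES
NULL

#' @rdname vocabularies
#' @export
DIAGNOSES <- c("N", "PM", "DM", "IBM")

#' @rdname vocabularies
#' @export
MUSCLE_GROUPS <- c("deltoid", "biceps", "flexor_carpi_radialis",
                   "flexor_digitorum_profundus", "rectus_femoris",
                   "tibialis_anterior", "gastrocnemius")

#' @rdname vocabularies
#' @export
SIDES <- c("left", "right")

## columns every study manifest / record table must carry
MANIFEST_COLUMNS <- c("subject_id", "diagnosis", "muscle_group", "side",
                      "view_index", "depth_cm", "image_path", "mask_path")

METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                  "kappa", "lr_pos", "lr_neg")

## classed condition helper so callers can distinguish failure modes
.err <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("myoUS_", class), "myoUS_error")))
}

## row-level validation shared by readManifest() and the MuscleStudy validity
.validateRecords <- function(d) {
  missing_cols <- setdiff(MANIFEST_COLUMNS, colnames(d))
  if (length(missing_cols) > 0L)
    .err(sprintf("manifest is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), "schema_error")
  bad <- which(!(d$diagnosis %in% DIAGNOSES))
  if (length(bad) > 0L)
    .err(sprintf("unknown diagnosis '%s' in row %d (allowed: %s)",
                 d$diagnosis[bad[1L]], bad[1L],
                 paste(DIAGNOSES, collapse = ", ")), "value_error")
  bad <- which(!(d$muscle_group %in% MUSCLE_GROUPS))
  if (length(bad) > 0L)
    .err(sprintf("unknown muscle_group '%s' in row %d",
                 d$muscle_group[bad[1L]], bad[1L]), "value_error")
  bad <- which(!(d$side %in% SIDES))
  if (length(bad) > 0L)
    .err(sprintf("unknown side '%s' in row %d", d$side[bad[1L]], bad[1L]),
         "value_error")
  vi <- as.integer(d$view_index)
  bad <- which(is.na(vi) | vi < 1L | vi > 3L)
  if (length(bad) > 0L)
    .err(sprintf("view_index must be 1..3 (at most three views per muscle); row %d has '%s'",
                 bad[1L], d$view_index[bad[1L]]), "value_error")
  dp <- as.numeric(d$depth_cm)
  bad <- which(!(dp %in% c(4, 6)))
  if (length(bad) > 0L)
    .err(sprintf("depth_cm must be 4 or 6; row %d has '%s'",
                 bad[1L], d$depth_cm[bad[1L]]), "value_error")
  ## protocol: 6 cm depth is used for the rectus femoris and only there
  bad <- which((dp == 6) != (d$muscle_group == "rectus_femoris"))
  if (length(bad) > 0L)
    .err(sprintf("row %d: depth_cm must be 6 iff muscle_group is rectus_femoris",
                 bad[1L]), "value_error")
  invisible(TRUE)
}

#' MuscleStudy: a cohort of acquired B-mode views
#'
#' Holds one validated record per acquired image (subject, diagnosis, muscle
#' group, side, view index, acquisition depth, file paths) plus, optionally,
#' the image and mask rasters themselves for in-memory synthetic studies.
#'
#' @slot records a \code{DataFrame} with the manifest columns and optionally
#'   a \code{label} column added by \code{\link{filterCohort}}.
#' @slot images,masks either empty lists (images live on disk at the recorded
#'   paths) or lists of matrices parallel to \code{records}.
#' @slot seed generator seed for synthetic studies (\code{NA} otherwise).
#' @export
setClass("MuscleStudy",
  representation(records = "DataFrame", images = "list", masks = "list",
                 seed = "integer"),
  prototype(records = S4Vectors::DataFrame(), images = list(), masks = list(),
            seed = NA_integer_))

setValidity("MuscleStudy", function(object) {
  d <- object@records
  if (nrow(d) == 0L) return(TRUE)
  ok <- tryCatch({ .validateRecords(as.data.frame(d)); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  n <- nrow(d)
  if (length(object@images) != 0L && length(object@images) != n)
    return("images must be empty or have one entry per record")
  if (length(object@masks) != length(object@images))
    return("images and masks must have the same length")
  TRUE
})

#' RegionPixels: the bag of intensities of one tissue region
#'
#' @slot values numeric intensities (8-bit scale, 0--255).
#' @slot tissue "muscle" or "fat".
#' @export
setClass("RegionPixels",
  representation(values = "numeric", tissue = "character"))

setValidity("RegionPixels", function(object) {
  if (length(object@values) < 1L) return("region must contain at least one pixel")
  if (!object@tissue %in% c("muscle", "fat")) return("tissue must be muscle or fat")
  TRUE
})

#' ProblemSpec: one of the binary classification problems
#'
#' Defines cohort inclusion and the positive class for the three diagnostic
#' problems: A (normal vs any myositis), B (normal vs IBM), C (PM/DM vs IBM).
#'
#' @slot problem "A", "B" or "C" (or a custom id).
#' @slot included,positive diagnosis codes; \code{positive} must be a proper,
#'   non-empty subset of \code{included}.
#' @export
setClass("ProblemSpec",
  representation(problem = "character", included = "character",
                 positive = "character"))

setValidity("ProblemSpec", function(object) {
  if (!all(object@included %in% DIAGNOSES)) return("unknown diagnosis in 'included'")
  if (!all(object@positive %in% object@included))
    return("'positive' must be a subset of 'included'")
  if (length(object@positive) == 0L) return("positive class is empty")
  if (length(setdiff(object@included, object@positive)) == 0L)
    return("negative class is empty")
  TRUE
})

#' FeatureSet: per-image feature vectors as a SummarizedExperiment
#'
#' Rows are the 22 named features, columns are images; \code{colData} carries
#' the image records (and the binary \code{label} after
#' \code{\link{filterCohort}}). GLCM/estimator settings are kept in
#' \code{metadata()$glcm}.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  m <- SummarizedExperiment::assay(object, "features")
  if (nrow(m) != 22L) return("feature assay must have exactly 22 rows")
  if (!identical(rownames(m), featureNames22()))
    return("feature rownames must equal featureNames22()")
  if (any(!is.finite(m))) return("all feature values must be finite")
  TRUE
})

#' TrainedEnsemble: a fitted random-forest classifier
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot config the \code{\link{classifierConfig}} used.
#' @slot featureNames training feature names, in order.
#' @slot classLevels the two class labels; the second is the positive class.
#' @slot fingerprint short description of the training set.
#' @export
setClass("TrainedEnsemble",
  representation(forest = "ANY", config = "list", featureNames = "character",
                 classLevels = "character", fingerprint = "character"))

#' FoldAssignment: muscle entities dealt to cross-validation folds
#'
#' Each muscle entity (subject, muscle group, side) -- or each subject under
#' subject-level grouping -- is assigned to exactly one fold, stratified by
#' its class label.
#'
#' @slot assignment a \code{DataFrame} with columns \code{entity},
#'   \code{label}, \code{fold}.
#' @slot nFolds,seed integers. @slot grouping "muscle" or "subject".
#' @export
setClass("FoldAssignment",
  representation(assignment = "DataFrame", nFolds = "integer",
                 seed = "integer", grouping = "character"))

setValidity("FoldAssignment", function(object) {
  a <- object@assignment
  if (anyDuplicated(a$entity)) return("an entity appears in more than one fold")
  if (any(a$fold < 1L | a$fold > object@nFolds)) return("fold index out of range")
  TRUE
})

#' MetricReport: cross-validated diagnostic metrics
#'
#' Per-fold values of the eight diagnostic metrics plus their across-fold mean
#' and sample standard deviation, the per-fold confusion counts, the fold
#' assignment, and every per-image prediction.
#'
#' @slot perFold folds x 8 matrix. @slot means,sds named numerics.
#' @slot confusion folds x 4 matrix (tp, fp, tn, fn).
#' @slot folds the \code{FoldAssignment}. @slot predictions per-image results.
#' @slot problem the problem id the report belongs to.
#' @export
setClass("MetricReport",
  representation(perFold = "matrix", means = "numeric", sds = "numeric",
                 confusion = "matrix", folds = "FoldAssignment",
                 predictions = "DataFrame", problem = "character"))
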