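#' @rdname MuscleStudy-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname MuscleStudy-class
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' Restrict a dataset to one classification problem's cohort
#'
#' Keeps only records whose diagnosis is included in the problem and attaches
#' a binary \code{label} (levels \code{negative}, \code{positive}); the label
#' is a pure function of the diagnosis, so the operation is idempotent.
#'
#' @param x a \code{MuscleStudy} or \code{FeatureSet}.
#' @param spec a \code{\link{problemSpec}}.
#' @param verbose log cohort sizes.
#' @return an object of the same class, subset, with a \code{label} column.
#' @export
setGeneric("filterCohort", function(x, spec, verbose = FALSE)
  standardGeneric("filterCohort"))

#' @rdname MetricReport-class
#' @export
setGeneric("metricMeans", function(x) standardGeneric("metricMeans"))

#' @rdname MetricReport-class
#' @export
setGeneric("metricSDs", function(x) standardGeneric("metricSDs"))

#' @rdname MetricReport-class
#' @export
setGeneric("perFoldMetrics", function(x) standardGeneric("perFoldMetrics"))

#' @rdname MetricReport-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname MetricReport-class
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname FoldAssignment-class
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))
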