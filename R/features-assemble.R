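#' Names of the 22 per-image features, in canonical order
#'
#' Five echointensity features, Nakagami shape/scale of muscle and of fat,
#' and the 13 Haralick texture statistics.
#' @return character vector of length 22.
#' @export
featureNames22 <- function() {
  c("echo_mean_muscle", "echo_sd_muscle", "echo_mean_fat", "echo_sd_fat",
    "echo_ratio",
    "nakagami_m_muscle", "nakagami_omega_muscle",
    "nakagami_m_fat", "nakagami_omega_fat",
    HARALICK_NAMES)
}

#' Assemble the 22-element feature vector of one image
#'
#' Extracts the muscle and fat pixel bags from the mask, computes the five
#' echointensity features, fits the Nakagami distribution to each tissue, and
#' computes the 13 Haralick features on the configured tissue region.
#'
#' @param image 2-D intensity matrix. @param mask label matrix (0/1/2).
#' @param config a \code{\link{glcmConfig}}.
#' @return named numeric vector of length 22 (all finite).
#' @export
assembleFeatureVector <- function(image, mask, config = glcmConfig()) {
  muscle <- extractRegion(image, mask, "muscle")
  fat <- extractRegion(image, mask, "fat")
  nm <- fitNakagami(muscle)
  nf <- fitNakagami(fat)
  v <- c(echoFeatures(muscle, fat),
         nakagami_m_muscle = unname(nm["m"]),
         nakagami_omega_muscle = unname(nm["omega"]),
         nakagami_m_fat = unname(nf["m"]),
         nakagami_omega_fat = unname(nf["omega"]),
         haralickFeatures(image, mask, config$tissue, config))
  stopifnot(identical(names(v), featureNames22()))
  if (any(!is.finite(v)))
    .err(sprintf("non-finite feature(s): %s",
                 paste(names(v)[!is.finite(v)], collapse = ", ")),
         "feature_error")
  v
}

#' Extract feature vectors for every image of a study
#'
#' Runs \code{\link{assembleFeatureVector}} on each record; any component
#' failure is re-signalled tagged with the offending record's subject, muscle,
#' side and view.
#'
#' @param study a \code{\link{MuscleStudy-class}} (on disk or in memory).
#' @param config a \code{\link{glcmConfig}}.
#' @param verbose log progress counts.
#' @return a \code{\link{FeatureSet-class}} (22 features x images); colData
#'   carries the image records.
#' @export
extractFeatures <- function(study, config = glcmConfig(), verbose = FALSE) {
  d <- records(study)
  n <- nrow(d)
  if (n == 0L) .err("study has no records", "schema_error")
  keys <- .recordKey(d)
  m <- matrix(NA_real_, nrow = 22L, ncol = n,
              dimnames = list(featureNames22(), keys))
  for (i in seq_len(n)) {
    m[, i] <- tryCatch(
      assembleFeatureVector(.getImage(study, i), .getMask(study, i), config),
      myoUS_error = function(e) .err(
        sprintf("feature extraction failed for %s: %s", keys[i],
                conditionMessage(e)), "feature_error"))
  }
  .msg(verbose, "extractFeatures: %d images x %d features", n, nrow(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m), colData = d)
  out <- new("FeatureSet", se)
  S4Vectors::metadata(out)$glcm <- config
  out
}

#' @rdname FeatureSet-class
#' @param x a FeatureSet
#' @return \code{featureMatrix}: the images x features numeric matrix
#'   (transposed assay, ready for a classifier).
#' @export
featureMatrix <- function(x) {
  t(SummarizedExperiment::assay(x, "features"))
}

#' Write a feature table to CSV (record keys, 22 features, optional label)
#' @param x a FeatureSet. @param path output CSV path.
#' @export
writeFeatureTable <- function(x, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- intersect(c("subject_id", "diagnosis", "muscle_group", "side",
                      "view_index", "label"), colnames(cd))
  out <- cbind(cd[, keep, drop = FALSE], as.data.frame(featureMatrix(x)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
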