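#' Construct a MuscleStudy from a record table
#'
#' @param records data.frame or DataFrame with the manifest columns
#'   \code{subject_id, diagnosis, muscle_group, side, view_index, depth_cm,
#'   image_path, mask_path}.
#' @param images,masks optional lists of matrices parallel to \code{records}
#'   (in-memory studies); leave empty when the rasters live on disk.
#' @param seed generator seed to record (synthetic studies).
#' @return a validated \code{\link{MuscleStudy-class}} object.
#' @export
muscleStudy <- function(records, images = list(), masks = list(),
                        seed = NA_integer_) {
  d <- as.data.frame(records, stringsAsFactors = FALSE)
  .validateRecords(d)
  d$view_index <- as.integer(d$view_index)
  d$depth_cm <- as.numeric(d$depth_cm)
  new("MuscleStudy", records = S4Vectors::DataFrame(d), images = images,
      masks = masks, seed = as.integer(seed))
}

#' @rdname MuscleStudy-class
#' @param x a MuscleStudy
#' @export
setMethod("records", "MuscleStudy", function(x) x@records)

#' @rdname MuscleStudy-class
#' @export
setMethod("nRecords", "MuscleStudy", function(x) nrow(x@records))

setMethod("show", "MuscleStudy", function(object) {
  d <- object@records
  cat(sprintf("MuscleStudy: %d image records, %d subjects\n",
              nrow(d), length(unique(d$subject_id))))
  if (nrow(d) > 0L) {
    tab <- table(d$diagnosis[!duplicated(d$subject_id)])
    cat("  subjects by diagnosis:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  storage: %s\n",
                if (length(object@images)) "in-memory" else "on disk"))
  }
})

#' Read a study manifest
#'
#' The manifest is a CSV with header \code{subject_id,diagnosis,muscle_group,
#' side,view_index,depth_cm,image_path,mask_path}; lines starting with
#' \code{#} (e.g. the generator's seed echo) are ignored. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param checkFiles verify that every referenced image/mask file exists.
#' @param verbose log the record count.
#' @return a \code{\link{MuscleStudy-class}}.
#' @export
readManifest <- function(path, checkFiles = TRUE, verbose = FALSE) {
  if (!file.exists(path))
    .err(sprintf("manifest not found: %s", path), "io_error")
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = "character")
  .validateRecords(d)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  d$image_path <- resolve(d$image_path)
  d$mask_path <- resolve(d$mask_path)
  if (checkFiles) {
    missing <- c(d$image_path[!file.exists(d$image_path)],
                 d$mask_path[!file.exists(d$mask_path)])
    if (length(missing) > 0L)
      .err(sprintf("missing %d referenced file(s), e.g.: %s",
                   length(missing), missing[1L]), "io_error")
  }
  .msg(verbose, "readManifest: %d records, %d subjects",
       nrow(d), length(unique(d$subject_id)))
  muscleStudy(d)
}

#' Write a study manifest
#'
#' Inverse of \code{\link{readManifest}}: paths are written as given in the
#' records. The generator seed, when known, is echoed as a \code{# seed:}
#' comment line.
#'
#' @param study a MuscleStudy. @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(study, path) {
  d <- as.data.frame(records(study))[, MANIFEST_COLUMNS]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(study@seed)) writeLines(sprintf("# seed: %d", study@seed), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an 8-bit grayscale image (PNG or TIFF) as a 0--255 matrix
#' @param path image file path.
#' @export
readImage <- function(path) {
  if (!file.exists(path)) .err(sprintf("image not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    .err(sprintf("unsupported image format '.%s' (PNG or TIFF expected): %s",
                 ext, path), "io_error"))
  if (length(dim(a)) == 3L) a <- a[, , 1L]  # gray+alpha / replicated channels
  round(a * 255)
}

#' Read a segmentation label mask (PNG/TIFF label raster or ITK-Snap NIfTI)
#'
#' Labels are normalized to the package coding background = 0, muscle = 1,
#' fat = 2; any other value is rejected.
#'
#' @param path mask file path (.png, .tif/.tiff, .nii, .nii.gz).
#' @export
readMask <- function(path) {
  if (!file.exists(path)) .err(sprintf("mask not found: %s", path), "io_error")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    m <- RNifti::readNifti(path)
    m <- drop(as.array(m))
    if (length(dim(m)) != 2L)
      .err(sprintf("NIfTI mask must be 2-D after dropping singleton dims: %s",
                   path), "io_error")
    m <- round(m)
  } else {
    m <- readImage(path)  # 8-bit raster storing raw label values
  }
  if (!all(m %in% c(0, 1, 2)))
    .err(sprintf("mask labels must be 0 (background), 1 (muscle), 2 (fat): %s",
                 path), "value_error")
  m
}

## fetch raster i of a study, from memory or from disk
.getImage <- function(study, i) {
  if (length(study@images)) study@images[[i]]
  else readImage(records(study)$image_path[i])
}

.getMask <- function(study, i) {
  if (length(study@masks)) study@masks[[i]]
  else readMask(records(study)$mask_path[i])
}

#' Extract the pixel bag of one tissue region
#'
#' Returns exactly the image intensities at positions whose mask label matches
#' the requested tissue (muscle = 1, fat = 2).
#'
#' @param image 2-D intensity matrix. @param mask same-shaped label matrix.
#' @param tissue "muscle" or "fat".
#' @return a \code{\link{RegionPixels-class}}.
#' @export
extractRegion <- function(image, mask, tissue = c("muscle", "fat")) {
  tissue <- match.arg(tissue)
  if (!identical(dim(image), dim(mask)))
    .err(sprintf("image (%s) and mask (%s) dimensions differ",
                 paste(dim(image), collapse = "x"),
                 paste(dim(mask), collapse = "x")), "dimension_error")
  label <- c(muscle = 1, fat = 2)[[tissue]]
  vals <- image[mask == label]
  if (length(vals) == 0L)
    .err(sprintf("no pixels labeled '%s' (label %d) in mask", tissue, label),
         "empty_region_error")
  new("RegionPixels", values = as.numeric(vals), tissue = tissue)
}

#' @rdname RegionPixels-class
#' @param x a RegionPixels
#' @export
regionValues <- function(x) x@values

setMethod("show", "RegionPixels", function(object) {
  cat(sprintf("RegionPixels: %s, %d pixels, mean %.1f\n", object@tissue,
              length(object@values), mean(object@values)))
})

setMethod("length", "RegionPixels", function(x) length(x@values))

#' Define one of the binary classification problems
#'
#' Problem A compares normal subjects against any myositis (positive =
#' PM/DM/IBM), problem B normal against IBM (positive = IBM), problem C the
#' treatable myositis subtypes PM/DM against treatment-refractory IBM
#' (positive = IBM). The positive class can be overridden.
#'
#' @param problem "A", "B" or "C".
#' @param included,positive optional overrides of the cohort and positive
#'   class (diagnosis codes).
#' @return a \code{\link{ProblemSpec-class}}.
#' @export
problemSpec <- function(problem = c("A", "B", "C"), included = NULL,
                        positive = NULL) {
  problem <- match.arg(problem)
  defaults <- list(
    A = list(included = c("N", "PM", "DM", "IBM"), positive = c("PM", "DM", "IBM")),
    B = list(included = c("N", "IBM"), positive = "IBM"),
    C = list(included = c("PM", "DM", "IBM"), positive = "IBM"))
  new("ProblemSpec", problem = problem,
      included = included %||% defaults[[problem]]$included,
      positive = positive %||% defaults[[problem]]$positive)
}

setMethod("show", "ProblemSpec", function(object) {
  cat(sprintf("ProblemSpec %s: {%s} vs positive {%s}\n", object@problem,
              paste(setdiff(object@included, object@positive), collapse = ","),
              paste(object@positive, collapse = ",")))
})

.labelFor <- function(diagnosis, spec) {
  factor(ifelse(diagnosis %in% spec@positive, "positive", "negative"),
         levels = c("negative", "positive"))
}

.checkCohort <- function(d, spec, verbose) {
  if (nrow(d) == 0L || nlevels(droplevels(d$label)) < 2L)
    .err(sprintf("problem %s cohort is degenerate: need both classes, got %s",
                 spec@problem,
                 paste(unique(as.character(d$label)), collapse = ",")),
         "degenerate_cohort_error")
  .msg(verbose, "problem %s cohort: %d subjects, %d images (%d positive)",
       spec@problem, length(unique(d$subject_id)), nrow(d),
       sum(d$label == "positive"))
}

#' @rdname filterCohort
#' @export
setMethod("filterCohort", "MuscleStudy", function(x, spec, verbose = FALSE) {
  keep <- which(records(x)$diagnosis %in% spec@included)
  d <- x@records[keep, , drop = FALSE]
  d$label <- .labelFor(d$diagnosis, spec)
  .checkCohort(d, spec, verbose)
  new("MuscleStudy", records = d,
      images = if (length(x@images)) x@images[keep] else list(),
      masks = if (length(x@masks)) x@masks[keep] else list(),
      seed = x@seed)
})

#' @rdname filterCohort
#' @export
setMethod("filterCohort", "FeatureSet", function(x, spec, verbose = FALSE) {
  keep <- which(SummarizedExperiment::colData(x)$diagnosis %in% spec@included)
  out <- x[, keep]
  cd <- SummarizedExperiment::colData(out)
  cd$label <- .labelFor(cd$diagnosis, spec)
  SummarizedExperiment::colData(out) <- cd
  .checkCohort(cd, spec, verbose)
  out
})
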