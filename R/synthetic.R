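#' Nakagami distribution utilities
#'
#' The Nakagami(m, omega) amplitude distribution (shape m >= 0.5, scale
#' omega = E[X^2]) models ultrasound speckle; m = 1 is Rayleigh scattering.
#' If X ~ Nakagami(m, omega) then X^2 ~ Gamma(shape = m, scale = omega/m),
#' which is how \code{rnakagami} draws. The mean is
#' Gamma(m + 1/2) / Gamma(m) * sqrt(omega / m), inverted by
#' \code{nakagamiOmegaForMean} to pick a scale achieving a target mean
#' echointensity.
#'
#' @param n number of draws. @param m shape. @param omega scale.
#' @name nakagami
NULL

#' @rdname nakagami
#' @export
rnakagami <- function(n, m, omega) {
  stopifnot(m >= 0.5, omega > 0)
  sqrt(stats::rgamma(n, shape = m, rate = m / omega))
}

#' @rdname nakagami
#' @export
nakagamiMean <- function(m, omega) {
  exp(lgamma(m + 0.5) - lgamma(m)) * sqrt(omega / m)
}

#' @rdname nakagami
#' @param mean target mean amplitude.
#' @export
nakagamiOmegaForMean <- function(m, mean) {
  stopifnot(m >= 0.5, mean > 0)
  m * (mean / exp(lgamma(m + 0.5) - lgamma(m)))^2
}

#' Nakagami parameters of one synthetic tissue
#'
#' @param m Nakagami shape (>= 0.5).
#' @param omega Nakagami scale; alternatively give \code{meanIntensity} and
#'   the scale achieving that mean is derived.
#' @param meanIntensity target mean echointensity (0--255 scale).
#' @param thicknessFraction for the fat band: fraction of image height
#'   occupied by the subcutaneous fat layer.
#' @param blurSigma optional Gaussian smoothing (pixels) emulating lateral
#'   speckle correlation; 0 = independent pixels.
#' @return a list of class \code{tissueParams}.
#' @export
tissueParams <- function(m, omega = NULL, meanIntensity = NULL,
                         thicknessFraction = NA_real_, blurSigma = 0) {
  if (is.null(omega)) {
    if (is.null(meanIntensity)) stop("give omega or meanIntensity")
    omega <- nakagamiOmegaForMean(m, meanIntensity)
  }
  stopifnot(m >= 0.5, omega > 0,
            is.na(thicknessFraction) ||
              (thicknessFraction > 0 && thicknessFraction < 1))
  structure(list(m = m, omega = omega,
                 thicknessFraction = thicknessFraction, blurSigma = blurSigma),
            class = "tissueParams")
}

#' Class-dependent tissue parameter presets
#'
#' Three generator presets with a shared subcutaneous-fat band (m = 1.2, mean
#' 120, 25\% of image height) and diagnosis-dependent muscle speckle:
#' \describe{
#'   \item{separable}{normal muscle m = 1.8, mean 50; affected (PM/DM/IBM)
#'     muscle m = 0.8, mean 110 -- mimicking the clinical direction that
#'     fatty-replaced, fibrotic muscle is markedly more echogenic.}
#'   \item{overlapping}{affected muscle m = 1.8, mean 70: classes differ only
#'     in mean echointensity, by a smaller margin; with between-subject
#'     variability enabled in the \code{\link{studyDesign}} the class
#'     distributions overlap substantially.}
#'   \item{null}{identical parameters (m = 1.5, mean 80) for every diagnosis;
#'     any classifier should perform at chance.}
#' }
#' All values are generator conventions (synthetic), not clinical
#' measurements.
#'
#' @param name preset name.
#' @return list of class \code{classPreset}: per-diagnosis
#'   \code{list(muscle =, fat =)} \code{\link{tissueParams}}.
#' @export
classPreset <- function(name = c("separable", "overlapping", "null")) {
  name <- match.arg(name)
  fat <- tissueParams(m = 1.2, meanIntensity = 120, thicknessFraction = 0.25)
  muscle <- switch(name,
    separable = list(N = tissueParams(1.8, meanIntensity = 50),
                     affected = tissueParams(0.8, meanIntensity = 110)),
    overlapping = list(N = tissueParams(1.8, meanIntensity = 50),
                       affected = tissueParams(1.8, meanIntensity = 70)),
    null = list(N = tissueParams(1.5, meanIntensity = 80),
                affected = tissueParams(1.5, meanIntensity = 80)))
  per_dx <- lapply(stats::setNames(DIAGNOSES, DIAGNOSES), function(dx)
    list(muscle = if (dx == "N") muscle$N else muscle$affected, fat = fat))
  structure(c(per_dx, list(preset_name = name)), class = "classPreset")
}

#' Synthetic study design mirroring the acquisition protocol
#'
#' Defaults reproduce the clinical study's shape: subjects per diagnosis
#' (33 N / 14 PM / 14 DM / 19 IBM), seven muscle groups imaged bilaterally,
#' three transverse views per muscle, 476 x 499 pixels at 4 cm depth and
#' 318 x 499 at the rectus femoris' 6 cm depth.
#'
#' By default every image of a class is drawn from identical tissue
#' parameters (pure class-conditional speckle). Optional between-subject and
#' between-entity lognormal variability of mean echointensity
#' (\code{subjectSD}, \code{entitySD}, SDs on the log scale, default 0)
#' emulates biological heterogeneity; turning it on makes subjects
#' individually recognizable from their echo level, which exposes the
#' subject-identity leakage that muscle-entity-grouped cross-validation
#' permits (see the vignette).
#'
#' @param nSubjects named integer vector of subjects per diagnosis.
#' @param muscles,sides,views muscle groups, sides and views per muscle.
#' @param sizes list with elements \code{"4"} and \code{"6"}: c(width,
#'   height) in pixels for each acquisition depth.
#' @param subjectSD,entitySD lognormal SDs of the per-subject and per-entity
#'   echointensity factors.
#' @param seed base seed; every record derives an independent substream.
#' @return list of class \code{studyDesign}.
#' @export
studyDesign <- function(nSubjects = c(N = 33L, PM = 14L, DM = 14L, IBM = 19L),
                        muscles = MUSCLE_GROUPS, sides = SIDES, views = 3L,
                        sizes = list(`4` = c(width = 476L, height = 499L),
                                     `6` = c(width = 318L, height = 499L)),
                        subjectSD = 0, entitySD = 0, seed = 1L) {
  nSubjects <- unlist(nSubjects)  # tolerate YAML-decoded lists
  sizes <- lapply(sizes, unlist)
  stopifnot(all(names(nSubjects) %in% DIAGNOSES), all(nSubjects >= 0L),
            all(muscles %in% MUSCLE_GROUPS), all(sides %in% SIDES),
            views >= 1L, views <= 3L,
            all(c("4", "6") %in% names(sizes)))
  structure(list(nSubjects = nSubjects, muscles = muscles, sides = sides,
                 views = as.integer(views), sizes = sizes,
                 subjectSD = subjectSD, entitySD = entitySD,
                 seed = as.integer(seed)),
            class = "studyDesign")
}

#' Generate one speckle phantom (image + mask)
#'
#' The top \code{thicknessFraction} of the image is the subcutaneous fat band
#' (label 2), the remainder muscle (label 1). Each pixel is drawn
#' independently from its tissue's Nakagami(m, omega), optionally smoothed,
#' then clipped to [0, 255] and quantized to 8 bits. The mask is exact.
#'
#' @param muscle,fat \code{\link{tissueParams}}; \code{fat$thicknessFraction}
#'   sets the band height.
#' @param height,width image size in pixels.
#' @param seed optional seed for this phantom.
#' @param blurSigma Gaussian smoothing in pixels (default: the muscle
#'   parameter's \code{blurSigma}).
#' @return \code{list(image =, mask =)} of height x width matrices.
#' @export
generatePhantom <- function(muscle, fat, height, width, seed = NULL,
                            blurSigma = muscle$blurSigma) {
  band <- round(fat$thicknessFraction * height)
  if (is.na(band) || band < 1L || band >= height)
    .err(sprintf("fat band of %s rows is impossible at height %d",
                 band, height), "geometry_error")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(1L, height, width)
  mask[seq_len(band), ] <- 2L
  img <- matrix(0, height, width)
  img[mask == 2L] <- rnakagami(band * width, fat$m, fat$omega)
  img[mask == 1L] <- rnakagami((height - band) * width, muscle$m, muscle$omega)
  if (blurSigma > 0) img <- .gaussianBlur(img, blurSigma)
  img[] <- round(pmin(pmax(img, 0), 255))  # clip + 8-bit quantize, keep dim
  list(image = img, mask = mask)
}

## per-subject / per-entity lognormal echointensity factors, drawn from
## substreams that do not depend on the diagnosis parameters
.subjectFactor <- function(design, subjIdx) {
  set.seed(.mix(design$seed, 1L, subjIdx))
  exp(stats::rnorm(1L, 0, design$subjectSD))
}

.entityFactor <- function(design, subjIdx, musIdx, sideIdx) {
  set.seed(.mix(design$seed, 2L, subjIdx, musIdx, sideIdx))
  exp(stats::rnorm(1L, 0, design$entitySD))
}

#' Generate a full synthetic study
#'
#' Builds every image record of the design (subjects x muscles x sides x
#' views), draws each phantom from an independent per-record substream of the
#' base seed (so the dataset is reproducible and partially regenerable, and
#' changing one diagnosis' parameters changes only that diagnosis' images),
#' and either returns the study in memory (\code{dir = NULL}) or writes
#' 8-bit grayscale PNG images, label-PNG masks and a manifest CSV.
#'
#' The disease effect is applied per subject: every muscle of an affected
#' subject uses the affected parameters, matching a per-patient gold-standard
#' label. Per-subject and per-entity echo factors scale the muscle mean
#' (omega scales by the squared factor).
#'
#' @param design a \code{\link{studyDesign}}. @param preset a
#'   \code{\link{classPreset}}.
#' @param dir output directory, or \code{NULL} for an in-memory study.
#' @param force overwrite a non-empty \code{dir}.
#' @param verbose log progress.
#' @return in-memory mode: a \code{\link{MuscleStudy-class}}; on-disk mode:
#'   the manifest path.
#' @export
generateStudy <- function(design, preset = classPreset("separable"),
                          dir = NULL, force = FALSE, verbose = FALSE) {
  dxs <- names(design$nSubjects)[design$nSubjects > 0L]
  subj_dx <- rep(dxs, design$nSubjects[dxs])
  n_subj <- length(subj_dx)
  if (n_subj == 0L) .err("design has no subjects", "configuration_error")
  subj_id <- sprintf("S%03d", seq_len(n_subj))

  grid <- expand.grid(view = seq_len(design$views),
                      sideIdx = seq_along(design$sides),
                      musIdx = seq_along(design$muscles),
                      subjIdx = seq_len(n_subj))
  d <- data.frame(
    subject_id = subj_id[grid$subjIdx],
    diagnosis = subj_dx[grid$subjIdx],
    muscle_group = design$muscles[grid$musIdx],
    side = design$sides[grid$sideIdx],
    view_index = grid$view,
    stringsAsFactors = FALSE)
  d$depth_cm <- ifelse(d$muscle_group == "rectus_femoris", 6, 4)
  keys <- .recordKey(d)
  d$image_path <- file.path("images", paste0(keys, ".png"))
  d$mask_path <- file.path("masks", paste0(keys, ".png"))

  images <- vector("list", nrow(d))
  masks <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    p <- preset[[d$diagnosis[i]]]
    f <- .subjectFactor(design, grid$subjIdx[i]) *
         .entityFactor(design, grid$subjIdx[i], grid$musIdx[i], grid$sideIdx[i])
    mus <- p$muscle
    mus$omega <- mus$omega * f^2  # scale mean echo by f
    sz <- design$sizes[[as.character(d$depth_cm[i])]]
    ph <- generatePhantom(mus, p$fat, height = sz[["height"]],
                          width = sz[["width"]],
                          seed = .mix(design$seed, 3L, grid$subjIdx[i],
                                      grid$musIdx[i], grid$sideIdx[i],
                                      grid$view[i]))
    images[[i]] <- ph$image
    masks[[i]] <- ph$mask
  }
  .msg(verbose, "generateStudy: %d subjects, %d records (preset %s, seed %d)",
       n_subj, nrow(d), preset$preset_name, design$seed)

  if (is.null(dir))
    return(muscleStudy(d, images = images, masks = masks, seed = design$seed))

  if (dir.exists(dir) && length(list.files(dir, recursive = TRUE)) > 0L &&
      !isTRUE(force))
    .err(sprintf("output directory '%s' is not empty (use force = TRUE)", dir),
         "overwrite_error")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(d))) {
    png::writePNG(images[[i]] / 255, file.path(dir, d$image_path[i]))
    png::writePNG(masks[[i]] / 255, file.path(dir, d$mask_path[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  writeManifest(muscleStudy(d, seed = design$seed), manifest)
  manifest
}
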