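#' Pipeline configuration
#'
#' One nested configuration drives generate -> extract -> cross-validate for
#' any of the problems A/B/C. Every stochastic component carries an explicit
#' seed. The dataset is either a manifest on disk (\code{dataset$manifest})
#' or a synthetic design (\code{dataset$synthetic} with \code{preset} and
#' \code{\link{studyDesign}} fields).
#'
#' @param dataset list: either \code{list(manifest = path)} or
#'   \code{list(synthetic = list(preset = "separable", ...studyDesign
#'   arguments...))}.
#' @param problems problems to run (subset of A/B/C).
#' @param glcm,classifier,cv settings lists merged over the package defaults
#'   (\code{cv}: \code{n_folds}, \code{grouping}, \code{seed}).
#' @param outDir where \code{\link{runProblem}} writes artifacts
#'   (\code{NULL} = return results only).
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(dataset, problems = c("A", "B", "C"),
                           glcm = list(), classifier = list(), cv = list(),
                           outDir = NULL) {
  stopifnot(is.list(dataset),
            !is.null(dataset$manifest) || !is.null(dataset$synthetic),
            all(problems %in% c("A", "B", "C")))
  g <- utils::modifyList(list(n_levels = 32L, distance = 1L,
                              tissue = "muscle"), glcm)
  cl <- utils::modifyList(list(n_trees = 500L, mtry = "sqrt",
                               max_nodes = NULL, seed = 1L), classifier)
  cvd <- utils::modifyList(list(n_folds = 5L, grouping = "muscle", seed = 1L), cv)
  structure(list(dataset = dataset, problems = problems, glcm = g,
                 classifier = cl, cv = cvd, outDir = outDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same nested blocks as \code{\link{pipelineConfig}} and
#' rejects unknown top-level keys.
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .err(sprintf("config not found: %s", path), "io_error")
  y <- yaml::read_yaml(path)
  known <- c("dataset", "problems", "glcm", "classifier", "cv", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    .err(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         "schema_error")
  if (is.null(y$dataset))
    .err("config requires a 'dataset' block", "schema_error")
  ## YAML 1.1 parses an unquoted key `N` (the normal-diagnosis code) as a
  ## boolean; undo that so `nSubjects: {N: 33, ...}` works unquoted
  ns <- y$dataset$synthetic$nSubjects
  if (!is.null(ns)) {
    names(ns)[names(ns) %in% c("FALSE", "no")] <- "N"
    y$dataset$synthetic$nSubjects <- ns
  }
  pipelineConfig(dataset = y$dataset,
                 problems = y$problems %||% c("A", "B", "C"),
                 glcm = y$glcm %||% list(),
                 classifier = y$classifier %||% list(),
                 cv = y$cv %||% list(),
                 outDir = y$out_dir)
}

.configGlcm <- function(config)
  glcmConfig(nLevels = config$glcm$n_levels, distance = config$glcm$distance,
             tissue = config$glcm$tissue)

.configClassifier <- function(config)
  classifierConfig(nTrees = config$classifier$n_trees,
                   mtry = config$classifier$mtry,
                   maxNodes = config$classifier$max_nodes,
                   seed = config$classifier$seed)

.resolveStudy <- function(config, verbose = FALSE) {
  ds <- config$dataset
  if (!is.null(ds$manifest)) return(readManifest(ds$manifest, verbose = verbose))
  s <- ds$synthetic
  preset <- classPreset(s$preset %||% "separable")
  args <- s[setdiff(names(s), "preset")]
  design <- do.call(studyDesign, args)
  generateStudy(design, preset, verbose = verbose)
}

.writeRunLog <- function(config, dir, extra = character()) {
  lines <- c(sprintf("myoUS %s run log", as.character(utils::packageVersion("myoUS"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "config:",
             strsplit(yaml::as.yaml(
               config[c("dataset", "problems", "glcm", "classifier", "cv")]),
               "\n")[[1L]],
             extra)
  writeLines(lines, file.path(dir, "run_log.txt"))
}

#' Run one classification problem end to end
#'
#' Resolves the dataset (manifest or synthetic), extracts the feature table
#' (or reuses one already extracted), filters the cohort of the requested
#' problem, and runs the grouped cross-validation. When \code{outDir} is set,
#' writes the feature table, per-fold predictions, the metric report JSON and
#' a run log recording config and seeds.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param problem "A", "B" or "C".
#' @param features optional pre-extracted \code{\link{FeatureSet-class}}
#'   (shared across problems).
#' @param verbose log stage progress.
#' @return the \code{\link{MetricReport-class}}.
#' @export
runProblem <- function(config, problem = config$problems[1L], features = NULL,
                       verbose = FALSE) {
  if (is.null(features)) {
    study <- .resolveStudy(config, verbose = verbose)
    features <- extractFeatures(study, .configGlcm(config), verbose = verbose)
  }
  spec <- problemSpec(problem)
  cohort <- filterCohort(features, spec, verbose = verbose)
  report <- crossValidate(cohort, .configClassifier(config),
                          nFolds = config$cv$n_folds, seed = config$cv$seed,
                          grouping = config$cv$grouping, problem = problem,
                          verbose = verbose)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(features, file.path(config$outDir, "features.csv"))
    utils::write.csv(as.data.frame(cvPredictions(report)),
                     file.path(config$outDir,
                               sprintf("predictions_%s.csv", problem)),
                     row.names = FALSE)
    writeMetricReport(report, file.path(config$outDir,
                                        sprintf("metrics_%s.json", problem)))
    .writeRunLog(config, config$outDir,
                 sprintf("problem %s: mean accuracy %.4f", problem,
                         metricMeans(report)[["accuracy"]]))
  }
  report
}

#' Run all configured problems on one shared feature table
#'
#' Features are extracted once per image regardless of how many problems
#' include it; each problem then filters its cohort and cross-validates
#' independently.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose log stage progress.
#' @return named list of \code{\link{MetricReport-class}} objects.
#' @export
runAll <- function(config, verbose = FALSE) {
  study <- .resolveStudy(config, verbose = verbose)
  features <- extractFeatures(study, .configGlcm(config), verbose = verbose)
  reports <- lapply(config$problems, function(p)
    runProblem(config, p, features = features, verbose = verbose))
  stats::setNames(reports, config$problems)
}
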