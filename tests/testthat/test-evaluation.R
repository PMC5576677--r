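labelledRecords <- function(st, problem = "B")
  filterCohort(st, problemSpec(problem))

test_that("fold assignment deals entities evenly without leakage", {
  st <- labelledRecords(tinyStudy(nN = 3L, nIBM = 2L, muscles = "deltoid",
                                  views = 2L, px = 24L))
  # 5 subjects x 1 muscle x 2 sides = 10 entities into 5 folds
  fa <- assignFolds(st, nFolds = 5L, seed = 1L)
  tab <- table(foldAssignment(fa)$fold)
  expect_identical(unname(as.integer(tab)), rep(2L, 5L))

  # every record of an entity shares the entity's fold
  d <- records(st)
  f <- myoUS:::.recordFolds(d, fa)
  ent <- paste(d$subject_id, d$muscle_group, d$side)
  expect_true(all(tapply(f, ent, function(x) length(unique(x))) == 1L))

  expect_error(assignFolds(st, nFolds = 11L, seed = 1L),
               class = "myoUS_configuration_error")
})

test_that("stratification keeps both classes in every fold", {
  st <- labelledRecords(tinyStudy(nN = 6L, nIBM = 6L, muscles = "deltoid",
                                  views = 1L, px = 24L))
  for (s in 1:5) {
    fa <- assignFolds(st, nFolds = 5L, seed = s)
    tab <- table(foldAssignment(fa)$fold, foldAssignment(fa)$label)
    expect_true(all(tab > 0L))
  }
})

test_that("metric formulas match hand-computed confusion examples", {
  m <- computeMetrics(tp = 40, fp = 15, tn = 35, fn = 10)
  expect_equal(m[["accuracy"]], 0.750)
  expect_equal(m[["sensitivity"]], 0.800)
  expect_equal(m[["specificity"]], 0.700)
  expect_equal(m[["ppv"]], 40 / 55, tolerance = 1e-12)   # 0.727
  expect_equal(m[["npv"]], 35 / 45, tolerance = 1e-12)   # 0.778
  expect_equal(m[["kappa"]], 0.500)
  expect_equal(m[["lr_pos"]], 0.8 / 0.3, tolerance = 1e-12)  # 2.667
  expect_equal(m[["lr_neg"]], 0.2 / 0.7, tolerance = 1e-12)  # 0.286

  # perfect classifier: LR+ hits the +Inf sentinel
  p <- computeMetrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(p[["accuracy"]], 1)
  expect_equal(p[["kappa"]], 1)
  expect_identical(p[["lr_pos"]], Inf)
  expect_equal(p[["lr_neg"]], 0)

  # constant positive prediction on balanced truth: chance-level kappa
  suppressWarnings(cst <- computeMetrics(tp = 10, fp = 10, tn = 0, fn = 0))
  expect_equal(cst[["kappa"]], 0)

  expect_error(computeMetrics(tp = 0, fp = 5, tn = 5, fn = 0),
               class = "myoUS_undefined_metric_error")
  expect_warning(computeMetrics(tp = 0, fp = 0, tn = 5, fn = 5), "PPV")
})

test_that("per-fold accuracy satisfies the sens/spec identity", {
  st <- labelledRecords(tinyStudy())
  rep <- crossValidate(extractFeatures(st), classifierConfig(nTrees = 100L),
                       nFolds = 5L, seed = 1L)
  pf <- perFoldMetrics(rep)
  cc <- confusionCounts(rep)
  P <- cc[, "tp"] + cc[, "fn"]
  N <- cc[, "tn"] + cc[, "fp"]
  expect_equal(unname(pf[, "accuracy"]),
               unname((pf[, "sensitivity"] * P + pf[, "specificity"] * N) / (P + N)))
  expect_equal(unname(metricMeans(rep)), unname(colMeans(pf)))
  expect_equal(unname(metricSDs(rep)), unname(apply(pf, 2, sd)))
})

test_that("train and test entities are disjoint in every run", {
  st <- labelledRecords(tinyStudy(nN = 4L, nIBM = 4L))
  fs <- extractFeatures(st)
  rep <- crossValidate(fs, classifierConfig(nTrees = 50L), nFolds = 5L, seed = 2L)
  pr <- as.data.frame(cvPredictions(rep))
  ent <- paste(pr$subject_id, pr$muscle_group, pr$side)
  # each entity is predicted in exactly one fold
  expect_true(all(tapply(pr$fold, ent, function(x) length(unique(x))) == 1L))
  # and every image was predicted exactly once
  expect_identical(nrow(pr), nRecords(st))
})

test_that("duplicated images stay co-fold and get identical predictions", {
  st <- labelledRecords(tinyStudy(nN = 3L, nIBM = 3L, muscles = "deltoid",
                                  views = 1L, px = 32L))
  d <- as.data.frame(records(st))
  dup <- d; dup$view_index <- 2L  # same entities, duplicated content
  st2 <- muscleStudy(rbind(d, dup),
                     images = c(st@images, st@images),
                     masks = c(st@masks, st@masks))
  st2@records$label <- factor(
    ifelse(st2@records$diagnosis == "IBM", "positive", "negative"),
    levels = c("negative", "positive"))
  rep <- crossValidate(extractFeatures(st2), classifierConfig(nTrees = 50L),
                       nFolds = 3L, seed = 1L)
  pr <- as.data.frame(cvPredictions(rep))
  ent <- paste(pr$subject_id, pr$muscle_group, pr$side)
  expect_true(all(tapply(pr$fold, ent, function(x) length(unique(x))) == 1L))
  # both views of one entity carry identical features, hence identical scores
  expect_true(all(tapply(pr$score, ent, function(x) length(unique(x))) == 1L))
})

test_that("results are invariant to record ordering in the manifest", {
  st <- labelledRecords(tinyStudy(nN = 3L, nIBM = 3L, px = 32L))
  fs <- extractFeatures(st)
  perm <- sample(ncol(fs))
  rep1 <- crossValidate(fs, classifierConfig(nTrees = 50L), nFolds = 3L, seed = 4L)
  rep2 <- crossValidate(fs[, perm], classifierConfig(nTrees = 50L),
                        nFolds = 3L, seed = 4L)
  expect_equal(metricMeans(rep1), metricMeans(rep2))
  expect_identical(perFoldMetrics(rep1), perFoldMetrics(rep2))
})

test_that("subject grouping guards the subject-identity leakage channel", {
  # With between-subject echo variability, a label-free (null) dataset still
  # scores above chance under muscle-entity grouping: other entities of a
  # test subject sit in training, and recognizing the subject reveals its
  # label. Subject-level grouping closes that channel.
  demo <- function(seed, grouping) {
    des <- studyDesign(nSubjects = c(N = 16L, IBM = 16L),
                       muscles = c("deltoid", "biceps", "rectus_femoris"),
                       views = 2L,
                       sizes = list(`4` = c(width = 64L, height = 64L),
                                    `6` = c(width = 64L, height = 64L)),
                       subjectSD = 0.15, entitySD = 0.05, seed = seed)
    fs <- extractFeatures(generateStudy(des, classPreset("null")))
    rep <- crossValidate(filterCohort(fs, problemSpec("B")),
                         classifierConfig(nTrees = 300L), nFolds = 5L,
                         seed = seed, grouping = grouping)
    metricMeans(rep)[["accuracy"]]
  }
  entity <- mean(sapply(31:33, demo, grouping = "muscle"))
  subject <- mean(sapply(31:33, demo, grouping = "subject"))
  expect_gt(entity - subject, 0.05)
  expect_lt(abs(subject - 0.5), 0.1)
})

test_that("folds that cannot hold both classes raise a named error", {
  # one positive subject = 2 entities; with 5 folds, 3 folds get no positive
  st <- labelledRecords(tinyStudy(nN = 5L, nIBM = 1L, muscles = "deltoid",
                                  views = 1L, px = 24L))
  fs <- extractFeatures(st)
  expect_error(crossValidate(fs, classifierConfig(nTrees = 20L),
                             nFolds = 5L, seed = 1L),
               "fold", class = "myoUS_fold_degeneracy_error")
})

test_that("labels inconsistent within an entity are rejected", {
  st <- labelledRecords(tinyStudy(nN = 2L, nIBM = 2L, muscles = "deltoid",
                                  views = 2L, px = 24L))
  cd <- records(st)
  cd$label <- factor(rep(c("negative", "positive"), length.out = nrow(cd)),
                     levels = c("negative", "positive"))
  expect_error(assignFolds(cd, nFolds = 2L), class = "myoUS_value_error")
})
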