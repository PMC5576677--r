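region <- function(v, tissue = "muscle") new("RegionPixels", values = v, tissue = tissue)

test_that("echointensity features match hand-computed values", {
  f <- echoFeatures(region(rep(100, 50)), region(rep(50, 20), "fat"))
  expect_equal(unname(f), c(100, 0, 50, 0, 2))

  f <- echoFeatures(region(c(1, 2, 3)), region(c(2, 2), "fat"))
  expect_equal(unname(f), c(2, 1, 2, 0, 1))  # sample SD of {1,2,3} is 1

  expect_error(echoFeatures(region(c(1, 2)), region(c(0, 0), "fat")),
               class = "myoUS_degenerate_ratio_error")
  expect_error(echoFeatures(region(5), region(c(2, 2), "fat")),
               class = "myoUS_insufficient_data_error")
})

test_that("Nakagami moment estimator recovers simulated parameters", {
  cases <- list(c(m = 1, omega = 1), c(m = 3, omega = 2))
  for (i in seq_along(cases)) {
    set.seed(100 + i)
    x <- rnakagami(1e5, cases[[i]]["m"], cases[[i]]["omega"])
    fit <- fitNakagami(x)
    expect_lt(abs(fit["m"] - cases[[i]]["m"]) / cases[[i]]["m"], 0.05)
    expect_lt(abs(fit["omega"] - cases[[i]]["omega"]) / cases[[i]]["omega"], 0.02)
  }
})

test_that("Nakagami estimator guards degenerate input", {
  expect_error(fitNakagami(region(rep(7, 100))),
               class = "myoUS_degenerate_texture_error")
  expect_error(fitNakagami(region(1:5)),
               class = "myoUS_insufficient_data_error")
  # shape estimates below the support bound are clamped with a warning
  set.seed(1)
  x <- exp(rnorm(5e3, 0, 1.2))  # heavy-tailed, m-hat << 0.5
  expect_warning(fit <- fitNakagami(x), "clamped")
  expect_identical(unname(fit["m"]), 0.5)
})

test_that("Nakagami estimator is scale-equivariant and consistent", {
  set.seed(42)
  x <- rnakagami(2e4, 1.5, 3)
  f1 <- fitNakagami(x)
  f2 <- fitNakagami(2.5 * x)
  expect_equal(f2[["m"]], f1[["m"]], tolerance = 1e-12)
  expect_equal(f2[["omega"]], 2.5^2 * f1[["omega"]], tolerance = 1e-12)

  # median |m-hat - m| shrinks with sample size (20 replicates per size)
  set.seed(7)
  mae <- sapply(c(1e3, 1e4, 1e5), function(n)
    median(abs(replicate(20, fitNakagami(rnakagami(n, 2, 1))[["m"]]) - 2)))
  expect_true(all(diff(mae) < 0))
})

test_that("Haralick features of simple patterns match hand enumeration", {
  # constant region: single-cell GLCM
  h <- haralickFeatures(matrix(5, 4, 4), config = glcmConfig(nLevels = 8))
  expect_equal(h[["haralick_asm"]], 1)
  expect_equal(h[["haralick_entropy"]], 0)
  expect_equal(h[["haralick_contrast"]], 0)

  # 4x4 two-level checkerboard, horizontal offset only: every pair differs
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 + 1)
  q <- myoUS:::.quantize(cb, 2L)
  P <- myoUS:::.pairCounts(matrix(q, 4, 4), 0L, 1L, 2L)
  P <- P / sum(P)
  st <- myoUS:::.haralickFromGLCM(P)
  expect_equal(st[["haralick_contrast"]], 1)
  expect_equal(st[["haralick_asm"]], 0.5)
})

test_that("all 13 Haralick statistics match the brute-force oracle", {
  set.seed(11)
  toys <- list(
    matrix(c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2, 3, 4, 4, 3, 2, 1), 4, 4),
    matrix(sample(1:4, 36, replace = TRUE), 6, 6),
    matrix(sample(1:6, 30, replace = TRUE), 5, 6))
  for (toy in toys) {
    G <- max(toy)
    impl <- haralickFeatures(toy, config = glcmConfig(nLevels = G))
    orac <- oracleHaralickImage(toy, G)
    expect_equal(unname(impl), orac, tolerance = 1e-10)
  }
})

test_that("Haralick oracle agreement holds inside a masked region too", {
  set.seed(12)
  img <- matrix(sample(1:5, 48, replace = TRUE), 6, 8)
  msk <- matrix(0L, 6, 8)
  msk[2:5, 3:7] <- 1L
  impl <- haralickFeatures(img, msk, "muscle", glcmConfig(nLevels = 5))
  q <- matrix(NA_integer_, 6, 8)
  q[msk == 1L] <- myoUS:::.quantize(img[msk == 1L], 5L)
  expect_equal(unname(impl), oracleHaralickImage(q, 5), tolerance = 1e-10)
})

test_that("GLCMs are normalized and features shift-invariant", {
  set.seed(13)
  img <- matrix(sample(0:200, 400, replace = TRUE), 20, 20)
  msk <- matrix(1L, 20, 20)
  mats <- myoUS:::.glcmMatrices(img, msk, "muscle", glcmConfig())
  for (P in mats) expect_equal(sum(P), 1)
  # quantization bounds are region-relative: adding a constant changes nothing
  h1 <- haralickFeatures(img, msk, "muscle")
  h2 <- haralickFeatures(img + 37, msk, "muscle")
  expect_equal(h1, h2)
  expect_gte(h1[["haralick_contrast"]], 0)

  # a single in-region pixel has no co-occurring pair
  one <- matrix(0L, 4, 4); one[2, 2] <- 1L
  expect_error(haralickFeatures(img[1:4, 1:4], one, "muscle"),
               class = "myoUS_insufficient_pairs_error")
})

test_that("feature assembly yields the named 22-vector and is deterministic", {
  st <- tinyStudy(nN = 1L, nIBM = 1L, muscles = "deltoid", views = 1L, px = 48L)
  v <- assembleFeatureVector(st@images[[1]], st@masks[[1]])
  expect_identical(names(v), featureNames22())
  expect_length(v, 22L)
  expect_true(all(is.finite(v)))
  # byte-identical image -> bit-identical features
  v2 <- assembleFeatureVector(st@images[[1]] + 0, st@masks[[1]])
  expect_identical(v, v2)

  # a missing fat region propagates as a tagged extraction error
  badmask <- st@masks[[1]]
  badmask[badmask == 2L] <- 0L
  st2 <- st
  st2@masks[[1]] <- badmask
  expect_error(extractFeatures(st2), "S001.*deltoid",
               class = "myoUS_feature_error")
})

test_that("extractFeatures builds a valid FeatureSet over a study", {
  st <- tinyStudy(nN = 2L, nIBM = 2L, muscles = "deltoid", views = 2L, px = 48L)
  fs <- extractFeatures(st)
  expect_s4_class(fs, "FeatureSet")
  expect_identical(dim(fs), c(22L, nRecords(st)))
  expect_identical(rownames(fs), featureNames22())
  expect_identical(SummarizedExperiment::colData(fs)$subject_id,
                   records(st)$subject_id)
  expect_true(all(is.finite(featureMatrix(fs))))
})
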