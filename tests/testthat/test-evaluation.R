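test_that("complement-mode episodes reproduce the 444-sample split sizes", {
  es <- generateEmbeddings(syntheticConfig(seed = 1))  # 444 samples, 4 classes
  for (k in c(4L, 8L, 16L)) {
    ep <- sampleEpisode(es, k, seed = 0)
    expect_identical(length(ep$trainIds), 4L * k)
    expect_identical(length(ep$testIds), 444L - 4L * k)
    expect_length(intersect(ep$trainIds, ep$testIds), 0)
    parts <- episodeSplit(es, ep)
    expect_identical(as.vector(table(sampleLabels(parts$train))),
                     rep(k, 4L))
  }
})

test_that("episode sampling is seeded and validates class sizes", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 3, dim = 8, totalSamples = 30,
    classProportions = c(0.5, 0.3, 0.2), seed = 2))
  e1 <- sampleEpisode(es, 2, seed = 7)
  e2 <- sampleEpisode(es, 2, seed = 7)
  expect_identical(e1$trainIds, e2$trainIds)
  expect_identical(e1$testIds, e2$testIds)
  expect_false(identical(sampleEpisode(es, 2, seed = 8)$trainIds,
                         e1$trainIds))
  # smallest class has 6 samples: k = 6 leaves no complement -> error names it
  expect_error(sampleEpisode(es, 6, seed = 0), "class3")
})

test_that("fixed_test mode evaluates against the provided set", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 2, dim = 8, totalSamples = 20,
    classProportions = c(0.5, 0.5), seed = 3))
  fixed <- generateEmbeddings(syntheticConfig(
    nClasses = 2, dim = 8, totalSamples = 10,
    classProportions = c(0.5, 0.5), seed = 4))
  ep <- sampleEpisode(es, 5, seed = 0, mode = "fixed_test", fixedTest = fixed)
  expect_identical(ep$testIds, sampleIds(fixed))
  parts <- episodeSplit(es, ep, fixedTest = fixed)
  expect_identical(ncol(parts$test), 10L)
  expect_error(sampleEpisode(es, 5, mode = "fixed_test"), "fixedTest")
})

test_that("computeMetrics matches hand-computed and oracle values", {
  expect_equal(computeMetrics(c("a", "b"), c("a", "b")),
               c(precision = 1, recall = 1, fscore = 1))
  # all predictions one class on a balanced 2-class set: macro recall 0.5
  m <- computeMetrics(c("a", "a", "b", "b"), rep("a", 4), "macro")
  expect_equal(unname(m["recall"]), 0.5)
  expect_equal(unname(m["precision"]), 0.25)  # classes contribute 0.5 and 0
  expect_error(computeMetrics("a", c("a", "b")), "length")
  expect_error(computeMetrics(character(), character()), "empty")
  expect_error(computeMetrics("a", "z", labels = c("a", "b")), "outside")

  for (seed in 1:15) {
    labs <- paste0("c", 1:sample(2:5, 1))
    n <- withr::with_seed(seed, sample(5:80, 1))
    true <- withr::with_seed(seed, sample(labs, n, replace = TRUE))
    pred <- withr::with_seed(seed + 500, sample(labs, n, replace = TRUE))
    for (avg in c("macro", "weighted", "micro")) {
      expect_equal(computeMetrics(true, pred, avg, labels = labs),
                   oracleMetrics(true, pred, avg, labels = labs),
                   tolerance = 1e-12)
    }
  }
})

test_that("micro precision, recall and F all equal accuracy", {
  true <- withr::with_seed(1, sample(c("x", "y", "z"), 50, replace = TRUE))
  pred <- withr::with_seed(2, sample(c("x", "y", "z"), 50, replace = TRUE))
  m <- computeMetrics(true, pred, "micro")
  acc <- mean(true == pred)
  expect_equal(unname(m), rep(acc, 3))
})

test_that("evaluateAveraged averages per-iteration metrics and is reproducible", {
  es <- generateEmbeddings(syntheticConfig(
    totalSamples = 120, dim = 16, withinClassNoise = 0.4, seed = 9))
  fm <- evaluateAveraged(es, "pt-snn", kShots = 4, mIterations = 3)
  per <- iterationMetrics(fm)
  expect_identical(dim(per), c(3L, 3L))
  expect_equal(meanMetrics(fm), colMeans(per))
  expect_true(all(meanMetrics(fm) >= apply(per, 2, min) - 1e-12))
  expect_true(all(meanMetrics(fm) <= apply(per, 2, max) + 1e-12))
  # exact reproduction on re-run, all 9 per-iteration numbers and the means
  fm2 <- evaluateAveraged(es, "pt-snn", kShots = 4, mIterations = 3)
  expect_identical(iterationMetrics(fm2), per)
  expect_identical(meanMetrics(fm2), meanMetrics(fm))

  one <- evaluateAveraged(es, "pt-snn", kShots = 4, mIterations = 1)
  expect_equal(meanMetrics(one), iterationMetrics(one)[1, ])
})

test_that("evaluateAveraged accepts a custom classifier function", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 2, dim = 8, totalSamples = 20,
    classProportions = c(0.5, 0.5), withinClassNoise = 0, seed = 5))
  majority <- function(train, testMat) {
    rep(names(which.max(table(sampleLabels(train))))[1], nrow(testMat))
  }
  fm <- evaluateAveraged(es, majority, kShots = 3, mIterations = 2)
  # balanced support: majority rule recalls exactly one of the two classes
  expect_equal(unname(meanMetrics(fm)["recall"]), 0.5)
})
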