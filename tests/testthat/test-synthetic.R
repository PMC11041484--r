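test_that("largest-remainder rounding reproduces the emulated class counts", {
  counts <- largestRemainderCounts(defaultClassProportions(), 444)
  expect_identical(counts, c(245L, 117L, 48L, 34L))
  expect_identical(sum(counts), 444L)
  # majority share matches the printed 55.2%
  expect_equal(round(100 * counts[1] / 444, 1), 55.2)
  # generic properties: always sums to total
  for (seed in 1:10) {
    p <- withr::with_seed(seed, {
      x <- runif(sample(2:6, 1))
      x / sum(x)
    })
    expect_identical(sum(largestRemainderCounts(p, 101L)), 101L)
  }
})

test_that("generated embeddings honor counts, centroids and the noise model", {
  es0 <- generateEmbeddings(syntheticConfig(withinClassNoise = 0, seed = 1))
  expect_identical(as.vector(table(sampleLabels(es0))[paste0("class", 1:4)]),
                   c(245L, 117L, 48L, 34L))
  m <- embeddingMatrix(es0)
  # zero noise: every sample sits on its unit-norm class centroid
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 444), tolerance = 1e-12)
  for (cl in paste0("class", 1:4)) {
    rows <- unname(m[sampleLabels(es0) == cl, , drop = FALSE])
    expect_equal(rows, rows[rep(1, nrow(rows)), , drop = FALSE],
                 tolerance = 1e-12)
  }
  # centroid separation respects the configured minimum angle (60 degrees)
  centroids <- unique(m)
  g <- cosineSimilarity(centroids, centroids)
  expect_lte(max(g[upper.tri(g)]), cos(60 * pi / 180) + 1e-9)

  # same config, different seed: same counts, different vectors
  es1 <- generateEmbeddings(syntheticConfig(withinClassNoise = 0, seed = 2))
  expect_identical(table(sampleLabels(es1)), table(sampleLabels(es0)))
  expect_false(isTRUE(all.equal(embeddingMatrix(es1), m)))
  # same seed: identical
  expect_identical(embeddingMatrix(
    generateEmbeddings(syntheticConfig(withinClassNoise = 0, seed = 1))), m)
})

test_that("an infeasible centroid-angle constraint fails with a clear error", {
  cfg <- syntheticConfig(nClasses = 12, dim = 2, totalSamples = 24,
                         classProportions = rep(1 / 12, 12),
                         minCentroidAngle = 100, seed = 1)
  expect_error(generateEmbeddings(cfg), "centroids")
})

test_that("the toy corpus is deterministic, imbalanced like the template, and separable", {
  cfg <- syntheticConfig(seed = 21)
  corpus <- generateToyCorpus(cfg)
  expect_identical(as.vector(table(corpus$label)[paste0("class", 1:4)]),
                   c(245L, 117L, 48L, 34L))
  expect_identical(generateToyCorpus(cfg), corpus)  # byte-identical

  # disjoint vocabularies: embed + PT-SNN solves a 1-shot episode perfectly
  cfg2 <- syntheticConfig(nClasses = 2, dim = 8, totalSamples = 24,
                          classProportions = c(0.5, 0.5), seed = 8)
  es <- embedCorpus(generateToyCorpus(cfg2), hashingBackend(dimension = 32))
  ep <- sampleEpisode(es, 1, seed = 0)
  parts <- episodeSplit(es, ep)
  pred <- classifyPT(parts$train, embeddingMatrix(parts$test))
  expect_identical(pred, sampleLabels(parts$test))
})

test_that("averaged PT-SNN F score decays as within-class noise grows", {
  meanF <- vapply(c(0.05, 0.6, 6), function(noise) {
    f <- vapply(1:5, function(seed) {
      es <- generateEmbeddings(syntheticConfig(
        totalSamples = 120, dim = 16, withinClassNoise = noise, seed = seed))
      meanMetrics(evaluateAveraged(es, "pt-snn", kShots = 4))["fscore"]
    }, numeric(1))
    mean(f)
  }, numeric(1))
  expect_lte(meanF[2], meanF[1] + 0.02)
  expect_lte(meanF[3], meanF[2] + 0.02)
})

test_that("syntheticConfig validates its fields", {
  expect_error(syntheticConfig(nClasses = 1))
  expect_error(syntheticConfig(totalSamples = 2, nClasses = 4))
  expect_error(syntheticConfig(classProportions = c(0.5, 0.5)))
  expect_error(syntheticConfig(withinClassNoise = -1))
})
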