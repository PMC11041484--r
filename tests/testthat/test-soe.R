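tinyConfig <- function(...) {
  encoderConfig(inputDim = 8L, hiddenDim = 4L, outputDim = 6L,
                chunkLength = 4L, epochs = 5L, seed = 3L, ...)
}

test_that("splitForSOE produces disjoint stratified halves deterministically", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 4, dim = 8, totalSamples = 32,
    classProportions = rep(0.25, 4), seed = 2))
  halves <- splitForSOE(es, seed = 1)
  expect_identical(ncol(halves$encoderHalf), 16L)
  expect_identical(ncol(halves$supportHalf), 16L)
  expect_identical(as.vector(table(sampleLabels(halves$encoderHalf))),
                   rep(4L, 4))
  expect_length(intersect(sampleIds(halves$encoderHalf),
                          sampleIds(halves$supportHalf)), 0)
  expect_setequal(c(sampleIds(halves$encoderHalf),
                    sampleIds(halves$supportHalf)), sampleIds(es))
  again <- splitForSOE(es, seed = 1)
  expect_identical(sampleIds(again$encoderHalf),
                   sampleIds(halves$encoderHalf))

  # odd per-class counts: the larger part goes to the encoder side
  odd <- EmbeddingSet(matrix(rnorm(5 * 4), 5, 4),
                      labels = c("a", "a", "a", "b", "b"))
  ho <- splitForSOE(odd, seed = 0)
  expect_identical(sum(sampleLabels(ho$encoderHalf) == "a"), 2L)
  expect_identical(sum(sampleLabels(ho$supportHalf) == "a"), 1L)
  expect_identical(sum(sampleLabels(ho$encoderHalf) == "b"), 1L)

  single <- EmbeddingSet(matrix(rnorm(8), 2, 4), labels = c("a", "b"))
  expect_error(splitForSOE(single), "fewer than 2")
})

test_that("pairSimilarity is sigmoid-of-distance, symmetric, in (0, 1)", {
  model <- initEncoder(tinyConfig())
  v <- withr::with_seed(5, rnorm(8))
  w <- withr::with_seed(6, rnorm(8))
  # identical inputs with cosine distance: sigma(1)
  expect_equal(pairSimilarity(model, v, v), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_identical(pairSimilarity(model, v, w), pairSimilarity(model, w, v))
  s <- pairSimilarity(model, v, w)
  expect_true(s > 0 && s < 1)
  expect_error(pairSimilarity(model, v, rnorm(7)), "dimension mismatch")
})

test_that("initialization and training are deterministic given the seed", {
  es <- separableTwoClassSet(perClass = 4)
  cfg <- tinyConfig()
  m1 <- trainEncoder(es, cfg)
  m2 <- trainEncoder(es, cfg)
  diffs <- mapply(function(a, b) max(abs(unlist(a) - unlist(b))),
                  m1@parameters, m2@parameters)
  expect_lt(max(diffs), 1e-6)
  expect_identical(m1@lossHistory, m2@lossHistory)
  # untrained scoring is a pure function of the seed
  u1 <- initEncoder(cfg)
  u2 <- initEncoder(cfg)
  v <- withr::with_seed(8, rnorm(8))
  w <- withr::with_seed(9, rnorm(8))
  expect_identical(pairSimilarity(u1, v, w), pairSimilarity(u2, v, w))
})

test_that("training separates same-class from different-class pairs", {
  es <- separableTwoClassSet(perClass = 4)
  cfg <- encoderConfig(inputDim = 8L, hiddenDim = 8L, chunkLength = 4L,
                       epochs = 60L, learningRate = 5e-3, seed = 1L)
  model <- trainEncoder(es, cfg)
  pt <- pairTable(makePairs(es))
  X <- embeddingMatrix(es)
  sims <- pairSimilarity(model, X[pt$i, , drop = FALSE],
                         X[pt$j, , drop = FALSE])
  expect_gt(mean(sims[pt$sameClass == 1]), mean(sims[pt$sameClass == 0]))
  # loss trend: the last quarter improves on the first quarter
  h <- model@lossHistory
  expect_lt(mean(tail(h, 15)), mean(head(h, 15)))
})

test_that("training preconditions are enforced", {
  es <- separableTwoClassSet(perClass = 4)
  expect_error(encoderConfig(inputDim = 8, epochs = 0), "epochs")
  oneClass <- EmbeddingSet(matrix(rnorm(32), 4, 8), labels = rep("a", 4))
  expect_error(trainEncoder(oneClass, tinyConfig()), "2 classes")
  expect_error(trainEncoder(es, encoderConfig(inputDim = 12)),
               "does not match")
})

test_that("encode has the declared shape and is deterministic", {
  model <- initEncoder(tinyConfig())
  X <- withr::with_seed(2, matrix(rnorm(10 * 8), 10, 8))
  e1 <- encode(model, X)
  expect_equal(dim(e1), c(10L, 6L))
  expect_identical(e1, encode(model, X))
  expect_error(encode(model, matrix(1, 2, 9)), "dimension mismatch")
})

test_that("the identity encoder reduces SOE classification to PT-SNN", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 3, dim = 12, totalSamples = 24,
    classProportions = rep(1 / 3, 3), withinClassNoise = 0.3, seed = 6))
  halves <- splitForSOE(es, seed = 0)
  idModel <- initEncoder(encoderConfig(inputDim = 12L,
                                       architecture = "identity"))
  test <- withr::with_seed(3, matrix(rnorm(9 * 12), 9, 12))
  expect_identical(classifySOE(idModel, halves$supportHalf, test),
                   classifyPT(halves$supportHalf, test))
})

test_that("trained SOE recovers noise-free clusters end to end", {
  es <- generateEmbeddings(syntheticConfig(
    nClasses = 4, dim = 16, totalSamples = 48,
    classProportions = rep(0.25, 4), withinClassNoise = 0, seed = 10))
  ep <- sampleEpisode(es, 4, seed = 0)
  parts <- episodeSplit(es, ep)
  halves <- splitForSOE(parts$train, seed = 0)
  cfg <- encoderConfig(inputDim = 16L, hiddenDim = 16L, chunkLength = 4L,
                       epochs = 50L, seed = 0L)
  model <- trainEncoder(halves$encoderHalf, cfg)
  pred <- classifySOE(model, halves$supportHalf,
                      embeddingMatrix(parts$test))
  expect_identical(pred, sampleLabels(parts$test))
})

test_that("SOE accuracy beats chance and does not degrade with more epochs", {
  accAt <- function(epochs, seed) {
    es <- generateEmbeddings(syntheticConfig(
      nClasses = 4, dim = 16, totalSamples = 40,
      classProportions = rep(0.25, 4), withinClassNoise = 0.15,
      seed = seed))
    ep <- sampleEpisode(es, 4, seed = seed)
    parts <- episodeSplit(es, ep)
    halves <- splitForSOE(parts$train, seed = seed)
    cfg <- encoderConfig(inputDim = 16L, hiddenDim = 8L, chunkLength = 4L,
                         epochs = epochs, seed = seed)
    model <- trainEncoder(halves$encoderHalf, cfg)
    pred <- classifySOE(model, halves$supportHalf,
                        embeddingMatrix(parts$test))
    mean(pred == sampleLabels(parts$test))
  }
  short <- vapply(1:5, function(s) accAt(2L, s), numeric(1))
  long <- vapply(1:5, function(s) accAt(40L, s), numeric(1))
  expect_gt(mean(long), 0.25)        # above 4-class chance
  expect_gte(mean(long), mean(short) - 0.02)  # no degradation on average
})

test_that("binary cross-entropy at a 0.5 prediction is ln 2 per pair", {
  bce <- fewshotSNN:::bceLoss
  expect_equal(bce(rep(0.5, 10), rep(c(0, 1), 5)), log(2), tolerance = 1e-12)
  expect_equal(bce(0.5, 1), log(2), tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- encoderConfig(inputDim = 8L, hiddenDim = 3L, outputDim = 4L,
                       chunkLength = 4L, seed = 7L)
  model <- initEncoder(cfg)
  X <- withr::with_seed(1, matrix(rnorm(5 * 8), 5, 8))
  pt <- pairTable(makePairs(c("a", "b", "a", "b", "a")))
  fwd <- fewshotSNN:::encoderForward
  bwd <- fewshotSNN:::encoderBackward
  plg <- fewshotSNN:::pairLossGradient
  lossOf <- function(params) {
    m <- model
    m@parameters <- params
    fp <- fwd(m, X, keepCache = FALSE)
    plg(fp$e, pt$i, pt$j, pt$sameClass, cfg@distance)$loss
  }
  fp <- fwd(model, X, keepCache = TRUE)
  pg <- plg(fp$e, pt$i, pt$j, pt$sameClass, cfg@distance)
  gr <- bwd(model, fp, pg$dE)
  p0 <- model@parameters
  flatten <- function(x) unlist(x, use.names = FALSE)
  theta <- flatten(p0)
  analytic <- flatten(gr[c("fwd", "bwd", "Wp", "bp")])
  relist <- function(v) utils::relist(v, p0)
  idx <- withr::with_seed(4, sample(length(theta), 25))
  eps <- 1e-6
  numeric_g <- vapply(idx, function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + eps
    tm[k] <- tm[k] - eps
    (lossOf(relist(tp)) - lossOf(relist(tm))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(numeric_g - analytic[idx])), 1e-7)
})

test_that("the negative-Euclidean distance option trains and scores symmetrically", {
  es <- separableTwoClassSet(perClass = 3)
  cfg <- encoderConfig(inputDim = 8L, hiddenDim = 4L, chunkLength = 4L,
                       epochs = 10L, seed = 2L,
                       distance = "negative_euclidean")
  model <- trainEncoder(es, cfg)
  v <- withr::with_seed(12, rnorm(8))
  w <- withr::with_seed(13, rnorm(8))
  expect_identical(pairSimilarity(model, v, w), pairSimilarity(model, w, v))
  expect_equal(pairSimilarity(model, v, v), 0.5, tolerance = 1e-9)
})
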