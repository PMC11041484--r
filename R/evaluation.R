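# Episodic N-way-K-shot evaluation with M-iteration metric averaging:
# iteration Idx draws a seeded K-shot support set (seed = Idx, 0-based),
# classifies the remaining samples (or a fixed test set), and precision /
# recall / F are averaged over the M iterations.

#' Sample one N-way-K-shot episode
#'
#' Draws exactly `kShots` samples per class without replacement using the
#' given seed. In `"complement"` mode the test set is every sample not
#' drawn (so n total samples give train NK / test n - NK); in
#' `"fixed_test"` mode the test set is the provided `fixedTest`.
#'
#' @param data [EmbeddingSet-class] to draw the support set from.
#' @param kShots Shots per class K.
#' @param seed Integer seed; identical seeds give identical episodes.
#' @param mode `"complement"` (default) or `"fixed_test"`.
#' @param fixedTest [EmbeddingSet-class], required in `"fixed_test"` mode.
#' @return An object of class `"Episode"`: a list with `kShots`, `nClasses`,
#'   `seed`, `mode`, `trainIds`, `testIds`.
#' @export
sampleEpisode <- function(data, kShots, seed = 0L,
                          mode = c("complement", "fixed_test"),
                          fixedTest = NULL) {
  mode <- match.arg(mode)
  stopifnot(methods::is(data, "EmbeddingSet"))
  kShots <- as.integer(kShots)
  if (kShots < 1L) stop("kShots must be >= 1")
  labs <- sampleLabels(data)
  ids <- sampleIds(data)
  classes <- classOrder(data)
  need <- kShots + if (mode == "complement") 1L else 0L
  counts <- table(labs)
  short <- classes[counts[classes] < need]
  if (length(short))
    stop("class(es) with fewer than ", need, " samples: ",
         paste(short, collapse = ", "))
  trainIds <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) sample(ids[labs == cl], kShots)),
           use.names = FALSE)
  })
  testIds <- if (mode == "complement") setdiff(ids, trainIds)
             else sampleIds(fixedTestCheck(fixedTest))
  structure(list(kShots = kShots, nClasses = length(classes),
                 seed = as.integer(seed), mode = mode,
                 trainIds = trainIds, testIds = testIds),
            class = "Episode")
}

fixedTestCheck <- function(fixedTest) {
  if (!methods::is(fixedTest, "EmbeddingSet"))
    stop("fixed_test mode requires an EmbeddingSet in 'fixedTest'")
  fixedTest
}

#' @export
print.Episode <- function(x, ...) {
  cat("Episode (seed ", x$seed, ", ", x$mode, "): ", x$nClasses, "-way ",
      x$kShots, "-shot; |train| = ", length(x$trainIds),
      ", |test| = ", length(x$testIds), "\n", sep = "")
  invisible(x)
}

#' Materialize an episode's train/test embedding sets
#'
#' @param data The [EmbeddingSet-class] the episode was sampled from.
#' @param episode An `"Episode"`.
#' @param fixedTest The fixed test [EmbeddingSet-class] when the episode's
#'   mode is `"fixed_test"`.
#' @return List with [EmbeddingSet-class] elements `train` and `test`.
#' @export
episodeSplit <- function(data, episode, fixedTest = NULL) {
  stopifnot(inherits(episode, "Episode"))
  test <- if (episode$mode == "complement") subsetSamples(data, episode$testIds)
          else subsetSamples(fixedTestCheck(fixedTest), episode$testIds)
  list(train = subsetSamples(data, episode$trainIds), test = test)
}

#' Multi-class precision, recall and F score
#'
#' Confusion-matrix based precision/recall/F1 under macro (unweighted mean
#' over classes), weighted (support-weighted mean) or micro (pooled counts;
#' equal to accuracy) averaging. A class never predicted contributes
#' precision 0; a class with no F-denominator contributes F 0.
#'
#' @param trueLabels,predictedLabels Equal-length label vectors.
#' @param averaging `"macro"` (default), `"weighted"` or `"micro"`.
#' @param labels Optional character vector fixing the class set; defaults to
#'   the sorted union of both inputs.
#' @return Named numeric vector `c(precision, recall, fscore)` in `[0, 1]`.
#' @export
computeMetrics <- function(trueLabels, predictedLabels,
                           averaging = c("macro", "weighted", "micro"),
                           labels = NULL) {
  averaging <- match.arg(averaging)
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors differ in length: ", length(trueLabels), " vs ",
         length(predictedLabels))
  if (length(trueLabels) == 0L) stop("empty input")
  if (is.null(labels)) labels <- sort(unique(c(trueLabels, predictedLabels)))
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), labels)
  if (length(unknown))
    stop("label(s) outside the declared set: ", paste(unknown, collapse = ", "))
  cm <- table(factor(trueLabels, levels = labels),
              factor(predictedLabels, levels = labels))
  tp <- diag(cm)
  predN <- colSums(cm)
  trueN <- rowSums(cm)
  if (averaging == "micro") {
    acc <- sum(tp) / sum(cm)
    return(c(precision = acc, recall = acc, fscore = acc))
  }
  prec <- ifelse(predN > 0, tp / predN, 0)
  rec <- ifelse(trueN > 0, tp / trueN, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (averaging == "macro") rep(1 / length(labels), length(labels))
       else trueN / sum(trueN)
  c(precision = sum(w * prec), recall = sum(w * rec), fscore = sum(w * f1))
}

resolveClassifier <- function(method, encoderConfig = NULL) {
  if (is.function(method)) {
    f <- method
    if (length(formals(f)) >= 3L) return(f)
    return(function(train, testMat, seed) f(train, testMat))
  }
  method <- match.arg(method, c("pt-snn", "soe-snn"))
  if (method == "pt-snn") {
    function(train, testMat, seed) classifyPT(train, testMat)
  } else {
    function(train, testMat, seed) {
      halves <- splitForSOE(train, seed = seed)
      cfg <- encoderConfig
      if (is.null(cfg))
        cfg <- fewshotSNN::encoderConfig(inputDim = ncol(testMat))
      model <- trainEncoder(halves$encoderHalf, cfg)
      classifySOE(model, halves$supportHalf, testMat)
    }
  }
}

#' Episodic evaluation with M-iteration averaging
#'
#' Runs `mIterations` seeded episodes (iteration Idx uses seed
#' `baseSeed + Idx`, Idx = 0 .. M-1), classifies each episode's test set with
#' the chosen method, and averages precision/recall/F over iterations.
#'
#' @param data [EmbeddingSet-class] of labeled embeddings.
#' @param method `"pt-snn"`, `"soe-snn"`, or a function
#'   `f(train, testMatrix, seed)` returning predicted labels.
#' @param kShots Shots per class K.
#' @param mIterations Number of averaging iterations M (default 3).
#' @param averaging Metric averaging scheme, see [computeMetrics()].
#' @param mode,fixedTest Episode mode, see [sampleEpisode()].
#' @param encoderConfig Optional [EncoderConfig-class] for `"soe-snn"`.
#' @param baseSeed Offset added to the 0-based iteration index to form each
#'   episode seed (default 0, i.e. seeds 0 .. M-1).
#' @return A [FewShotMetrics-class].
#' @export
evaluateAveraged <- function(data, method, kShots, mIterations = 3L,
                             averaging = c("macro", "weighted", "micro"),
                             mode = c("complement", "fixed_test"),
                             fixedTest = NULL, encoderConfig = NULL,
                             baseSeed = 0L) {
  averaging <- match.arg(averaging)
  mode <- match.arg(mode)
  mIterations <- as.integer(mIterations)
  if (mIterations < 1L) stop("mIterations must be >= 1")
  classifier <- resolveClassifier(method, encoderConfig)
  classes <- classOrder(data)
  per <- matrix(NA_real_, mIterations, 3L,
                dimnames = list(NULL, c("precision", "recall", "fscore")))
  for (idx in seq_len(mIterations) - 1L) {
    seed <- as.integer(baseSeed) + idx
    ep <- sampleEpisode(data, kShots, seed = seed, mode = mode,
                        fixedTest = fixedTest)
    parts <- episodeSplit(data, ep, fixedTest = fixedTest)
    pred <- classifier(parts$train, embeddingMatrix(parts$test), seed)
    per[idx + 1L, ] <- computeMetrics(sampleLabels(parts$test), pred,
                                      averaging = averaging, labels = classes)
  }
  methods::new("FewShotMetrics", perIteration = per, mean = colMeans(per),
               kShots = as.integer(kShots), mIterations = mIterations,
               averaging = averaging)
}
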