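# Independent scalar oracles and tiny fixtures shared across test files.
# Everything here is deliberately loop-based and framework-free so it stays
# independent of the vectorized implementation paths it checks.

scalarCosine <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# per-test-sample, per-class mean cosine similarity by explicit double loop
oracleClassScores <- function(trainMat, trainLabels, testMat) {
  classes <- sort(unique(trainLabels))
  out <- matrix(NA_real_, nrow(testMat), length(classes),
                dimnames = list(NULL, classes))
  for (t in seq_len(nrow(testMat))) {
    for (ci in seq_along(classes)) {
      rows <- which(trainLabels == classes[ci])
      sims <- vapply(rows, function(r)
        scalarCosine(testMat[t, ], trainMat[r, ]), numeric(1))
      out[t, ci] <- mean(sims)
    }
  }
  out
}

# confusion-matrix precision/recall/F by explicit per-class loops
oracleMetrics <- function(true, pred, averaging, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(true, pred)))
  tp <- fp <- fn <- setNames(numeric(length(labels)), labels)
  for (i in seq_along(true)) {
    if (true[i] == pred[i]) tp[true[i]] <- tp[true[i]] + 1
    else {
      fp[pred[i]] <- fp[pred[i]] + 1
      fn[true[i]] <- fn[true[i]] + 1
    }
  }
  if (averaging == "micro") {
    acc <- sum(tp) / length(true)
    return(c(precision = acc, recall = acc, fscore = acc))
  }
  prec <- rec <- f1 <- setNames(numeric(length(labels)), labels)
  for (l in labels) {
    prec[l] <- if (tp[l] + fp[l] > 0) tp[l] / (tp[l] + fp[l]) else 0
    rec[l] <- if (tp[l] + fn[l] > 0) tp[l] / (tp[l] + fn[l]) else 0
    f1[l] <- if (prec[l] + rec[l] > 0)
      2 * prec[l] * rec[l] / (prec[l] + rec[l]) else 0
  }
  w <- if (averaging == "macro") rep(1 / length(labels), length(labels))
       else as.numeric(table(factor(true, levels = labels))) / length(true)
  c(precision = sum(w * prec), recall = sum(w * rec), fscore = sum(w * f1))
}

# small random labeled instance for oracle-equivalence loops
randomInstance <- function(seed, nTrain = NULL, nTest = NULL, d = NULL,
                           nClasses = NULL) {
  withr::with_seed(seed, {
    if (is.null(nClasses)) nClasses <- sample(2:4, 1)
    if (is.null(nTrain)) nTrain <- sample(nClasses:64, 1)
    if (is.null(nTest)) nTest <- sample(1:64, 1)
    if (is.null(d)) d <- sample(2:32, 1)
    labels <- paste0("c", c(seq_len(nClasses),
                            sample(nClasses, nTrain - nClasses, replace = TRUE)))
    list(trainMat = matrix(rnorm(nTrain * d), nTrain, d),
         labels = labels,
         testMat = matrix(rnorm(nTest * d), nTest, d))
  })
}

# two tight, well-separated class clusters in the plane
separableTwoClassSet <- function(perClass = 4, d = 8, seed = 11) {
  withr::with_seed(seed, {
    c1 <- c(1, rep(0, d - 1))
    c2 <- c(0, 1, rep(0, d - 2))
    X <- rbind(
      matrix(rep(c1, perClass), ncol = d, byrow = TRUE),
      matrix(rep(c2, perClass), ncol = d, byrow = TRUE)
    ) + matrix(rnorm(2 * perClass * d, sd = 0.01), 2 * perClass, d)
    EmbeddingSet(X, labels = rep(c("a", "b"), each = perClass))
  })
}
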