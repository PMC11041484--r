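# PT-SNN: classification of test embeddings by mean per-class cosine
# similarity to a frozen support set. Fully vectorized: L2-normalize both
# sides, take the inner-product similarity table, and average per class by
# multiplying with the L1-normalized one-hot label table.

asTestMatrix <- function(testVectors, d) {
  if (methods::is(testVectors, "EmbeddingSet"))
    testVectors <- embeddingMatrix(testVectors)
  if (is.null(dim(testVectors))) testVectors <- matrix(testVectors, nrow = 1L)
  testVectors <- as.matrix(testVectors)
  if (ncol(testVectors) != d)
    stop("dimension mismatch: test vectors are ", nrow(testVectors), "x",
         ncol(testVectors), " but train embeddings have dimension ", d)
  testVectors
}

#' Mean per-class cosine-similarity scores
#'
#' For every test vector, the arithmetic mean of its cosine similarities to
#' all support (train) samples of each class. Computed vectorized as
#' `S %*% t(L)` where `S` is the n_test x n_train inner-product table of the
#' L2-normalized rows and `L` the row-L1-normalized one-hot class-by-sample
#' label table.
#'
#' @param train [EmbeddingSet-class] support set (every declared class must
#'   have at least one sample).
#' @param testVectors Numeric matrix of test embeddings (rows), a single
#'   vector, or an [EmbeddingSet-class].
#' @return n_test x N numeric matrix of mean similarities; columns named and
#'   ordered by [classOrder()] of `train`.
#' @examples
#' tr <- EmbeddingSet(rbind(c(1, 0), c(0, 1)), labels = c("a", "b"))
#' classScores(tr, c(1, 0))  # a = 1, b = 0
#' @export
classScores <- function(train, testVectors) {
  stopifnot(methods::is(train, "EmbeddingSet"))
  trainMat <- embeddingMatrix(train)
  test <- asTestMatrix(testVectors, ncol(trainMat))
  labs <- sampleLabels(train)
  classes <- classOrder(train)
  if (length(classes) < 1L) stop("no classes in training set")
  s <- l2Normalize(test) %*% t(l2Normalize(trainMat))
  oneHot <- outer(classes, labs, "==") * 1          # N x n_train
  oneHot <- oneHot / rowSums(oneHot)                # L1-normalize class rows
  scores <- s %*% t(oneHot)
  colnames(scores) <- classes
  rownames(scores) <- rownames(test)
  scores
}

#' Classify by highest mean class similarity
#'
#' Assigns each test vector the class with the largest mean cosine
#' similarity; exact ties go to the class earliest in [classOrder()].
#' The k-NN-like decision rule: a test sample whose mean similarities to two
#' classes are 0.2 and 0.6 is assigned the 0.6 class.
#'
#' @inheritParams classScores
#' @return Character vector of predicted labels, one per test row.
#' @export
classifyPT <- function(train, testVectors) {
  scores <- classScores(train, testVectors)
  argmaxLabels(scores)
}

# deterministic argmax over a named score matrix; ties -> first column
argmaxLabels <- function(scores) {
  colnames(scores)[max.col(scores, ties.method = "first")]
}
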