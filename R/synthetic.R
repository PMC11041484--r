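# Synthetic class-conditional embedding data emulating the statistical
# structure the classifiers assume: class centroids on the unit hypersphere
# (cosine geometry carries the signal), isotropic within-class noise, and a
# heavily imbalanced label distribution mirroring a 444-sentence clinical
# corpus with majority share 55.2% (class counts 245/117/48/34).

#' Default imbalanced class proportions
#'
#' The printed percentage distribution of the 4-class clinical sentence
#' data set this generator emulates (55.2 / 26.4 / 10.8 / 7.7, renormalized
#' to sum to 1).
#'
#' @return Numeric simplex vector of length 4.
#' @export
defaultClassProportions <- function() {
  p <- c(0.552, 0.264, 0.108, 0.077)
  p / sum(p)
}

#' Synthetic-data configuration
#'
#' @param nClasses Number of classes N (default 4).
#' @param dim Embedding dimension (default 64).
#' @param totalSamples Total sample count (default 444).
#' @param classProportions Simplex vector of length `nClasses` (default
#'   [defaultClassProportions()] for 4 classes, uniform otherwise).
#' @param withinClassNoise Standard deviation of the isotropic Gaussian
#'   noise around each centroid (default 0.25; 0 collapses every sample
#'   onto its class centroid).
#' @param minCentroidAngle Minimum pairwise angle between class centroids in
#'   degrees (default 60).
#' @param seed Integer seed (default 1).
#' @return An object of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nClasses = 4L, dim = 64L, totalSamples = 444L,
                            classProportions = NULL, withinClassNoise = 0.25,
                            minCentroidAngle = 60, seed = 1L) {
  nClasses <- as.integer(nClasses)
  dim <- as.integer(dim)
  totalSamples <- as.integer(totalSamples)
  if (is.null(classProportions)) {
    classProportions <- if (nClasses == 4L) defaultClassProportions()
                        else rep(1 / nClasses, nClasses)
  }
  classProportions <- classProportions / sum(classProportions)
  stopifnot(nClasses >= 2L, dim >= 2L, totalSamples >= nClasses,
            length(classProportions) == nClasses,
            all(classProportions > 0),
            abs(sum(classProportions) - 1) <= 1e-9,
            withinClassNoise >= 0, minCentroidAngle >= 0,
            minCentroidAngle < 180)
  structure(list(nClasses = nClasses, dim = dim, totalSamples = totalSamples,
                 classProportions = classProportions,
                 withinClassNoise = withinClassNoise,
                 minCentroidAngle = minCentroidAngle,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat("SyntheticConfig: ", x$totalSamples, " samples, ", x$nClasses,
      " classes, dim ", x$dim, ", noise ", x$withinClassNoise, "\n", sep = "")
  invisible(x)
}

#' Largest-remainder apportionment of class counts
#'
#' Rounds `proportions * total` to integers that sum exactly to `total`:
#' floors first, then the classes with the largest fractional remainders
#' receive the leftover units. The default 4-class proportions at total 444
#' give counts 245, 117, 48, 34.
#'
#' @param proportions Simplex vector (renormalized if needed).
#' @param total Positive integer total.
#' @return Integer vector of per-class counts summing to `total`.
#' @examples
#' largestRemainderCounts(defaultClassProportions(), 444)
#' @export
largestRemainderCounts <- function(proportions, total) {
  total <- as.integer(total)
  stopifnot(total >= 1L, all(proportions >= 0), sum(proportions) > 0)
  proportions <- proportions / sum(proportions)
  raw <- proportions * total
  counts <- floor(raw)
  leftover <- total - sum(counts)
  if (leftover > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(leftover)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# rejection-sample nClasses unit vectors with pairwise angle >= minAngle
sampleCentroids <- function(nClasses, dim, minAngle, maxTries = 1000L) {
  maxCos <- cos(minAngle * pi / 180)
  for (try in seq_len(maxTries)) {
    c0 <- l2Normalize(matrix(stats::rnorm(nClasses * dim), nClasses, dim))
    g <- c0 %*% t(c0)
    if (all(g[upper.tri(g)] <= maxCos + 1e-12)) return(c0)
  }
  stop("could not place ", nClasses, " centroids at pairwise angle >= ",
       minAngle, " degrees in dimension ", dim, " after ", maxTries, " tries")
}

#' Generate a synthetic labeled embedding set
#'
#' Class centroids are drawn on the unit hypersphere with pairwise angle at
#' least `minCentroidAngle`; each sample is its class centroid plus
#' isotropic Gaussian noise of scale `withinClassNoise`. Per-class counts
#' follow [largestRemainderCounts()]. Fully deterministic given the seed.
#'
#' @param config A `"SyntheticConfig"` from [syntheticConfig()].
#' @return An [EmbeddingSet-class] with labels `class1 ... classN`.
#' @export
generateEmbeddings <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  counts <- largestRemainderCounts(config$classProportions, config$totalSamples)
  withr::with_seed(config$seed, {
    centroids <- sampleCentroids(config$nClasses, config$dim,
                                 config$minCentroidAngle)
    labels <- rep(paste0("class", seq_len(config$nClasses)), counts)
    X <- centroids[rep(seq_len(config$nClasses), counts), , drop = FALSE]
    if (config$withinClassNoise > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = config$withinClassNoise),
                      nrow(X), ncol(X))
    EmbeddingSet(X, labels = labels,
                 ids = sprintf("s%04d", seq_len(nrow(X))))
  })
}

#' Generate a toy labeled text corpus
#'
#' Builds texts from disjoint class-specific token pools, so the
#' deterministic [hashingBackend()] maps different classes to well-separated
#' regions of embedding space. Class counts follow the configured
#' proportions exactly; byte-identical output for a given seed.
#'
#' @param config A `"SyntheticConfig"`.
#' @param vocabularyPerClass Tokens in each class's private vocabulary
#'   (default 20).
#' @param wordsPerText Length range of each text in tokens (default 5 to 12).
#' @return A `data.frame` with columns `id`, `text`, `label`.
#' @export
generateToyCorpus <- function(config, vocabularyPerClass = 20L,
                              wordsPerText = c(5L, 12L)) {
  stopifnot(inherits(config, "SyntheticConfig"), vocabularyPerClass >= 1L)
  counts <- largestRemainderCounts(config$classProportions, config$totalSamples)
  withr::with_seed(config$seed, {
    vocab <- lapply(seq_len(config$nClasses), function(cl)
      sprintf("c%dtok%02d", cl, seq_len(vocabularyPerClass)))
    rows <- lapply(seq_len(config$nClasses), function(cl) {
      texts <- vapply(seq_len(counts[cl]), function(i) {
        len <- sample(seq(wordsPerText[1L], wordsPerText[2L]), 1L)
        paste(sample(vocab[[cl]], len, replace = TRUE), collapse = " ")
      }, character(1L))
      data.frame(text = texts, label = paste0("class", cl))
    })
    corpus <- do.call(rbind, rows)
    corpus <- cbind(id = sprintf("t%04d", seq_len(nrow(corpus))), corpus)
    rownames(corpus) <- NULL
    corpus
  })
}
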