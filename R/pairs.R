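# Siamese-style pair augmentation: NK labeled samples become all
# ((NK)^2 - NK)/2 unique unordered pairs with a same/different-class flag.

#' Number of unique sample pairs under N-way-K-shot augmentation
#'
#' With NK training samples, the number of unordered pairs (i < j) is
#' ((NK)^2 - NK) / 2; e.g. 8 samples yield 28 pairs and 16 samples 120.
#'
#' @param nClasses Number of classes N (>= 1).
#' @param kShots Samples per class K (>= 1).
#' @return Integer pair count.
#' @examples
#' pairCount(1, 8)   # 28
#' pairCount(4, 4)   # 120
#' @export
pairCount <- function(nClasses, kShots) {
  nClasses <- as.integer(nClasses)
  kShots <- as.integer(kShots)
  if (is.na(nClasses) || is.na(kShots) || nClasses < 1L || kShots < 1L)
    stop("nClasses and kShots must be positive integers")
  nk <- nClasses * kShots
  (nk * nk - nk) %/% 2L
}

#' Data-augmentation factor of pair enumeration
#'
#' Ratio of pair count to sample count, `(NK - 1) / 2`: 8 samples give a
#' 3.5-fold augmentation, 16 samples a 7.5-fold one.
#'
#' @inheritParams pairCount
#' @return Numeric augmentation factor.
#' @export
augmentationFactor <- function(nClasses, kShots) {
  nk <- as.integer(nClasses) * as.integer(kShots)
  pairCount(nClasses, kShots) / nk
}

#' @describeIn makePairs Exhaustive unique pairs of an `EmbeddingSet`, in
#'   lexicographic (i, j) order, with `sameClass = 1` iff the two samples
#'   share a label.
#' @export
setMethod("makePairs", "EmbeddingSet", function(x, ...) {
  labelsToPairs(sampleLabels(x))
})

#' @describeIn makePairs Pairs from a bare label vector.
#' @export
setMethod("makePairs", "character", function(x, ...) labelsToPairs(x))

labelsToPairs <- function(labels) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 samples to form pairs (got ", n, ")")
  idx <- t(utils::combn(n, 2L))  # already lexicographic in (i, j)
  same <- as.integer(labels[idx[, 1L]] == labels[idx[, 2L]])
  methods::new("PairSet",
    pairs = S4Vectors::DataFrame(i = as.integer(idx[, 1L]),
                                 j = as.integer(idx[, 2L]),
                                 sameClass = same),
    sourceSize = as.integer(n))
}

#' Write / read a PairSet as TSV
#'
#' Plain `i <TAB> j <TAB> sameClass` with a header row.
#'
#' @param x A [PairSet-class].
#' @param path File path.
#' @return `writePairs` returns `path` invisibly; `readPairs` a [PairSet-class].
#' @export
writePairs <- function(x, path) {
  stopifnot(methods::is(x, "PairSet"))
  df <- pairTable(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairs
#' @param sourceSize Sample count the pairs came from; inferred as
#'   `max(j)` when omitted.
#' @export
readPairs <- function(path, sourceSize = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(sourceSize)) sourceSize <- max(df$j)
  methods::new("PairSet",
    pairs = S4Vectors::DataFrame(i = as.integer(df$i), j = as.integer(df$j),
                                 sameClass = as.integer(df$sameClass)),
    sourceSize = as.integer(sourceSize))
}
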