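#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

# ---------------------------------------------------------------------------
# EmbeddingSet
# ---------------------------------------------------------------------------

#' EmbeddingSet: labeled sentence embeddings
#'
#' An n-sample set of d-dimensional first-order sentence embeddings with
#' aligned class labels and stable sample identifiers, stored as a
#' `SummarizedExperiment` whose single assay holds the d x n matrix
#' (features in rows, samples in columns, the Bioconductor convention);
#' [embeddingMatrix()] returns the transposed n x d view used by the
#' classifiers. Labels live in `colData(x)$label`.
#'
#' @slot .Data see `SummarizedExperiment`.
#' @seealso [EmbeddingSet()], [embeddingMatrix()], [sampleLabels()]
#' @export
setClass("EmbeddingSet", contains = "SummarizedExperiment")

setValidity("EmbeddingSet", function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("EmbeddingSet must carry one 'embedding' assay")
  m <- SummarizedExperiment::assay(object, "embedding")
  if (!is.numeric(m)) msg <- c(msg, "embedding assay must be numeric")
  if (ncol(object) < 1L) msg <- c(msg, "at least one sample (n >= 1) required")
  if (nrow(object) < 1L) msg <- c(msg, "at least one dimension (d >= 1) required")
  if (any(!is.finite(m))) msg <- c(msg, "embedding matrix contains NaN/Inf/NA entries")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingSet
#'
#' @param vectors Numeric n x d matrix, one row per sample; all entries finite.
#' @param labels Length-n vector of class labels (coerced to character).
#' @param ids Optional length-n character vector of unique sample ids;
#'   defaults to `s1 ... sn`.
#' @return An [EmbeddingSet-class] object.
#' @examples
#' es <- EmbeddingSet(matrix(rnorm(20), 5, 4), labels = c("a", "a", "b", "b", "b"))
#' embeddingMatrix(es)
#' sampleLabels(es)
#' @export
EmbeddingSet <- function(vectors, labels, ids = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  n <- nrow(vectors)
  if (length(labels) != n)
    stop("length(labels) [", length(labels), "] must equal nrow(vectors) [", n, "]")
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal nrow(vectors)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = t(vectors)),
    colData = S4Vectors::DataFrame(label = as.character(labels), row.names = ids)
  )
  rownames(se) <- paste0("d", seq_len(ncol(vectors)))
  methods::new("EmbeddingSet", se)
}

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "EmbeddingSet", function(x) {
  t(SummarizedExperiment::assay(x, "embedding"))
})

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "EmbeddingSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$label)
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "EmbeddingSet", function(x) colnames(x))

#' @rdname classOrder
#' @export
setMethod("classOrder", "EmbeddingSet", function(x) sort(unique(sampleLabels(x))))

setMethod("show", "EmbeddingSet", function(object) {
  labs <- sampleLabels(object)
  cat("EmbeddingSet with", ncol(object), "samples x", nrow(object), "dimensions\n")
  cat("classes (", length(unique(labs)), "): ",
      paste(utils::head(sort(unique(labs)), 6), collapse = ", "), "\n", sep = "")
})

# subset by sample ids, preserving class
subsetSamples <- function(es, ids) {
  stopifnot(all(ids %in% sampleIds(es)))
  es[, match(ids, sampleIds(es))]
}

# ---------------------------------------------------------------------------
# PairSet
# ---------------------------------------------------------------------------

#' PairSet: exhaustive unique sample pairs
#'
#' The Siamese-style augmented training set: all unordered pairs (i < j) of
#' samples with a binary same-class flag. Built by [makePairs()].
#'
#' @slot pairs A `DataFrame` with integer columns `i`, `j` and binary
#'   `sameClass`, in lexicographic (i, j) order.
#' @slot sourceSize Number of samples NK the pairs were built from.
#' @seealso [makePairs()], [pairCount()]
#' @export
setClass("PairSet",
  representation(pairs = "DataFrame", sourceSize = "integer"))

setValidity("PairSet", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("i", "j", "sameClass") %in% colnames(p)))
    return("pairs must have columns i, j, sameClass")
  if (nrow(p)) {
    if (any(p$i >= p$j)) msg <- c(msg, "pairs must satisfy i < j")
    if (anyDuplicated(paste(p$i, p$j))) msg <- c(msg, "duplicate (i, j) pair")
    if (!all(p$sameClass %in% c(0L, 1L))) msg <- c(msg, "sameClass must be 0/1")
    if (max(p$j) > object@sourceSize) msg <- c(msg, "pair index exceeds sourceSize")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairSet", function(object) {
  p <- object@pairs
  cat("PairSet:", nrow(p), "unique pairs from", object@sourceSize, "samples (",
      sum(p$sameClass == 1L), "same-class /", sum(p$sameClass == 0L),
      "different-class )\n")
})

#' @describeIn PairSet-class number of pairs.
#' @param x,... see generic.
#' @export
setMethod("length", "PairSet", function(x) nrow(x@pairs))

#' Pairs accessor
#'
#' @param x A [PairSet-class].
#' @return A `data.frame` with columns `i`, `j`, `sameClass`.
#' @export
pairTable <- function(x) {
  stopifnot(methods::is(x, "PairSet"))
  as.data.frame(x@pairs)
}

# ---------------------------------------------------------------------------
# EncoderConfig / EncoderModel
# ---------------------------------------------------------------------------

#' Configuration of the second-order Siamese encoder
#'
#' Hyperparameters of the trainable encoder stacked on frozen first-order
#' embeddings. The d-dimensional input vector is viewed as a sequence of
#' `chunkLength` segments of size `d / chunkLength` so the bidirectional
#' LSTM sees a genuine sequence; `chunkLength` must divide `inputDim`.
#'
#' @slot inputDim,hiddenDim,outputDim Integer layer sizes.
#' @slot chunkLength Integer number of sequence steps the input is cut into.
#' @slot epochs,batchSize Integer training-loop sizes; `batchSize = 0L` means
#'   full batch (all pairs at once, the few-shot default).
#' @slot learningRate,weightDecay Positive reals for the AdamW optimizer.
#' @slot seed Integer seed controlling initialization and pair shuffling.
#' @slot distance Either `"cosine_similarity"` or `"negative_euclidean"`;
#'   the pair score is the sigmoid of this distance between the two
#'   second-order embeddings.
#' @slot architecture `"bilstm"` (default) or `"identity"` (pass-through
#'   encoder; second-order classification then reduces to PT-SNN).
#' @seealso [encoderConfig()], [trainEncoder()]
#' @export
setClass("EncoderConfig",
  representation(inputDim = "integer", hiddenDim = "integer",
                 outputDim = "integer", chunkLength = "integer",
                 epochs = "integer", learningRate = "numeric",
                 batchSize = "integer", weightDecay = "numeric",
                 seed = "integer", distance = "character",
                 architecture = "character"))

setValidity("EncoderConfig", function(object) {
  msg <- character()
  if (object@inputDim < 1L) msg <- c(msg, "inputDim must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@chunkLength < 1L || object@inputDim %% object@chunkLength != 0L)
    msg <- c(msg, "chunkLength must divide inputDim")
  if (!object@distance %in% c("cosine_similarity", "negative_euclidean"))
    msg <- c(msg, "distance must be 'cosine_similarity' or 'negative_euclidean'")
  if (!object@architecture %in% c("bilstm", "identity"))
    msg <- c(msg, "architecture must be 'bilstm' or 'identity'")
  if (length(msg)) msg else TRUE
})

#' Construct an EncoderConfig
#'
#' @param inputDim Dimension d of the first-order embeddings.
#' @param hiddenDim LSTM hidden size per direction (default 32).
#' @param outputDim Second-order embedding size (default `inputDim`).
#' @param chunkLength Sequence length the input vector is reshaped to
#'   (default 16, shrunk automatically to the largest divisor of `inputDim`
#'   not exceeding it).
#' @param epochs Training epochs over the pair set (default 50).
#' @param learningRate AdamW step size (default 1e-3).
#' @param batchSize Pairs per gradient step; 0 = all pairs (default).
#' @param weightDecay Decoupled weight decay (default 0.01).
#' @param seed Integer seed (default 0).
#' @param distance Distance inside the sigmoid: `"cosine_similarity"`
#'   (default) or `"negative_euclidean"`.
#' @param architecture `"bilstm"` or `"identity"`.
#' @return An [EncoderConfig-class].
#' @export
encoderConfig <- function(inputDim, hiddenDim = 32L, outputDim = inputDim,
                          chunkLength = 16L, epochs = 50L, learningRate = 1e-3,
                          batchSize = 0L, weightDecay = 0.01, seed = 0L,
                          distance = c("cosine_similarity", "negative_euclidean"),
                          architecture = c("bilstm", "identity")) {
  distance <- match.arg(distance)
  architecture <- match.arg(architecture)
  inputDim <- as.integer(inputDim)
  if (is.na(inputDim) || inputDim < 1L) stop("inputDim must be a positive integer")
  chunkLength <- as.integer(chunkLength)
  while (chunkLength > 1L && inputDim %% chunkLength != 0L)
    chunkLength <- chunkLength - 1L
  methods::new("EncoderConfig",
    inputDim = inputDim, hiddenDim = as.integer(hiddenDim),
    outputDim = as.integer(outputDim), chunkLength = chunkLength,
    epochs = as.integer(epochs), learningRate = as.numeric(learningRate),
    batchSize = as.integer(batchSize), weightDecay = as.numeric(weightDecay),
    seed = as.integer(seed), distance = distance, architecture = architecture)
}

#' A (possibly trained) second-order Siamese encoder
#'
#' Two weight-sharing copies of this encoder form the Siamese pair scorer;
#' a single copy maps first-order embeddings to second-order embeddings via
#' [encode()]. Produced by [initEncoder()] / [trainEncoder()].
#'
#' @slot parameters Named list of weight matrices (both LSTM directions and
#'   the output projection).
#' @slot config The [EncoderConfig-class] used.
#' @slot lossHistory Numeric vector of per-epoch mean binary cross-entropy
#'   (empty for an untrained model).
#' @export
setClass("EncoderModel",
  representation(parameters = "list", config = "EncoderConfig",
                 lossHistory = "numeric"))

setMethod("show", "EncoderModel", function(object) {
  cfg <- object@config
  cat("EncoderModel [", cfg@architecture, "] ", cfg@inputDim, " -> ",
      cfg@outputDim, " (hidden ", cfg@hiddenDim, ", seq len ",
      cfg@chunkLength, ", distance ", cfg@distance, ")\n", sep = "")
  if (length(object@lossHistory))
    cat("trained ", length(object@lossHistory), " epochs; final BCE ",
        signif(utils::tail(object@lossHistory, 1), 4), "\n", sep = "")
  else cat("untrained\n")
})

# ---------------------------------------------------------------------------
# FewShotMetrics
# ---------------------------------------------------------------------------

#' Averaged episodic evaluation metrics
#'
#' Precision/recall/F per evaluation iteration plus their arithmetic mean,
#' the M-iteration averaging protocol (M defaults to 3).
#'
#' @slot perIteration M x 3 matrix with columns precision, recall, fscore.
#' @slot mean Named numeric length-3 vector of column means.
#' @slot kShots,mIterations Integers describing the protocol.
#' @slot averaging The multi-class averaging scheme used.
#' @seealso [evaluateAveraged()]
#' @export
setClass("FewShotMetrics",
  representation(perIteration = "matrix", mean = "numeric",
                 kShots = "integer", mIterations = "integer",
                 averaging = "character"))

setValidity("FewShotMetrics", function(object) {
  msg <- character()
  m <- object@perIteration
  if (ncol(m) != 3L) msg <- c(msg, "perIteration must have 3 columns")
  if (nrow(m) != object@mIterations)
    msg <- c(msg, "mIterations must equal nrow(perIteration)")
  if (any(m < -1e-12 | m > 1 + 1e-12)) msg <- c(msg, "metrics must lie in [0, 1]")
  if (max(abs(object@mean - colMeans(m))) > 1e-12)
    msg <- c(msg, "mean slot must be the column means of perIteration")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FewShotMetrics", function(object) {
  cat("FewShotMetrics: ", object@mIterations, " iterations, ",
      object@kShots, "-shot, ", object@averaging, " averaging\n", sep = "")
  print(round(rbind(object@perIteration, mean = object@mean), 4))
})

#' Per-iteration metrics accessor
#' @param x A [FewShotMetrics-class].
#' @return M x 3 numeric matrix (precision, recall, fscore).
#' @export
iterationMetrics <- function(x) {
  stopifnot(methods::is(x, "FewShotMetrics"))
  x@perIteration
}

#' Mean metrics accessor
#' @param x A [FewShotMetrics-class].
#' @return Named numeric vector (precision, recall, fscore).
#' @export
meanMetrics <- function(x) {
  stopifnot(methods::is(x, "FewShotMetrics"))
  x@mean
}
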