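#' @import methods
NULL

#' Embedding matrix accessor
#'
#' Returns the n x d matrix of first-order embeddings (samples in rows),
#' the orientation all downstream linear algebra uses.
#'
#' @param x An [EmbeddingSet-class] object.
#' @return A numeric matrix with one row per sample.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' Sample label accessor
#'
#' @param x An [EmbeddingSet-class] or [PairSet-class] object.
#' @return For an `EmbeddingSet`, a character vector of class labels aligned
#'   with the rows of [embeddingMatrix()].
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' Sample identifier accessor
#'
#' @param x An [EmbeddingSet-class] object.
#' @return Character vector of stable sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Class order of a labeled object
#'
#' The deterministic ordering of the label set (sorted unique labels) used
#' for score-table columns and argmax tie-breaking.
#'
#' @param x An [EmbeddingSet-class] object.
#' @return Character vector of the distinct class labels, in order.
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))

#' Enumerate unique sample pairs for Siamese-style augmentation
#'
#' @param x A labeled object (typically an [EmbeddingSet-class]).
#' @param ... Passed to methods.
#' @return A [PairSet-class].
#' @export
setGeneric("makePairs", function(x, ...) standardGeneric("makePairs"))

#' Map first-order embeddings to second-order embeddings
#'
#' @param model A trained or initialized [EncoderModel-class].
#' @param vectors A numeric matrix (rows are samples) with `inputDim` columns,
#'   or an [EmbeddingSet-class].
#' @return A numeric matrix with `outputDim` columns, one row per input row.
#' @export
setGeneric("encode", function(model, vectors) standardGeneric("encode"))
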