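#' @importFrom withr with_seed
#' @importFrom stats rnorm
NULL

# ---------------------------------------------------------------------------
# similarity primitives
# ---------------------------------------------------------------------------

#' L2-normalize the rows of a matrix
#'
#' Rescales every row to unit Euclidean norm; directions are preserved, so
#' cosine similarities reduce to plain inner products afterwards.
#'
#' @param m Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape with unit-norm rows.
#' @examples
#' l2Normalize(matrix(c(3, 4), 1))  # 0.6 0.8
#' @export
l2Normalize <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  bad <- which(norms == 0)
  if (length(bad))
    stop("cannot L2-normalize all-zero row(s): ", paste(bad, collapse = ", "))
  m / norms
}

#' Cosine similarity between the rows of two matrices
#'
#' Entry (i, j) is `sum(a_i * b_j) / (||a_i|| * ||b_j||)`, the standard cosine
#' of the angle between row i of `a` and row j of `b`.
#'
#' @param a Numeric n x d matrix (or length-d vector).
#' @param b Numeric m x d matrix (or length-d vector).
#' @return n x m matrix with entries in `[-1, 1]`.
#' @examples
#' cosineSimilarity(c(1, 2, 3), c(4, 5, 6))  # ~0.9746
#' @export
cosineSimilarity <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (ncol(a) != ncol(b))
    stop("dimension mismatch: a is ", nrow(a), "x", ncol(a),
         ", b is ", nrow(b), "x", ncol(b))
  s <- l2Normalize(a) %*% t(l2Normalize(b))
  # clamp floating-point excursions beyond [-1, 1]
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

# ---------------------------------------------------------------------------
# backends
# ---------------------------------------------------------------------------

#' Declare a sentence-embedding backend
#'
#' A backend is the frozen component that maps texts to first-order
#' embeddings. Real pretrained language models (served e.g. through an
#' external sentence-encoder process) plug in here; the bundled
#' [hashingBackend()] is a deterministic offline default.
#'
#' @param name Identifier string.
#' @param dimension Positive integer embedding dimension, fixed for the
#'   backend's lifetime.
#' @param embed Function mapping a character vector of texts to a
#'   `length(texts) x dimension` numeric matrix.
#' @param deterministic Logical; `TRUE` promises identical vectors for
#'   identical texts.
#' @return An object of class `"EmbeddingBackend"`.
#' @export
embeddingBackend <- function(name, dimension, embed, deterministic = FALSE) {
  dimension <- as.integer(dimension)
  stopifnot(is.character(name), length(name) == 1L,
            dimension >= 1L, is.function(embed))
  structure(list(name = name, dimension = dimension, embed = embed,
                 deterministic = isTRUE(deterministic)),
            class = "EmbeddingBackend")
}

#' @export
print.EmbeddingBackend <- function(x, ...) {
  cat("EmbeddingBackend '", x$name, "': dim ", x$dimension,
      if (x$deterministic) " (deterministic)" else "", "\n", sep = "")
  invisible(x)
}

# 31-adic rolling hash over code points, exact in double precision
hashString <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

charNgrams <- function(text, n) {
  padded <- paste0(" ", tolower(text), " ")
  L <- nchar(padded)
  if (L < n) return(padded)
  substring(padded, seq_len(L - n + 1L), seq(n, L))
}

#' Deterministic offline hashing backend
#'
#' Embeds a sentence as the sum of seeded Gaussian random projections of its
#' character n-grams: each n-gram hashes to a seed that generates a fixed
#' d-vector, and the sentence embedding is the sum over its n-grams (scaled
#' by 1/sqrt(count)). Identical texts always map to identical vectors, texts
#' sharing n-grams land close in cosine space, and disjoint-vocabulary texts
#' are near-orthogonal — enough structure to exercise every classifier
#' offline without downloading a pretrained language model.
#'
#' @param dimension Embedding dimension (default 64).
#' @param ngram Character n-gram length (default 3).
#' @return An `"EmbeddingBackend"` with `deterministic = TRUE`.
#' @examples
#' be <- hashingBackend(dimension = 16)
#' v <- be$embed(c("heart failure", "heart failure"))
#' identical(v[1, ], v[2, ])
#' @export
hashingBackend <- function(dimension = 64L, ngram = 3L) {
  dimension <- as.integer(dimension)
  ngram <- as.integer(ngram)
  stopifnot(dimension >= 1L, ngram >= 1L)
  cache <- new.env(parent = emptyenv())
  gramVector <- function(g) {
    v <- cache[[g]]
    if (is.null(v)) {
      v <- withr::with_seed(hashString(g), stats::rnorm(dimension))
      assign(g, v, envir = cache)
    }
    v
  }
  embed <- function(texts) {
    out <- matrix(0, length(texts), dimension)
    for (i in seq_along(texts)) {
      grams <- charNgrams(texts[i], ngram)
      acc <- numeric(dimension)
      for (g in grams) acc <- acc + gramVector(g)
      out[i, ] <- acc / sqrt(length(grams))
    }
    out
  }
  embeddingBackend(paste0("hash-", ngram, "gram-", dimension, "d"),
                   dimension, embed, deterministic = TRUE)
}

#' Embed a labeled corpus
#'
#' Applies a backend to every text of a corpus, preserving order, and returns
#' the embeddings aligned with the corpus labels.
#'
#' @param corpus A `data.frame` with character columns `text` and `label`
#'   (see [readCorpus()]), optionally an `id` column.
#' @param backend An `"EmbeddingBackend"`, e.g. [hashingBackend()].
#' @return An [EmbeddingSet-class] with one row per text.
#' @export
embedCorpus <- function(corpus, backend) {
  if (!inherits(backend, "EmbeddingBackend"))
    stop("unknown backend: expected an 'EmbeddingBackend' object")
  if (!is.data.frame(corpus) || !all(c("text", "label") %in% names(corpus)))
    stop("corpus must be a data.frame with columns 'text' and 'label'")
  if (nrow(corpus) == 0L) stop("corpus is empty")
  ids <- if ("id" %in% names(corpus)) as.character(corpus$id)
         else paste0("s", seq_len(nrow(corpus)))
  empty <- which(!nzchar(trimws(corpus$text)))
  if (length(empty))
    stop("empty text for item(s): ", paste(ids[empty], collapse = ", "))
  m <- backend$embed(as.character(corpus$text))
  if (!is.matrix(m) || nrow(m) != nrow(corpus) || ncol(m) != backend$dimension)
    stop("backend '", backend$name, "' returned a malformed matrix")
  EmbeddingSet(m, labels = corpus$label, ids = ids)
}
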