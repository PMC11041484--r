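# Readers and writers for every artifact the pipeline exchanges: JSONL/CSV
# corpora, delimited-text and little-endian binary embedding files, TSV
# metrics, and YAML run configurations. Round-trips are lossless.

#' Read a labeled corpus
#'
#' JSONL (one object per line with keys `text` and `label`) or CSV with a
#' `text,label` header; UTF-8. An optional `id` field is preserved.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A `data.frame` with columns `text`, `label` (and `id` if present).
#' @export
readCorpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  corpus <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  if (!all(c("text", "label") %in% names(corpus)))
    stop("corpus must provide 'text' and 'label' fields: ", path)
  corpus
}

#' Write a labeled corpus
#'
#' @param corpus `data.frame` with `text` and `label` (and optionally `id`).
#' @param path Destination path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(corpus, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus)))
      writeLines(jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write / read embeddings as delimited text
#'
#' Tab-separated with columns `id`, `label`, then `V1 ... Vd`.
#'
#' @param es An [EmbeddingSet-class].
#' @param path File path.
#' @return `writeEmbeddingsTSV` returns `path` invisibly; `readEmbeddingsTSV`
#'   an [EmbeddingSet-class].
#' @export
writeEmbeddingsTSV <- function(es, path) {
  stopifnot(methods::is(es, "EmbeddingSet"))
  m <- embeddingMatrix(es)
  df <- data.frame(id = sampleIds(es), label = sampleLabels(es), m)
  colnames(df) <- c("id", "label", paste0("V", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingsTSV
#' @export
readEmbeddingsTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  vecCols <- grep("^V\\d+$", names(df))
  EmbeddingSet(as.matrix(df[, vecCols, drop = FALSE]),
               labels = df$label, ids = df$id)
}

#' Write / read embeddings as a binary matrix file with JSON sidecar
#'
#' The `.bin` file holds the n x d matrix as little-endian IEEE-754 doubles
#' in row-major order; `<path>.json` records `n`, `d`, `byte_order`, ids and
#' labels. Exact (bit-level) round-trip.
#'
#' @param es An [EmbeddingSet-class].
#' @param path Path of the binary file; the sidecar is `<path>.json`.
#' @return `writeEmbeddingsBinary` returns `path` invisibly;
#'   `readEmbeddingsBinary` an [EmbeddingSet-class].
#' @export
writeEmbeddingsBinary <- function(es, path) {
  stopifnot(methods::is(es, "EmbeddingSet"))
  m <- embeddingMatrix(es)
  con <- file(path, open = "wb")
  writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
  close(con)
  sidecar <- list(format = "fewshot-embeddings-v1", n = nrow(m), d = ncol(m),
                  byte_order = "little", dtype = "float64",
                  order = "row-major", ids = sampleIds(es),
                  labels = sampleLabels(es))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEmbeddingsBinary
#' @export
readEmbeddingsBinary <- function(path) {
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecarPath))
    stop("binary embedding file or its sidecar missing: ", path)
  meta <- jsonlite::fromJSON(sidecarPath)
  con <- file(path, open = "rb")
  vals <- readBin(con, what = "numeric", n = meta$n * meta$d, size = 8L,
                  endian = "little")
  close(con)
  m <- matrix(vals, nrow = meta$n, ncol = meta$d, byrow = TRUE)
  EmbeddingSet(m, labels = meta$labels, ids = meta$ids)
}

#' Write an evaluation metrics table as TSV
#'
#' @param df `data.frame` of metric rows (see [runExperiment()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeMetricsTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricsTSV
#' @export
readMetricsTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
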