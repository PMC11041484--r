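# Reproducible experiment runs: a RunConfig names every input, method choice
# and seed; runExperiment executes the K-shot grid and writes one metrics row
# per (method, backend, shots, iteration) plus a mean row.

#' Build a run configuration
#'
#' Captures a full experimental grid — method, backend, shot counts, number
#' of averaging iterations, episode mode, metric averaging, optional encoder
#' settings and the master seed — so a run is reproducible from the config
#' alone. Serializes losslessly to YAML via [writeRunConfig()].
#'
#' @param method `"pt-snn"` or `"soe-snn"`.
#' @param backend Backend name: `"hash"` (the offline deterministic backend)
#'   or `"synthetic"` (embeddings generated directly, no text involved).
#' @param shots Integer vector of K values (default `c(4, 8, 16)`).
#' @param mIterations Averaging iterations M (default 3).
#' @param episodeMode `"complement"` or `"fixed_test"`.
#' @param averaging `"macro"`, `"weighted"` or `"micro"`.
#' @param encoder Optional named list of [encoderConfig()] arguments for
#'   `"soe-snn"`.
#' @param synthetic Optional named list of [syntheticConfig()] arguments for
#'   the `"synthetic"` backend.
#' @param seed Master seed; episode seeds are `seed + 0 .. M-1`.
#' @param input Optional path to a corpus (JSONL/CSV) or embeddings TSV.
#' @param output Optional path for the metrics TSV.
#' @return An object of class `"RunConfig"`.
#' @export
runConfig <- function(method = c("pt-snn", "soe-snn"), backend = "synthetic",
                      shots = c(4L, 8L, 16L), mIterations = 3L,
                      episodeMode = c("complement", "fixed_test"),
                      averaging = c("macro", "weighted", "micro"),
                      encoder = NULL, synthetic = NULL, seed = 0L,
                      input = NULL, output = NULL) {
  method <- match.arg(method)
  episodeMode <- match.arg(episodeMode)
  averaging <- match.arg(averaging)
  shots <- as.integer(shots)
  if (any(shots < 1L)) stop("invalid config field 'shots': all values must be >= 1")
  if (!backend %in% c("hash", "synthetic"))
    stop("invalid config field 'backend': ", backend)
  structure(list(method = method, backend = backend, shots = shots,
                 mIterations = as.integer(mIterations),
                 episodeMode = episodeMode, averaging = averaging,
                 encoder = encoder, synthetic = synthetic,
                 seed = as.integer(seed), input = input, output = output),
            class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig: ", x$method, " / ", x$backend, "; shots ",
      paste(x$shots, collapse = ","), "; M = ", x$mIterations,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param config A `"RunConfig"`.
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig` a
#'   `"RunConfig"`.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals[!vapply(vals, is.null, logical(1L))])
}

loadExperimentData <- function(config) {
  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("missing input: ", config$input)
    if (grepl("\\.(tsv|txt)$", config$input, ignore.case = TRUE))
      return(readEmbeddingsTSV(config$input))
    corpus <- readCorpus(config$input)
    return(embedCorpus(corpus, hashingBackend()))
  }
  synthArgs <- if (is.null(config$synthetic)) list() else config$synthetic
  if (is.null(synthArgs$seed)) synthArgs$seed <- config$seed
  if (config$backend == "hash") {
    corpus <- generateToyCorpus(do.call(syntheticConfig, synthArgs))
    embedCorpus(corpus, hashingBackend())
  } else {
    generateEmbeddings(do.call(syntheticConfig, synthArgs))
  }
}

#' Run a configured few-shot experiment grid
#'
#' Loads (or generates) the labeled embeddings, runs [evaluateAveraged()]
#' for every K in `config$shots`, and returns the long metrics table: one
#' row per iteration plus a `"mean"` row per K. Logs every episode's sizes
#' and seed via `message()`. Re-running the same config reproduces the
#' table exactly.
#'
#' @param config A `"RunConfig"`.
#' @param quiet Suppress log messages (default `FALSE`).
#' @return A `data.frame` with columns `method`, `backend`, `shots`,
#'   `iteration`, `precision`, `recall`, `fscore`; written to
#'   `config$output` as TSV when that is set.
#' @export
runExperiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  data <- loadExperimentData(config)
  log <- function(...) if (!quiet) message(...)
  log("data: ", ncol(data), " samples, ", nrow(data), " dims, ",
      length(classOrder(data)), " classes")
  encCfg <- NULL
  if (config$method == "soe-snn") {
    encArgs <- if (is.null(config$encoder)) list() else config$encoder
    encArgs$inputDim <- nrow(data)
    encCfg <- do.call(encoderConfig, encArgs)
  }
  rows <- lapply(config$shots, function(k) {
    log("evaluating ", config$method, " at K = ", k, ", M = ",
        config$mIterations, ", seeds ", config$seed, "..",
        config$seed + config$mIterations - 1L)
    fm <- evaluateAveraged(data, config$method, kShots = k,
                           mIterations = config$mIterations,
                           averaging = config$averaging,
                           mode = config$episodeMode,
                           encoderConfig = encCfg, baseSeed = config$seed)
    per <- iterationMetrics(fm)
    data.frame(method = config$method, backend = config$backend, shots = k,
               iteration = c(seq_len(nrow(per)) - 1L, "mean"),
               rbind(per, meanMetrics(fm)), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$output)) {
    writeMetricsTSV(out, config$output)
    log("metrics written to ", config$output)
  }
  out
}
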