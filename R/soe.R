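# SOE-SNN: a trainable second-order encoder stacked on frozen first-order
# embeddings. Two weight-sharing copies score a sample pair as
# sigma(distance(e1, e2)) and are trained with binary cross-entropy against
# the same-class flag of every unique pair; classification then applies the
# PT-SNN mean-class-similarity rule to the second-order embeddings.
#
# The encoder is a bidirectional LSTM over the input vector viewed as
# chunkLength segments, followed by a linear projection of the concatenated
# final hidden states. Written in plain R with exact backpropagation through
# time and an AdamW update; few-shot scale (tens of samples, hundreds of
# pairs) keeps this fast.

sigm <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# parameter init / forward / backward
# ---------------------------------------------------------------------------

initLstmDir <- function(p, H) {
  sc <- 1 / sqrt(max(H, p))
  list(W = matrix(stats::runif(4L * H * p, -sc, sc), 4L * H, p),
       U = matrix(stats::runif(4L * H * H, -sc, sc), 4L * H, H),
       b = numeric(4L * H))
}

#' Initialize an untrained encoder
#'
#' Weight initialization is a deterministic function of `config@seed`.
#'
#' @param config An [EncoderConfig-class].
#' @return An untrained [EncoderModel-class].
#' @export
initEncoder <- function(config) {
  stopifnot(methods::is(config, "EncoderConfig"))
  methods::validObject(config)
  if (config@architecture == "identity") {
    if (config@outputDim != config@inputDim)
      stop("identity architecture requires outputDim == inputDim")
    return(methods::new("EncoderModel", parameters = list(),
                        config = config, lossHistory = numeric()))
  }
  H <- config@hiddenDim
  p <- config@inputDim %/% config@chunkLength
  params <- withr::with_seed(config@seed, {
    sc <- 1 / sqrt(2L * H)
    list(fwd = initLstmDir(p, H),
         bwd = initLstmDir(p, H),
         Wp = matrix(stats::runif(config@outputDim * 2L * H, -sc, sc),
                     config@outputDim, 2L * H),
         bp = numeric(config@outputDim))
  })
  methods::new("EncoderModel", parameters = params, config = config,
               lossHistory = numeric())
}

# run one LSTM direction over the chunk sequence; returns final hidden state
# and (optionally) the caches needed for backprop
lstmDirForward <- function(dir, chunks, order, keepCache = FALSE) {
  n <- nrow(chunks[[1L]])
  H <- length(dir$b) %/% 4L
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  cache <- if (keepCache) vector("list", length(order)) else NULL
  iH <- seq_len(H)
  for (k in seq_along(order)) {
    t <- order[k]
    x <- chunks[[t]]
    z <- x %*% t(dir$W) + h %*% t(dir$U)
    z <- sweep(z, 2L, dir$b, "+")
    ig <- sigm(z[, iH, drop = FALSE])
    fg <- sigm(z[, iH + H, drop = FALSE])
    og <- sigm(z[, iH + 2L * H, drop = FALSE])
    gg <- tanh(z[, iH + 3L * H, drop = FALSE])
    cPrev <- cc
    hPrev <- h
    cc <- fg * cPrev + ig * gg
    h <- og * tanh(cc)
    if (keepCache)
      cache[[k]] <- list(x = x, hPrev = hPrev, cPrev = cPrev,
                         i = ig, f = fg, o = og, g = gg, c = cc)
  }
  list(h = h, cache = cache)
}

# backprop through one direction given dL/d(final hidden state)
lstmDirBackward <- function(dir, cache, dhFinal) {
  H <- length(dir$b) %/% 4L
  dW <- matrix(0, nrow(dir$W), ncol(dir$W))
  dU <- matrix(0, nrow(dir$U), ncol(dir$U))
  db <- numeric(length(dir$b))
  dh <- dhFinal
  dc <- matrix(0, nrow(dhFinal), H)
  for (k in rev(seq_along(cache))) {
    cs <- cache[[k]]
    tc <- tanh(cs$c)
    do <- dh * tc
    dct <- dh * cs$o * (1 - tc^2) + dc
    di <- dct * cs$g
    df <- dct * cs$cPrev
    dg <- dct * cs$i
    dz <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                do * cs$o * (1 - cs$o),
                dg * (1 - cs$g^2))
    dW <- dW + t(dz) %*% cs$x
    dU <- dU + t(dz) %*% cs$hPrev
    db <- db + colSums(dz)
    dh <- dz %*% dir$U
    dc <- dct * cs$f
  }
  list(W = dW, U = dU, b = db)
}

splitChunks <- function(vectors, chunkLength) {
  p <- ncol(vectors) %/% chunkLength
  lapply(seq_len(chunkLength), function(t)
    vectors[, ((t - 1L) * p + 1L):(t * p), drop = FALSE])
}

encoderForward <- function(model, vectors, keepCache = FALSE) {
  cfg <- model@config
  chunks <- splitChunks(vectors, cfg@chunkLength)
  Tn <- cfg@chunkLength
  fw <- lstmDirForward(model@parameters$fwd, chunks, seq_len(Tn), keepCache)
  bw <- lstmDirForward(model@parameters$bwd, chunks, rev(seq_len(Tn)), keepCache)
  hh <- cbind(fw$h, bw$h)
  e <- hh %*% t(model@parameters$Wp)
  e <- sweep(e, 2L, model@parameters$bp, "+")
  list(e = e, hh = hh, fw = fw, bw = bw, chunks = chunks)
}

# gradients of all parameters given dL/dE (n x outputDim)
encoderBackward <- function(model, fwdPass, dE) {
  H <- model@config@hiddenDim
  dWp <- t(dE) %*% fwdPass$hh
  dbp <- colSums(dE)
  dhh <- dE %*% model@parameters$Wp
  gF <- lstmDirBackward(model@parameters$fwd, fwdPass$fw$cache,
                        dhh[, seq_len(H), drop = FALSE])
  gB <- lstmDirBackward(model@parameters$bwd, fwdPass$bw$cache,
                        dhh[, H + seq_len(H), drop = FALSE])
  list(fwd = gF, bwd = gB, Wp = dWp, bp = dbp)
}

#' @describeIn encode Second-order embeddings of a matrix of first-order
#'   embeddings (one row per sample); deterministic for a given model.
#' @export
setMethod("encode", "EncoderModel", function(model, vectors) {
  if (methods::is(vectors, "EmbeddingSet")) vectors <- embeddingMatrix(vectors)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != model@config@inputDim)
    stop("dimension mismatch: got ", ncol(vectors), " columns, model expects ",
         model@config@inputDim)
  if (model@config@architecture == "identity") return(vectors)
  encoderForward(model, vectors)$e
})

# ---------------------------------------------------------------------------
# pair scoring and loss
# ---------------------------------------------------------------------------

pairDistance <- function(e1, e2, distance) {
  if (distance == "cosine_similarity") {
    n1 <- sqrt(rowSums(e1^2))
    n2 <- sqrt(rowSums(e2^2))
    rowSums(e1 * e2) / (n1 * n2)
  } else {
    -sqrt(rowSums((e1 - e2)^2))
  }
}

#' Siamese pair similarity
#'
#' The probability-like score of two samples belonging to the same class:
#' the sigmoid of the configured distance (cosine similarity or negative
#' Euclidean) between their second-order embeddings. Symmetric in its
#' arguments because the two branches share weights.
#'
#' @param model An [EncoderModel-class].
#' @param v1,v2 First-order embedding vectors of length `inputDim` (or
#'   matrices with matching row counts for a batch of pairs).
#' @return Numeric score(s) in (0, 1).
#' @export
pairSimilarity <- function(model, v1, v2) {
  e1 <- encode(model, v1)
  e2 <- encode(model, v2)
  if (nrow(e1) != nrow(e2)) stop("v1 and v2 must hold the same number of rows")
  as.numeric(sigm(pairDistance(e1, e2, model@config@distance)))
}

# mean binary cross-entropy of predicted pair scores vs same-class targets
bceLoss <- function(out, y) {
  eps <- 1e-12
  out <- pmin(pmax(out, eps), 1 - eps)
  -mean(y * log(out) + (1 - y) * log(1 - out))
}

# dL/dE for a batch of pairs given encoded samples E (rows indexed by pairs)
pairLossGradient <- function(E, ii, jj, y, distance) {
  P <- length(ii)
  e1 <- E[ii, , drop = FALSE]
  e2 <- E[jj, , drop = FALSE]
  s <- pairDistance(e1, e2, distance)
  out <- sigm(s)
  gs <- (out - y) / P            # d(mean BCE)/ds, sigmoid folded in
  if (distance == "cosine_similarity") {
    n1 <- sqrt(rowSums(e1^2))
    n2 <- sqrt(rowSums(e2^2))
    cosv <- rowSums(e1 * e2) / (n1 * n2)
    d1 <- gs * (e2 / (n1 * n2) - cosv * e1 / n1^2)
    d2 <- gs * (e1 / (n1 * n2) - cosv * e2 / n2^2)
  } else {
    diff <- e1 - e2
    dist <- pmax(sqrt(rowSums(diff^2)), 1e-12)
    d1 <- gs * (-diff / dist)
    d2 <- -d1
  }
  dE <- matrix(0, nrow(E), ncol(E))
  for (k in seq_len(P)) {
    dE[ii[k], ] <- dE[ii[k], ] + d1[k, ]
    dE[jj[k], ] <- dE[jj[k], ] + d2[k, ]
  }
  list(dE = dE, loss = bceLoss(out, y))
}

# ---------------------------------------------------------------------------
# AdamW
# ---------------------------------------------------------------------------

adamwInitState <- function(params) {
  lapply(params, function(x)
    if (is.list(x)) adamwInitState(x) else list(m = x * 0, v = x * 0))
}

adamwStep <- function(params, grads, state, lr, wd, step,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g^2
    mh <- s$m / (1 - b1^step)
    vh <- s$v / (1 - b2^step)
    p <- p - lr * (mh / (sqrt(vh) + eps) + wd * p)
    list(p = p, s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out <- Map(walk, p, g, s)
      list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s"))
    } else upd(p, g, s)
  }
  walk(params, grads, state)
}

# ---------------------------------------------------------------------------
# training
# ---------------------------------------------------------------------------

#' Stratified half split for SOE-SNN
#'
#' Splits a support set per class into an encoder-training half and a
#' classification (support) half; with an odd per-class count the larger
#' half goes to the encoder side. Deterministic given the seed.
#'
#' @param train An [EmbeddingSet-class] with at least 2 samples per class.
#' @param seed Integer seed.
#' @return Named list with [EmbeddingSet-class] elements `encoderHalf` and
#'   `supportHalf` (disjoint, union = input).
#' @export
splitForSOE <- function(train, seed = 0L) {
  stopifnot(methods::is(train, "EmbeddingSet"))
  labs <- sampleLabels(train)
  ids <- sampleIds(train)
  counts <- table(labs)
  tooFew <- names(counts)[counts < 2L]
  if (length(tooFew))
    stop("class(es) with fewer than 2 samples cannot be halved: ",
         paste(tooFew, collapse = ", "))
  encIds <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classOrder(train), function(cl) {
      clIds <- ids[labs == cl]
      take <- ceiling(length(clIds) / 2)
      sample(clIds, take)
    }), use.names = FALSE)
  })
  list(encoderHalf = subsetSamples(train, encIds),
       supportHalf = subsetSamples(train, setdiff(ids, encIds)))
}

#' Train the second-order Siamese encoder
#'
#' Enumerates all unique pairs of the encoder half ([makePairs()]), scores
#' every pair as the sigmoid of the distance between the two second-order
#' embeddings, and minimizes binary cross-entropy against the same-class
#' flags with AdamW. The first-order backend is frozen throughout; only the
#' encoder weights move. Fully deterministic given `config@seed`.
#'
#' @param encoderHalf [EmbeddingSet-class] with >= 2 samples and >= 2 classes.
#' @param config An [EncoderConfig-class]; `inputDim` must match the data.
#' @return A trained [EncoderModel-class] carrying the per-epoch loss in
#'   `@lossHistory`.
#' @export
trainEncoder <- function(encoderHalf, config) {
  stopifnot(methods::is(encoderHalf, "EmbeddingSet"))
  methods::validObject(config)
  X <- embeddingMatrix(encoderHalf)
  if (ncol(X) != config@inputDim)
    stop("config inputDim (", config@inputDim, ") does not match data (",
         ncol(X), ")")
  if (length(classOrder(encoderHalf)) < 2L)
    stop("encoder training needs >= 2 classes; the pair loss is degenerate otherwise")
  ps <- makePairs(encoderHalf)
  pt <- pairTable(ps)
  model <- initEncoder(config)
  if (config@architecture == "identity") return(model)

  params <- model@parameters
  state <- adamwInitState(params)
  nPairs <- nrow(pt)
  batch <- if (config@batchSize <= 0L) nPairs else min(config@batchSize, nPairs)
  losses <- numeric(config@epochs)
  step <- 0L
  withr::with_seed(config@seed + 1L, {
    for (ep in seq_len(config@epochs)) {
      ord <- if (batch < nPairs) sample.int(nPairs) else seq_len(nPairs)
      epLoss <- 0
      nb <- 0L
      for (start in seq(1L, nPairs, by = batch)) {
        sel <- ord[start:min(start + batch - 1L, nPairs)]
        model@parameters <- params
        fp <- encoderForward(model, X, keepCache = TRUE)
        pg <- pairLossGradient(fp$e, pt$i[sel], pt$j[sel],
                               pt$sameClass[sel], config@distance)
        grads <- encoderBackward(model, fp, pg$dE)
        step <- step + 1L
        out <- adamwStep(params, grads, state, config@learningRate,
                         config@weightDecay, step)
        params <- out$p
        state <- out$s
        epLoss <- epLoss + pg$loss
        nb <- nb + 1L
      }
      losses[ep] <- epLoss / nb
    }
  })
  methods::new("EncoderModel", parameters = params, config = config,
               lossHistory = losses)
}

#' Classify with second-order embeddings
#'
#' Applies the PT-SNN mean-class-cosine-similarity rule ([classifyPT()]) to
#' the second-order embeddings of the support half and the test vectors.
#'
#' @param model Trained [EncoderModel-class].
#' @param supportHalf [EmbeddingSet-class] used as the labeled support set.
#' @param testVectors Matrix of first-order test embeddings (rows), or an
#'   [EmbeddingSet-class].
#' @return Character vector of predicted labels.
#' @export
classifySOE <- function(model, supportHalf, testVectors) {
  stopifnot(methods::is(model, "EncoderModel"),
            methods::is(supportHalf, "EmbeddingSet"))
  sup2 <- encode(model, embeddingMatrix(supportHalf))
  test2 <- encode(model, asTestMatrix(testVectors, model@config@inputDim))
  train2 <- EmbeddingSet(sup2, labels = sampleLabels(supportHalf),
                         ids = sampleIds(supportHalf))
  classifyPT(train2, test2)
}
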