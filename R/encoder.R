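# Deterministic positionwise text encoder. There is no cross-token
# attention: each token position flows through the same linear blocks,
# and mean pooling makes the text embedding depend on token content.
# This is sufficient to exercise every quantization and alignment
# contract (the quantized operator set is exactly matmul/add/relu) and
# is documented as a stand-in for pretrained transformer encoders,
# which are out of scope.

.PAD <- 0L
.CLS <- 1L
.SEP <- 2L

#' Create a seeded FP32 text encoder
#'
#' Token embeddings are drawn from a seeded standard normal (the PAD row
#' is zeroed so padded positions contribute nothing to the literal
#' full-length mean pool); linear weights are standard normal scaled by
#' `1/sqrt(fan_in)` so activations stay O(1) and the int8 range is
#' exercised meaningfully.
#'
#' @param config An [encoderConfig()].
#' @return A FP32 [TextEncoder-class].
#' @export
newTextEncoder <- function(config = encoderConfig()) {
  validObject(config)
  withr::with_seed(config@seed, {
    emb <- matrix(stats::rnorm(config@vocabSize * config@embedDim),
                  config@vocabSize, config@embedDim)
    emb[.PAD + 1L, ] <- 0
    layers <- vector("list", config@nLayers)
    din <- config@embedDim
    for (l in seq_len(config@nLayers)) {
      dout <- config@hiddenDim
      layers[[l]] <- list(
        W = matrix(stats::rnorm(din * dout), din, dout) / sqrt(din),
        b = stats::rnorm(dout) * 0.1)
      din <- dout
    }
  })
  new("TextEncoder", config = config, embedding = emb, layers = layers,
      quantized = FALSE)
}

# Positional amplitude relative to the unit-variance token embeddings.
# Position is secondary information for bag-of-content matching; a small
# amplitude keeps token content dominant in the pooled representation
# while still breaking positional symmetry.
.POS_SCALE <- 0.1

# Fixed sinusoidal positional signal, L x d, scaled by .POS_SCALE.
.posSignal <- function(L, d) {
  pos <- seq_len(L)
  k <- seq_len(d)
  freq <- 1 / 10000^((2 * ((k - 1) %/% 2)) / d)
  ang <- outer(pos, freq)
  out <- matrix(0, L, d)
  odd <- seq(1L, d, by = 2L)
  even <- seq(2L, d, by = 2L)
  out[, odd] <- sin(ang[, odd, drop = FALSE])
  if (length(even)) out[, even] <- cos(ang[, even, drop = FALSE])
  out * .POS_SCALE
}

#' Tokenize a batch of texts (or text pairs)
#'
#' Deterministic: text is normalized and whitespace-split; each token's
#' id is `3 + (FNV-1a hash mod (V - 3))`, with reserved ids PAD = 0,
#' CLS = 1, SEP = 2. Rows follow `[CLS] tokens [SEP]` (single texts) or
#' `[CLS] A [SEP] B [SEP]` (pairs), are truncated to `maxLen` keeping a
#' trailing SEP, and padded with PAD. Identical text always yields
#' identical ids.
#'
#' @param texts Character vector of texts.
#' @param cfg An [encoderConfig()].
#' @param texts2 Optional second sentences; supplying them switches the
#'   batch into pair mode.
#' @return A [TokenizedBatch-class].
#' @export
tokenizeBatch <- function(texts, cfg = encoderConfig(), texts2 = NULL) {
  if (!length(texts)) stop("cannot tokenize an empty batch", call. = FALSE)
  pairMode <- !is.null(texts2)
  if (pairMode && length(texts2) != length(texts))
    stop("texts2 must have the same length as texts", call. = FALSE)
  V <- cfg@vocabSize
  L <- cfg@maxLen
  tokIds <- function(t) {
    toks <- strsplit(normalizeText(t), " ", fixed = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) return(integer(0))
    as.integer(3 + fnv1a32(toks) %% (V - 3))
  }
  rows <- lapply(seq_along(texts), function(i) {
    row <- c(.CLS, tokIds(texts[i]), .SEP)
    if (pairMode) row <- c(row, tokIds(texts2[i]), .SEP)
    if (length(row) > L) row <- c(row[seq_len(L - 1L)], .SEP)
    c(row, rep(.PAD, L - length(row)))
  })
  ids <- do.call(rbind, rows)
  storage.mode(ids) <- "integer"
  new("TokenizedBatch", ids = ids, mask = (ids != .PAD) * 1,
      pairMode = pairMode)
}

# Forward pass for one sequence: ids (length L) -> pooled H-vector.
# The quantized path smooths, quantizes the activation per-tensor for
# this individual sequence (so results are batch-size invariant), runs
# the integer matmul, and applies bias/relu via the quantized
# elementwise ops.
.forwardSequence <- function(ids, mask, enc) {
  cfg <- enc@config
  X <- enc@embedding[ids + 1L, , drop = FALSE] +
    .posSignal(cfg@maxLen, cfg@embedDim)
  nL <- cfg@nLayers
  if (!enc@quantized) {
    for (l in seq_len(nL)) {
      X <- X %*% enc@layers[[l]]$W
      X <- sweep(X, 2L, enc@layers[[l]]$b, "+")
      if (l < nL) X <- pmax(X, 0)
    }
  } else {
    for (l in seq_len(nL)) {
      ql <- enc@qlayers[[l]]
      Xs <- sweep(X, 2L, ql$smooth, "/")
      xq <- quantize(Xs, perTensor())
      X <- qlinearMatmul(xq, ql$Wq)
      X <- qlinearElementwise(X, ql$b, "add")
      if (l < nL) X <- qlinearElementwise(X, op = "relu")
    }
  }
  if (cfg@pooling == "full") colMeans(X) else colMeans(X[mask == 1, , drop = FALSE])
}

#' Encode a tokenized batch into per-text embeddings
#'
#' Runs the forward pass (FP32 or quantized, depending on the model) and
#' mean-pools the hidden states over the sequence length. With the
#' default `pooling = "full"` the mean runs over all `maxLen` positions,
#' padding included; `"masked"` averages non-pad positions only.
#'
#' @param batch A [TokenizedBatch-class].
#' @param model A [TextEncoder-class].
#' @return Numeric matrix, one row per text, `hiddenDim` columns.
#' @export
encodeBatch <- function(batch, model) {
  if (ncol(batch@ids) != model@config@maxLen)
    stop("batch length does not match the model's maxLen", call. = FALSE)
  out <- t(vapply(seq_len(nrow(batch@ids)), function(i) {
    .forwardSequence(batch@ids[i, ], batch@mask[i, ], model)
  }, numeric(model@config@hiddenDim)))
  out
}

#' Encode a corpus in batches and stack the embeddings
#'
#' Partitions the N texts into `ceiling(N / batchSize)` consecutive
#' batches (the last may be short), encodes each, and stacks rows in
#' input order. Activation quantization is dynamic per individual
#' sequence, so the result is identical for every batch size.
#'
#' @param texts Character vector.
#' @param model A [TextEncoder-class].
#' @param batchSize Batch size B >= 1 (default 10).
#' @param provenance Corpus tag stored on the result.
#' @return An [EmbeddingMatrix-class], N x hiddenDim.
#' @export
encodeCorpus <- function(texts, model, batchSize = 10L,
                         provenance = "unspecified") {
  if (!length(texts)) stop("cannot encode an empty corpus", call. = FALSE)
  if (batchSize < 1L) stop("batchSize must be >= 1", call. = FALSE)
  idx <- split(seq_along(texts), ceiling(seq_along(texts) / batchSize))
  blocks <- lapply(idx, function(ix) {
    encodeBatch(tokenizeBatch(texts[ix], model@config), model)
  })
  e <- do.call(rbind, blocks)
  rownames(e) <- NULL
  new("EmbeddingMatrix", e, provenance = provenance)
}

#' Collect per-layer activation statistics on a calibration corpus
#'
#' Runs the FP32 forward pass over the calibration texts and records,
#' for the input of every linear layer, the per-channel maximum absolute
#' activation and variance over all token positions.
#'
#' @param encoder A FP32 [TextEncoder-class].
#' @param calibrationTexts Non-empty character vector.
#' @return List with one [ActivationStats-class] per layer.
#' @export
collectActivationStats <- function(encoder, calibrationTexts) {
  if (!length(calibrationTexts))
    stop("calibration set must be non-empty", call. = FALSE)
  if (encoder@quantized)
    stop("calibration requires the FP32 encoder", call. = FALSE)
  cfg <- encoder@config
  batch <- tokenizeBatch(calibrationTexts, cfg)
  nL <- cfg@nLayers
  acc <- vector("list", nL)
  pos <- .posSignal(cfg@maxLen, cfg@embedDim)
  for (i in seq_len(nrow(batch@ids))) {
    X <- encoder@embedding[batch@ids[i, ] + 1L, , drop = FALSE] + pos
    for (l in seq_len(nL)) {
      acc[[l]] <- rbind(acc[[l]], X)
      X <- sweep(X %*% encoder@layers[[l]]$W, 2L, encoder@layers[[l]]$b, "+")
      if (l < nL) X <- pmax(X, 0)
    }
  }
  lapply(acc, function(A) {
    new("ActivationStats",
        maxabs = apply(abs(A), 2L, max),
        variance = apply(A, 2L, stats::var),
        nSamples = nrow(A))
  })
}

#' Quantize an encoder to simulated INT8 (W8A8)
#'
#' For every linear layer: compute smoothing scales from calibration
#' statistics (all-ones when `smoothing = NULL`), fold them into the
#' weights, and quantize the smoothed weights (per output channel by
#' default). The returned encoder's forward pass divides activations by
#' the smoothing scales, quantizes them dynamically per-tensor per
#' sequence, and routes through [qlinearMatmul()] and
#' [qlinearElementwise()]. Biases stay FP32.
#'
#' @param encoder A FP32 [TextEncoder-class].
#' @param calibrationTexts Non-empty calibration corpus.
#' @param scheme Weight quantization scheme: [perChannel()] on output
#'   columns (default) or [perTensor()].
#' @param smoothing A [smoothingConfig()], or `NULL` for no smoothing.
#' @return A quantized [TextEncoder-class].
#' @export
quantizeEncoder <- function(encoder, calibrationTexts,
                            scheme = perChannel(2L),
                            smoothing = smoothingConfig()) {
  stats <- collectActivationStats(encoder, calibrationTexts)
  qlayers <- lapply(seq_along(encoder@layers), function(l) {
    W <- encoder@layers[[l]]$W
    s <- if (is.null(smoothing)) rep(1, nrow(W))
         else computeSmoothingScales(stats[[l]], W, smoothing)
    list(Wq = quantize(W * s, scheme), b = encoder@layers[[l]]$b, smooth = s)
  })
  new("TextEncoder", config = encoder@config, embedding = encoder@embedding,
      layers = encoder@layers, quantized = TRUE, qlayers = qlayers,
      smoothing = if (is.null(smoothing)) list() else list(smoothing))
}

#' Serialized payload size of the quantizable weights
#'
#' Byte count of the linear-layer weight payload under the documented
#' archive layout: FP32 weights cost 4 bytes per value; quantized layers
#' cost 1 byte per int8 grid value plus 4 bytes per weight scale and 4
#' bytes per smoothing scale. Biases are excluded on both sides (they
#' are never quantized).
#'
#' @param encoder A [TextEncoder-class].
#' @return Number of bytes.
#' @export
payloadBytes <- function(encoder) {
  if (!encoder@quantized) {
    sum(vapply(encoder@layers, function(l) 4 * length(l$W), numeric(1)))
  } else {
    sum(vapply(encoder@qlayers, function(l) {
      length(l$Wq@q) + 4 * length(l$Wq@scales) + 4 * length(l$smooth)
    }, numeric(1)))
  }
}

#' Write an encoder archive
#'
#' Single JSON archive (version 1) holding the config, the token
#' embedding, and either FP32 layer weights or integer grids with their
#' scale vectors, scheme metadata and smoothing scales, plus a hash of
#' the serialized config.
#'
#' @param encoder A [TextEncoder-class].
#' @param path Output path (`.json`).
#' @export
writeEncoderArchive <- function(encoder, path) {
  cfg <- encoder@config
  cfgList <- list(vocabSize = cfg@vocabSize, embedDim = cfg@embedDim,
                  hiddenDim = cfg@hiddenDim, nLayers = cfg@nLayers,
                  maxLen = cfg@maxLen, seed = cfg@seed, pooling = cfg@pooling)
  obj <- list(format = "quantalign-encoder", version = 1L,
              quantized = encoder@quantized, config = cfgList,
              configHash = fnv1a32(paste(unlist(cfgList), collapse = "|")),
              embedding = encoder@embedding)
  if (!encoder@quantized) {
    obj$layers <- lapply(encoder@layers, function(l) list(W = l$W, b = l$b))
  } else {
    obj$qlayers <- lapply(encoder@qlayers, function(l) list(
      q = l$Wq@q, scales = l$Wq@scales,
      granularity = l$Wq@scheme@granularity, axis = l$Wq@scheme@axis,
      shape = l$Wq@shape, b = l$b, smooth = l$smooth))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read an encoder archive written by [writeEncoderArchive()]
#'
#' @param path Archive path.
#' @return A [TextEncoder-class].
#' @export
readEncoderArchive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "quantalign-encoder") || obj$version != 1L)
    stop("not a version-1 encoder archive: ", path, call. = FALSE)
  cl <- obj$config
  cfg <- encoderConfig(cl$vocabSize, cl$embedDim, cl$hiddenDim, cl$nLayers,
                       cl$maxLen, cl$seed, cl$pooling)
  emb <- as.matrix(obj$embedding)
  if (!isTRUE(obj$quantized)) {
    layers <- lapply(obj$layers, function(l)
      list(W = as.matrix(l$W), b = as.numeric(l$b)))
    new("TextEncoder", config = cfg, embedding = emb, layers = layers,
        quantized = FALSE)
  } else {
    qlayers <- lapply(obj$qlayers, function(l) {
      sch <- if (l$granularity == "per_channel") perChannel(l$axis) else perTensor()
      list(Wq = new("QuantizedTensor", q = as.matrix(l$q),
                    scales = as.numeric(l$scales), scheme = sch,
                    shape = as.integer(l$shape)),
           b = as.numeric(l$b), smooth = as.numeric(l$smooth))
    })
    new("TextEncoder", config = cfg, embedding = emb, layers = list(),
        quantized = TRUE, qlayers = qlayers)
  }
}
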