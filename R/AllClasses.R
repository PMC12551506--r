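#' Quantization scheme descriptor
#'
#' Describes how a real tensor is mapped onto the signed INT8 grid:
#' one scale for the whole tensor (`per_tensor`) or one scale per channel
#' along `axis` (`per_channel`). Only symmetric 8-bit quantization with
#' zero-point 0 and range \[-127, 127\] is supported.
#'
#' @slot granularity `"per_tensor"` or `"per_channel"`.
#' @slot axis Channel axis (1 = rows, 2 = columns); meaningful only for
#'   per-channel schemes.
#' @slot bits Bit width, fixed at 8.
#' @slot symmetric Always `TRUE`: the grid is symmetric about zero.
#' @export
setClass("QuantScheme",
  representation(granularity = "character", axis = "integer",
                 bits = "integer", symmetric = "logical"),
  prototype(granularity = "per_tensor", axis = NA_integer_,
            bits = 8L, symmetric = TRUE))

setValidity("QuantScheme", function(object) {
  msg <- character(0)
  if (!object@granularity %in% c("per_tensor", "per_channel"))
    msg <- c(msg, "granularity must be 'per_tensor' or 'per_channel'")
  if (object@bits != 8L)
    msg <- c(msg, "only 8-bit quantization is supported")
  if (!isTRUE(object@symmetric))
    msg <- c(msg, "only symmetric quantization is supported")
  if (object@granularity == "per_channel" &&
      (is.na(object@axis) || !object@axis %in% c(1L, 2L)))
    msg <- c(msg, "per_channel scheme needs axis 1 or 2")
  if (object@granularity == "per_tensor" && !is.na(object@axis))
    msg <- c(msg, "per_tensor scheme must not define an axis")
  if (length(msg)) msg else TRUE
})

#' @describeIn QuantScheme Per-tensor scheme constructor.
#' @export
perTensor <- function() new("QuantScheme")

#' @describeIn QuantScheme Per-channel scheme constructor.
#' @param axis Channel axis (1 = rows, 2 = columns).
#' @export
perChannel <- function(axis = 2L) {
  new("QuantScheme", granularity = "per_channel", axis = as.integer(axis))
}

#' Quantized tensor
#'
#' An integer grid in \[-127, 127\] together with the positive scale(s)
#' that map it back to real values. This is the unit of all simulated
#' W8A8 arithmetic: matrix products accumulate the integer grids exactly
#' and apply the scales afterwards.
#'
#' @slot q Integer matrix (vectors are stored as a single row).
#' @slot scales Positive scale(s): length 1 for per-tensor, one per
#'   channel along the scheme's axis for per-channel.
#' @slot scheme A [QuantScheme-class].
#' @slot shape Original shape of the quantized array.
#' @export
setClass("QuantizedTensor",
  representation(q = "matrix", scales = "numeric",
                 scheme = "QuantScheme", shape = "integer"))

setValidity("QuantizedTensor", function(object) {
  msg <- character(0)
  if (any(abs(object@q) > 127)) msg <- c(msg, "grid values must lie in [-127, 127]")
  if (any(object@scales <= 0)) msg <- c(msg, "scales must be strictly positive")
  if (object@scheme@granularity == "per_tensor" && length(object@scales) != 1L)
    msg <- c(msg, "per_tensor tensor must carry exactly one scale")
  if (object@scheme@granularity == "per_channel" &&
      length(object@scales) != dim(object@q)[object@scheme@axis])
    msg <- c(msg, "per_channel scales length must equal the size along the axis")
  if (length(msg)) msg else TRUE
})

#' @describeIn QuantizedTensor Integer grid accessor.
#' @param x A `QuantizedTensor`.
#' @export
quantGrid <- function(x) x@q

#' @describeIn QuantizedTensor Scale accessor.
#' @export
quantScales <- function(x) x@scales

#' @describeIn QuantizedTensor Scheme accessor.
#' @export
quantScheme <- function(x) x@scheme

setMethod("show", "QuantizedTensor", function(object) {
  cat(sprintf("QuantizedTensor %s [%s], int8 grid, %d scale(s)\n",
              paste(object@shape, collapse = "x"),
              object@scheme@granularity, length(object@scales)))
})

#' Smoothing configuration
#'
#' Parameters of the outlier-redistribution step that migrates activation
#' range difficulty into the weights via a per-input-channel diagonal
#' rescaling. `alpha` balances the two sides (0 = all burden on weights,
#' 1 = all on activations); `epsilon` floors degenerate channel ranges.
#'
#' @slot alpha Smoothing factor in \[0, 1\]; default 0.5.
#' @slot epsilon Positive floor applied to channel maxima before the
#'   power-ratio formula.
#' @export
setClass("SmoothingConfig",
  representation(alpha = "numeric", epsilon = "numeric"),
  prototype(alpha = 0.5, epsilon = 1e-8))

setValidity("SmoothingConfig", function(object) {
  msg <- character(0)
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SmoothingConfig Constructor.
#' @param alpha Smoothing factor in \[0, 1\].
#' @param epsilon Positive floor for channel maxima.
#' @export
smoothingConfig <- function(alpha = 0.5, epsilon = 1e-8) {
  new("SmoothingConfig", alpha = alpha, epsilon = epsilon)
}

#' Per-channel activation statistics
#'
#' Collected by running the FP32 forward pass on a calibration corpus:
#' for each input channel of a linear layer, the maximum absolute
#' activation and the variance over all calibration token positions.
#'
#' @slot maxabs Non-negative per-channel maximum absolute values.
#' @slot variance Per-channel variances.
#' @slot nSamples Number of token rows observed.
#' @export
setClass("ActivationStats",
  representation(maxabs = "numeric", variance = "numeric", nSamples = "integer"))

setValidity("ActivationStats", function(object) {
  msg <- character(0)
  if (any(object@maxabs < 0)) msg <- c(msg, "maxabs must be non-negative")
  if (length(object@maxabs) != length(object@variance))
    msg <- c(msg, "maxabs and variance must have equal length")
  if (length(msg)) msg else TRUE
})

#' Encoder configuration
#'
#' Hyperparameters of the deterministic positionwise text encoder. All
#' weights derive from `seed`, so a config fully determines the model.
#'
#' @slot vocabSize Vocabulary size V (ids 0..V-1; 0 = PAD, 1 = CLS, 2 = SEP).
#' @slot embedDim Token embedding dimension d.
#' @slot hiddenDim Output hidden dimension H.
#' @slot nLayers Number of linear blocks.
#' @slot maxLen Maximum sequence length L (padding/truncation target).
#' @slot seed Integer seed for weight initialization.
#' @slot pooling `"full"` (mean over all L positions, padding included) or
#'   `"masked"` (mean over non-pad positions only).
#' @export
setClass("EncoderConfig",
  representation(vocabSize = "integer", embedDim = "integer",
                 hiddenDim = "integer", nLayers = "integer",
                 maxLen = "integer", seed = "integer", pooling = "character"),
  prototype(vocabSize = 4096L, embedDim = 192L, hiddenDim = 384L,
            nLayers = 2L, maxLen = 512L, seed = 1L, pooling = "full"))

setValidity("EncoderConfig", function(object) {
  msg <- character(0)
  dims <- c(object@vocabSize, object@embedDim, object@hiddenDim,
            object@nLayers, object@maxLen)
  if (any(dims <= 0)) msg <- c(msg, "all dimensions must be positive")
  if (object@maxLen < 3L) msg <- c(msg, "maxLen must be >= 3 (room for CLS and SEP)")
  if (object@vocabSize <= 3L) msg <- c(msg, "vocabSize must exceed the 3 reserved ids")
  if (!object@pooling %in% c("full", "masked"))
    msg <- c(msg, "pooling must be 'full' or 'masked'")
  if (length(msg)) msg else TRUE
})

#' @describeIn EncoderConfig Constructor. The default dimensions
#'   (d = 192, H = 384) are sized so the random-feature map preserves
#'   token-overlap geometry well enough for reliable alignment at desk
#'   scale; smaller encoders distort cosine margins noticeably.
#' @param vocabSize,embedDim,hiddenDim,nLayers,maxLen,seed,pooling See slots.
#' @export
encoderConfig <- function(vocabSize = 4096L, embedDim = 192L, hiddenDim = 384L,
                          nLayers = 2L, maxLen = 512L, seed = 1L,
                          pooling = c("full", "masked")) {
  pooling <- match.arg(pooling)
  new("EncoderConfig", vocabSize = as.integer(vocabSize),
      embedDim = as.integer(embedDim), hiddenDim = as.integer(hiddenDim),
      nLayers = as.integer(nLayers), maxLen = as.integer(maxLen),
      seed = as.integer(seed), pooling = pooling)
}

#' Text encoder with FP32 and quantized execution paths
#'
#' A deterministic positionwise encoder: token-embedding lookup plus a
#' fixed sinusoidal positional signal, followed by `nLayers` linear blocks
#' (matmul, bias add, ReLU; the final block omits the ReLU), then mean
#' pooling over the sequence. When `quantized` is `TRUE` the linear
#' layers hold smoothed, integer-quantized weights and the forward pass
#' routes through the simulated W8A8 operators with dynamic per-tensor
#' activation quantization computed per individual sequence.
#'
#' @slot config An [EncoderConfig-class].
#' @slot embedding V x d token embedding matrix (PAD row is all zero).
#' @slot layers List of FP32 layers, each `list(W, b)`.
#' @slot quantized Logical flag.
#' @slot qlayers For quantized encoders: list of
#'   `list(Wq = QuantizedTensor, b, smooth)` per layer, where `smooth` is
#'   the per-input-channel smoothing scale vector.
#' @slot smoothing The [SmoothingConfig-class] used, or empty list.
#' @export
setClass("TextEncoder",
  representation(config = "EncoderConfig", embedding = "matrix",
                 layers = "list", quantized = "logical",
                 qlayers = "list", smoothing = "list"),
  prototype(quantized = FALSE, qlayers = list(), smoothing = list()))

setMethod("show", "TextEncoder", function(object) {
  cfg <- object@config
  cat(sprintf("TextEncoder (%s): V=%d d=%d H=%d layers=%d L=%d seed=%d pooling=%s\n",
              if (object@quantized) "INT8 W8A8" else "FP32",
              cfg@vocabSize, cfg@embedDim, cfg@hiddenDim, cfg@nLayers,
              cfg@maxLen, cfg@seed, cfg@pooling))
})

#' @describeIn TextEncoder Config accessor.
#' @param x A `TextEncoder`.
#' @export
encoderConfigOf <- function(x) x@config

#' @describeIn TextEncoder Is the encoder quantized?
#' @export
isQuantized <- function(x) x@quantized

#' Tokenized batch
#'
#' Integer id grid and mask for a batch of texts. Every row starts with
#' CLS (id 1) and carries at least one SEP (id 2); mask is 0 exactly on
#' PAD (id 0) positions. In pair mode rows follow the layout
#' `[CLS] A [SEP] B [SEP]`.
#'
#' @slot ids B x L integer matrix of token ids.
#' @slot mask B x L 0/1 matrix.
#' @slot pairMode Logical: two-sentence encoding.
#' @export
setClass("TokenizedBatch",
  representation(ids = "matrix", mask = "matrix", pairMode = "logical"))

setValidity("TokenizedBatch", function(object) {
  msg <- character(0)
  if (any(object@ids[, 1L] != 1L)) msg <- c(msg, "every row must start with CLS (id 1)")
  if (any(rowSums(object@ids == 2L) < 1L)) msg <- c(msg, "every row must contain a SEP (id 2)")
  if (!identical(dim(object@ids), dim(object@mask)))
    msg <- c(msg, "ids and mask must share dimensions")
  if (any((object@mask == 0) != (object@ids == 0L)))
    msg <- c(msg, "mask must be 0 exactly on PAD positions")
  if (length(msg)) msg else TRUE
})

#' Embedding matrix with provenance
#'
#' A stacked matrix of mean-pooled text embeddings (one row per input
#' text, in input order) tagged with the corpus it came from.
#'
#' @slot .Data N x H numeric matrix.
#' @slot provenance Corpus tag, e.g. `"LEX"` or `"ONTO"`.
#' @export
setClass("EmbeddingMatrix", contains = "matrix",
  representation(provenance = "character"),
  prototype(provenance = "unspecified"))

#' @describeIn EmbeddingMatrix Provenance accessor.
#' @param x An `EmbeddingMatrix`.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix [%s]: %d texts x %d dims\n",
              object@provenance, nrow(object), ncol(object)))
})
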