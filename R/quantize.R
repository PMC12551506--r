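# Simulated W8A8 arithmetic. All grids are symmetric signed int8 in
# [-127, 127] with zero-point 0; rounding is round-half-to-even (base
# round()), which is unbiased and reproducible across platforms.

.QEPS <- 1e-12  # scale floor for all-zero tensors/channels

#' Quantize a real tensor onto the signed INT8 grid
#'
#' Per-tensor: one scale `s = max(|x|)/127` (floored at a tiny epsilon
#' for all-zero input). Per-channel: one scale per slice along the
#' scheme's axis. The grid is `clamp(round(x/s), -127, 127)` with
#' round-half-to-even.
#'
#' @param x Numeric vector or matrix; must be finite.
#' @param scheme A [QuantScheme-class]; default per-tensor.
#' @return A [QuantizedTensor-class].
#' @export
quantize <- function(x, scheme = perTensor()) {
  .assertFinite(x, "tensor to quantize")
  shape <- if (is.matrix(x)) dim(x) else length(x)
  m <- .asMatrix(x)
  if (scheme@granularity == "per_tensor") {
    s <- max(abs(m)) / 127
    if (s == 0) s <- .QEPS
    q <- pmin(pmax(round(m / s), -127), 127)
  } else {
    ax <- scheme@axis
    if (ax > length(dim(m)))
      stop("per_channel axis out of range for this tensor", call. = FALSE)
    s <- apply(abs(m), ax, max) / 127
    s[s == 0] <- .QEPS
    q <- if (ax == 1L) round(m / s) else round(sweep(m, 2L, s, "/"))
    q <- pmin(pmax(q, -127), 127)
  }
  new("QuantizedTensor", q = matrix(as.numeric(q), nrow(m), ncol(m)),
      scales = as.numeric(s), scheme = scheme, shape = as.integer(shape))
}

#' Dequantize back to real values
#'
#' Returns `q * scale`, broadcast along the channel axis for per-channel
#' tensors. The round-trip error of `dequantize(quantize(x))` is bounded
#' elementwise by half the relevant scale.
#'
#' @param t A [QuantizedTensor-class].
#' @return Numeric vector or matrix with the original shape.
#' @export
dequantize <- function(t) {
  q <- t@q
  x <- if (t@scheme@granularity == "per_tensor") {
    q * t@scales
  } else if (t@scheme@axis == 1L) {
    q * t@scales
  } else {
    sweep(q, 2L, t@scales, "*")
  }
  if (length(t@shape) == 1L) as.numeric(x) else x
}

#' Quantized matrix product with exact integer accumulation
#'
#' Computes `y[i,j] = (sum_k qx[i,k] * qW[k,j]) * s_x * s_j`: the integer
#' grids are accumulated exactly (int32-style; R doubles hold the sums
#' exactly at supported sizes), then the activation scale and the
#' weight's (per-column or per-tensor) scale are applied. Activations
#' must be per-tensor; per-channel activations combined with per-channel
#' weights have channel-coupled scales that cannot be factored out of
#' the accumulation, so that combination is rejected as
#' non-dequantizable.
#'
#' @param xq Activations: per-tensor [QuantizedTensor-class].
#' @param Wq Weights: [QuantizedTensor-class], per-channel on output
#'   columns (axis 2) or per-tensor.
#' @return Real matrix, equal to the product of the dequantized operands
#'   up to float rounding.
#' @export
qlinearMatmul <- function(xq, Wq) {
  if (xq@scheme@granularity != "per_tensor")
    stop("non-dequantizable scheme combination: per-channel activations ",
         "cannot be combined with per-channel weights", call. = FALSE)
  if (Wq@scheme@granularity == "per_channel" && Wq@scheme@axis != 2L)
    stop("non-dequantizable scheme combination: weight channel axis must ",
         "be the output-column axis", call. = FALSE)
  if (ncol(xq@q) != nrow(Wq@q))
    stop("inner dimensions do not agree", call. = FALSE)
  yInt <- xq@q %*% Wq@q
  if (Wq@scheme@granularity == "per_tensor") {
    yInt * (xq@scales * Wq@scales)
  } else {
    sweep(yInt, 2L, Wq@scales * xq@scales, "*")
  }
}

#' Quantized elementwise operators (add, relu)
#'
#' Dequantize-then-apply semantics: operands that are
#' [QuantizedTensor-class] objects are dequantized, then the op is
#' applied in real arithmetic. `add` accepts a matrix plus a same-shape
#' matrix or a vector broadcast across rows; `relu` takes one operand.
#'
#' @param a First operand (QuantizedTensor or numeric).
#' @param b Second operand for `add` (QuantizedTensor, matrix, or
#'   vector of length `ncol(a)`); ignored for `relu`.
#' @param op `"add"` or `"relu"`.
#' @return Real vector or matrix.
#' @export
qlinearElementwise <- function(a, b = NULL, op = c("add", "relu")) {
  op <- match.arg(op)
  av <- if (is(a, "QuantizedTensor")) dequantize(a) else a
  if (op == "relu") return(pmax(av, 0))
  bv <- if (is(b, "QuantizedTensor")) dequantize(b) else b
  if (is.null(bv)) stop("add requires two operands", call. = FALSE)
  am <- .asMatrix(av)
  if (!is.matrix(bv) && length(bv) == ncol(am)) {
    out <- sweep(am, 2L, bv, "+")
  } else {
    bm <- .asMatrix(bv)
    if (!identical(dim(am), dim(bm)))
      stop("shape mismatch in quantized add", call. = FALSE)
    out <- am + bm
  }
  if (!is.matrix(av) && !is.matrix(bv) && nrow(out) == 1L) as.numeric(out) else out
}

#' Compute smoothing scales from calibration statistics
#'
#' The per-input-channel scale `s_j = max(maxX_j, eps)^alpha /
#' max(maxW_j, eps)^(1-alpha)`, where `maxX_j` is the calibration
#' maximum absolute activation of channel j and `maxW_j` the maximum
#' absolute weight in row j. With `alpha = 0.5` the channel's range
#' difficulty is split evenly between activations and weights.
#'
#' @param stats An [ActivationStats-class] for the layer input.
#' @param W Real weight matrix (input channels in rows).
#' @param cfg A [smoothingConfig()].
#' @return Strictly positive numeric vector, one scale per input channel.
#' @export
computeSmoothingScales <- function(stats, W, cfg = smoothingConfig()) {
  if (length(stats@maxabs) != nrow(W))
    stop("activation channel count must equal the weight input-row count",
         call. = FALSE)
  maxW <- apply(abs(W), 1L, max)
  s <- pmax(stats@maxabs, cfg@epsilon)^cfg@alpha /
       pmax(maxW, cfg@epsilon)^(1 - cfg@alpha)
  s
}

#' Apply smoothing scales to an activation/weight pair
#'
#' Divides activation column j by `s_j` and multiplies weight row j by
#' `s_j`; the layer's product is unchanged (exactly, in exact
#' arithmetic), while activation outlier channels shrink and the
#' corresponding weight rows absorb the range.
#'
#' @param X Real activation matrix (channels in columns).
#' @param W Real weight matrix (channels in rows).
#' @param s Strictly positive scale vector, length = shared inner dim.
#' @return List with elements `X` and `W`.
#' @export
applySmoothing <- function(X, W, s) {
  if (any(s <= 0)) stop("smoothing scales must be strictly positive", call. = FALSE)
  if (length(s) != ncol(X) || length(s) != nrow(W))
    stop("smoothing scale length must match the shared inner dimension",
         call. = FALSE)
  list(X = sweep(X, 2L, s, "/"), W = W * s)
}
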