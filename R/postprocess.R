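#' Min-max rescaling of raw similarity scores
#'
#' Maps the observed minimum to `lo` and maximum to `hi`, preserving
#' order: `y = lo + (x - min)(hi - lo)/(max - min)`. A constant input
#' has no similarity evidence and maps conservatively to `lo`
#' (configurable via `constantTo`).
#'
#' @param scores Non-empty numeric vector.
#' @param lo,hi Target bounds, `hi > lo` (defaults 0 and 5, the
#'   six-point rating scale).
#' @param constantTo Value (default `lo`) for degenerate constant input.
#' @return Numeric vector in \[lo, hi\].
#' @export
minmaxRescale <- function(scores, lo = 0, hi = 5, constantTo = lo) {
  if (!length(scores)) stop("cannot rescale an empty score vector", call. = FALSE)
  if (hi <= lo) stop("hi must exceed lo", call. = FALSE)
  rng <- range(scores)
  if (rng[1L] == rng[2L]) return(rep(constantTo, length(scores)))
  lo + (scores - rng[1L]) * (hi - lo) / (rng[2L] - rng[1L])
}

#' Complementarity merge of two models' rated alignments
#'
#' Iterates the rating r from 5 down to 0; at each r it first admits the
#' primary model's alignments rated r whose source is not yet covered,
#' then the secondary model's. The merged set covers exactly the union
#' of source keys, keeps at most one alignment per source, and retains
#' every primary rating-5 alignment verbatim.
#'
#' @param primarySet,secondarySet data.frames with columns `source_key`,
#'   `target_key`, `score`, `rating` (integers 0-5) and optionally
#'   `model_tag`; at most one row per source within each input.
#' @param minRating Drop merged alignments rated below this (default 0,
#'   i.e. keep everything).
#' @return Merged data.frame in admission order, with a `model_tag`
#'   column recording the contributing side.
#' @export
complementarityMerge <- function(primarySet, secondarySet, minRating = 0L) {
  .checkRated <- function(x, what) {
    need <- c("source_key", "target_key", "score", "rating")
    if (!all(need %in% names(x)))
      stop(what, " needs columns source_key, target_key, score, rating",
           call. = FALSE)
    if (anyDuplicated(x$source_key))
      stop("duplicate source_key in ", what, call. = FALSE)
    if (nrow(x) && (any(x$rating < 0L) || any(x$rating > 5L)))
      stop("ratings in ", what, " must lie in 0..5", call. = FALSE)
    if (is.null(x$model_tag)) x$model_tag <- what
    x
  }
  a <- .checkRated(primarySet, "primary")
  b <- .checkRated(secondarySet, "secondary")
  covered <- character(0)
  out <- list()
  for (r in 5L:0L) {
    for (side in list(a, b)) {
      hit <- side[side$rating == r & !(side$source_key %in% covered), ,
                  drop = FALSE]
      if (nrow(hit)) {
        out[[length(out) + 1L]] <- hit
        covered <- c(covered, hit$source_key)
      }
    }
  }
  merged <- if (length(out)) do.call(rbind, out) else a[0, , drop = FALSE]
  merged <- merged[merged$rating >= minRating, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Pareto frontier of (quality, cost) evaluation points
#'
#' Returns every point not strictly dominated: a point is dominated if
#' another has quality >= and cost <= with at least one strict
#' inequality. Exact duplicates are all retained. Equals the exhaustive
#' pairwise-dominance scan on every input.
#'
#' @param points data.frame with numeric columns `quality` and `cost`.
#' @return The non-dominated sublist (rows of `points`, original order),
#'   with the original row positions in attribute `"indices"`.
#' @export
paretoFrontier <- function(points) {
  if (!nrow(points)) stop("cannot take the frontier of an empty set", call. = FALSE)
  q <- points$quality; cst <- points$cost
  keep <- vapply(seq_along(q), function(i) {
    !any(q >= q[i] & cst <= cst[i] & (q > q[i] | cst < cst[i]))
  }, logical(1))
  out <- points[keep, , drop = FALSE]
  attr(out, "indices") <- which(keep)
  out
}

#' Quantization-candidate descriptor
#'
#' @param granularity `"per_tensor"` or `"per_channel"` weight scheme.
#' @param alpha Smoothing factor in \[0, 1\], or `NULL` for no smoothing.
#' @param label Candidate name (auto-built if missing).
#' @return A list of class `QuantCandidate`.
#' @export
quantCandidate <- function(granularity = c("per_channel", "per_tensor"),
                           alpha = 0.5, label = NULL) {
  granularity <- match.arg(granularity)
  if (!is.null(alpha) && (alpha < 0 || alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (is.null(label))
    label <- paste0(granularity,
                    if (is.null(alpha)) "+raw" else paste0("+alpha", alpha))
  structure(list(granularity = granularity, alpha = alpha, label = label),
            class = "QuantCandidate")
}

#' Search constraints for the quantization-configuration search
#'
#' @param maxDegradation Maximum admissible quality degradation relative
#'   to the FP32 reference (default 1e-4, i.e. 0.01%).
#' @param minCostReduction Minimum fractional payload-size reduction
#'   versus FP32 (default 0.20). Serialized size is the deterministic
#'   desk-scale proxy for the latency-improvement constraint.
#' @return A list of class `QuantConstraints`.
#' @export
quantConstraints <- function(maxDegradation = 1e-4, minCostReduction = 0.20) {
  if (maxDegradation < 0 || maxDegradation > 1 ||
      minCostReduction < 0 || minCostReduction > 1)
    stop("constraints must lie in [0, 1]", call. = FALSE)
  structure(list(maxDegradation = maxDegradation,
                 minCostReduction = minCostReduction),
            class = "QuantConstraints")
}

#' Exhaustive constraint-filtered search over quantization configurations
#'
#' Quantizes the FP32 reference encoder under each candidate (using the
#' lexicon and ontology texts as the calibration corpus), measures
#' quality as the fraction of lexicon entries whose argmax alignment
#' agrees with the FP32 alignment, and cost as the serialized weight
#' payload in bytes. A candidate is feasible when its degradation
#' `1 - quality` is at most `maxDegradation` and its payload shrinks by
#' at least `minCostReduction` versus FP32. The candidate space is
#' finite and evaluated exhaustively; the best configuration is the
#' feasible frontier point with the highest quality (ties broken toward
#' the lowest cost). An empty feasible set is reported, not an error.
#'
#' @param candidates Non-empty list of [quantCandidate()] objects.
#' @param fpEncoder The FP32 reference [TextEncoder-class].
#' @param lexicon,ontology Evaluation corpora (as for [alignCorpora()]).
#' @param constraints A [quantConstraints()].
#' @param batchSize Encoding batch size.
#' @return List with `points` (data.frame: label, quality, cost,
#'   degradation, cost_reduction, feasible), `frontier` (row indices of
#'   the Pareto frontier), `best` (row index or `NA`), and
#'   `fp32_bytes`.
#' @export
searchQuantConfigs <- function(candidates, fpEncoder, lexicon, ontology,
                               constraints = quantConstraints(),
                               batchSize = 10L) {
  if (!length(candidates)) stop("candidate list is empty", call. = FALSE)
  calib <- c(lexicon$concat_text, ontology$str_text)
  ref <- alignCorpora(lexicon, ontology, fpEncoder, batchSize)
  fpBytes <- payloadBytes(fpEncoder)
  rows <- lapply(candidates, function(cand) {
    scheme <- if (cand$granularity == "per_channel") perChannel(2L) else perTensor()
    sm <- if (is.null(cand$alpha)) NULL else smoothingConfig(alpha = cand$alpha)
    qenc <- quantizeEncoder(fpEncoder, calib, scheme, sm)
    ali <- alignCorpora(lexicon, ontology, qenc, batchSize)
    quality <- mean(ali$target_index == ref$target_index)
    cost <- payloadBytes(qenc)
    data.frame(label = cand$label, quality = quality, cost = cost,
               degradation = 1 - quality,
               cost_reduction = 1 - cost / fpBytes,
               stringsAsFactors = FALSE)
  })
  points <- do.call(rbind, rows)
  points$feasible <- points$degradation <= constraints$maxDegradation &
    points$cost_reduction >= constraints$minCostReduction
  frontier <- attr(paretoFrontier(points), "indices")
  feasFront <- intersect(frontier, which(points$feasible))
  best <- if (length(feasFront)) {
    ord <- feasFront[order(-points$quality[feasFront], points$cost[feasFront])]
    ord[1L]
  } else NA_integer_
  list(points = points, frontier = frontier, best = best, fp32_bytes = fpBytes)
}
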