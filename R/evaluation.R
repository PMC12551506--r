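#' EDRM: mean relative distance to the reference similarity scores
#'
#' For predictions h and references r on a \[lo, hi\] scale,
#' `EDRM = mean(1 - d_i / dmax_i)` with `d_i = |h_i - r_i|` and
#' `dmax_i = max(r_i - lo, hi - r_i)`, the maximum distance achievable
#' from that reference on the legal scale. Predictions are clamped into
#' \[lo, hi\] before scoring so the metric stays within \[0, 1\] for
#' arbitrary raw scores. (With `hi > lo`, `dmax_i` is always positive;
#' a degenerate `dmax_i = 0` term would contribute 1 exactly when
#' `d_i = 0`.)
#'
#' @param h Numeric predictions.
#' @param r Numeric references in \[lo, hi\].
#' @param lo,hi Scale bounds (defaults 0 and 5).
#' @return EDRM in \[0, 1\].
#' @export
edrm <- function(h, r, lo = 0, hi = 5) {
  if (!length(h)) stop("EDRM needs at least one prediction", call. = FALSE)
  if (length(h) != length(r)) stop("h and r must have equal length", call. = FALSE)
  if (any(r < lo | r > hi)) stop("references must lie in [lo, hi]", call. = FALSE)
  h <- pmin(pmax(h, lo), hi)
  d <- abs(h - r)
  dmax <- pmax(r - lo, hi - r)
  term <- ifelse(dmax == 0, as.numeric(d == 0), 1 - d / dmax)
  mean(term)
}

#' Mean average precision over triplet groups
#'
#' Each group has one source, three candidate targets and a single
#' correct target. Targets are ranked by cosine similarity to the
#' source (ties broken toward the smaller target index); with one
#' correct answer the group's average precision is `1/rank`, and MAP is
#' the mean over groups. Supply either a model (targets are encoded) or
#' precomputed `ranks` of the correct targets.
#'
#' @param groups data.frame from [readGoldTriplets()] (columns
#'   `group_id`, `source`, `target_1..3`, `label` with 1-based labels).
#' @param model A [TextEncoder-class], or `NULL` when `ranks` is given.
#' @param ranks Optional integer vector: rank of the correct target per
#'   group.
#' @param batchSize Encoding batch size.
#' @return MAP in \[0, 1\].
#' @export
mapTriplets <- function(groups, model = NULL, ranks = NULL, batchSize = 10L) {
  if (is.null(ranks)) {
    if (!nrow(groups)) stop("no triplet groups supplied", call. = FALSE)
    need <- c("source", "target_1", "target_2", "target_3", "label")
    if (!all(need %in% names(groups)))
      stop("groups must carry source, target_1..3 and label columns",
           call. = FALSE)
    texts <- c(groups$source, groups$target_1, groups$target_2, groups$target_3)
    e <- encodeCorpus(texts, model, batchSize)
    n <- nrow(groups)
    src <- e[seq_len(n), , drop = FALSE]
    ranks <- vapply(seq_len(n), function(i) {
      tg <- e[n * (1:3) + i, , drop = FALSE]
      s <- as.numeric(cosineSimilarityMatrix(src[i, , drop = FALSE], tg))
      ord <- order(-s, seq_along(s))  # ties -> smaller target index first
      which(ord == groups$label[i])
    }, integer(1))
  }
  if (any(ranks < 1L)) stop("ranks must be positive", call. = FALSE)
  mean(1 / ranks)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via
#' `stats::cor(method = "spearman")`. Constant input has no defined
#' rank correlation and raises an error.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector",
         call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Rating distribution of a set of rated alignments
#'
#' Tallies the 0-5 ratings; zero counts are reported explicitly.
#'
#' @param alignments data.frame with an integer `rating` column.
#' @return Named integer vector of counts, names `"0"` through `"5"`.
#' @export
ratingDistribution <- function(alignments) {
  r <- alignments$rating
  if (length(r) && (any(r < 0L) || any(r > 5L) || any(r != round(r))))
    stop("ratings must be integers in 0..5", call. = FALSE)
  table(factor(r, levels = 0:5)) |> as.integer() |>
    stats::setNames(as.character(0:5))
}
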