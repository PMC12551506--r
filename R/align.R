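#' Cosine-similarity matrix between two embedding matrices
#'
#' `s[i,j] = <a_i, b_j> / (||a_i|| ||b_j||)`. Computed in one dense pass
#' (the naive O(n^2) formulation): no approximate nearest-neighbour
#' index, so the result is exact and oracle-testable.
#'
#' @param a,b Numeric matrices (or [EmbeddingMatrix-class]) with equal
#'   column dimension and no all-zero rows.
#' @return Numeric matrix `nrow(a) x nrow(b)` with entries in \[-1, 1\].
#' @export
cosineSimilarityMatrix <- function(a, b) {
  a <- unclass(as(a, "matrix")); b <- unclass(as(b, "matrix"))
  if (ncol(a) != ncol(b)) stop("embedding dimensions differ", call. = FALSE)
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  if (any(na == 0))
    stop("zero-norm embedding row ", which(na == 0)[1L],
         " in first matrix: cosine undefined", call. = FALSE)
  if (any(nb == 0))
    stop("zero-norm embedding row ", which(nb == 0)[1L],
         " in second matrix: cosine undefined", call. = FALSE)
  tcrossprod(a / na, b / nb)
}

#' Argmax alignment of a similarity matrix
#'
#' For every source row i, selects the target `j* = argmax_j s[i,j]`,
#' breaking ties toward the smallest target index (deterministic and
#' order-stable). Equivalent to the exhaustive row scan.
#'
#' @param s Similarity matrix (sources in rows).
#' @return data.frame with columns `source_index`, `target_index`
#'   (both 1-based) and `score`.
#' @export
alignArgmax <- function(s) {
  s <- as.matrix(s)
  if (!length(s)) stop("similarity matrix is empty", call. = FALSE)
  j <- apply(s, 1L, which.max)  # which.max returns the first maximum
  data.frame(source_index = seq_len(nrow(s)), target_index = as.integer(j),
             score = s[cbind(seq_len(nrow(s)), j)])
}

#' Align a lexicon against an ontology string table
#'
#' Encodes the lexicon `concat_text` column and the ontology `str_text`
#' column with the same model, builds the cosine-similarity matrix, and
#' returns the argmax alignment of every lexicon entry, annotated with
#' the matched CUI and surface string. Deterministic given the model
#' seed and the inputs.
#'
#' @param lexicon data.frame from [readLexicon()].
#' @param ontology data.frame from [readRRF()].
#' @param model A [TextEncoder-class].
#' @param batchSize Encoding batch size (default 10).
#' @return data.frame with columns `source_index`, `term`,
#'   `target_index`, `cui`, `str_text`, `score`.
#' @export
alignCorpora <- function(lexicon, ontology, model, batchSize = 10L) {
  if (!nrow(lexicon) || !nrow(ontology))
    stop("both corpora must be non-empty", call. = FALSE)
  eL <- encodeCorpus(lexicon$concat_text, model, batchSize, provenance = "LEX")
  eM <- encodeCorpus(ontology$str_text, model, batchSize, provenance = "ONTO")
  s <- cosineSimilarityMatrix(eL, eM)
  res <- alignArgmax(s)
  data.frame(source_index = res$source_index,
             term = lexicon$term,
             target_index = res$target_index,
             cui = ontology$cui[res$target_index],
             str_text = ontology$str_text[res$target_index],
             score = res$score,
             stringsAsFactors = FALSE)
}
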