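# Seeded synthetic-corpus generation. Every generator draws all
# randomness from a single seeded generator scoped to the call (the
# global RNG state is untouched) and writes plain-text files in the
# exact dialects the readers consume, so outputs are byte-identical
# per seed.

#' Synthetic-corpus configuration
#'
#' Each concept owns four unique base tokens; the lexicon side emits a
#' term (tokens 1-2) plus explanation (tokens 3-4) and the ontology side
#' emits the full base sequence plus a variant affix token, so matched
#' texts share all concept tokens in the same order while distinct
#' concepts share none. Each token is independently replaced by a token
#' from a disjoint noise pool with probability `noiseRate`, which makes
#' alignment difficulty increase monotonically with the noise rate.
#'
#' @param nConcepts Number of concepts (>= 2).
#' @param synonymsPerSide Entries per concept on each side (default 1:
#'   one lexicon row and one ontology string per concept, keeping top-1
#'   accuracy against ground truth well-defined).
#' @param noiseRate Per-token replacement probability in \[0, 1\].
#' @param poolSize Size of the disjoint noise-token pool.
#' @param seed Integer seed.
#' @return A list of class `SynthConfig`.
#' @export
synthConfig <- function(nConcepts = 50L, synonymsPerSide = 1L,
                        noiseRate = 0.1, poolSize = 200L, seed = 1L) {
  if (nConcepts < 2L) stop("nConcepts must be >= 2", call. = FALSE)
  if (noiseRate < 0 || noiseRate > 1)
    stop("noiseRate must lie in [0, 1]", call. = FALSE)
  structure(list(nConcepts = as.integer(nConcepts),
                 synonymsPerSide = as.integer(synonymsPerSide),
                 noiseRate = noiseRate, poolSize = as.integer(poolSize),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate an aligned lexicon/ontology corpus pair with ground truth
#'
#' Writes `lexicon.tsv` (term, explanation) and `ontology.rrf`
#' (MRCONSO-style 18-column RRF, one synthetic CUI per concept, language
#' `ENG`) under `dir`, and returns the parsed tables plus the
#' ground-truth map from every lexicon row to its concept's CUI.
#' Fully deterministic per seed.
#'
#' @param cfg A [synthConfig()].
#' @param dir Output directory (created if needed).
#' @return List with `lexicon`, `ontology` (parsed data.frames), `truth`
#'   (data.frame `lex_row`, `cui`), and the two file `paths`.
#' @export
genAlignedCorpora <- function(cfg = synthConfig(), dir = tempfile("synth")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- sprintf("zz%03d", seq_len(cfg$poolSize))
  noisy <- function(toks) {
    hit <- stats::runif(length(toks)) < cfg$noiseRate
    toks[hit] <- sample(pool, sum(hit), replace = TRUE)
    toks
  }
  lex <- list(); onto <- list(); truth <- list()
  withr::with_seed(cfg$seed, {
    for (k in seq_len(cfg$nConcepts)) {
      base <- sprintf("c%da%d", k, 1:4)
      cui <- sprintf("C%07d", k)
      for (v in seq_len(cfg$synonymsPerSide)) {
        lex[[length(lex) + 1L]] <- data.frame(
          term = paste(noisy(base[1:2]), collapse = " "),
          explanation = paste(noisy(base[3:4]), collapse = " "),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- cui
        onto[[length(onto) + 1L]] <- data.frame(
          cui = cui,
          str_text = paste(c(noisy(base), sprintf("v%dx%d", k, v)),
                           collapse = " "),
          stringsAsFactors = FALSE)
      }
    }
  })
  lexDf <- do.call(rbind, lex)
  ontoDf <- do.call(rbind, onto)
  lexPath <- file.path(dir, "lexicon.tsv")
  ontoPath <- file.path(dir, "ontology.rrf")
  utils::write.table(lexDf, lexPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  spec <- columnSpec()
  full <- data.frame(cui = ontoDf$cui, lat = "ENG", str_text = ontoDf$str_text,
                     stringsAsFactors = FALSE)
  for (j in seq_len(spec$nColumns - 3L)) full[[paste0("extra", j)]] <- ""
  attr(full, "spec") <- spec
  writeRRF(full, ontoPath)
  list(lexicon = readLexicon(lexPath),
       ontology = readRRF(ontoPath),
       truth = data.frame(lex_row = seq_len(nrow(lexDf)),
                          cui = unlist(truth), stringsAsFactors = FALSE),
       paths = c(lexicon = lexPath, ontology = ontoPath))
}

#' Generate scored sentence pairs (semantic-similarity gold data)
#'
#' Per pair, an overlap fraction `rho` is drawn uniformly; the two
#' sentences share the first `ceiling(rho * len)` tokens (same order and
#' positions) and differ elsewhere, and the gold mark is `round(5 *
#' rho)` on the six-point scale. By construction the token-overlap
#' signal is monotone in the mark.
#'
#' @param nPairs Number of pairs (>= 1).
#' @param seed Integer seed.
#' @param path Output TSV path (`id`, `source`, `target`, `mark`); or
#'   `NULL` to skip writing.
#' @param len Tokens per sentence (default 8).
#' @return data.frame of the generated pairs (invisibly also written).
#' @export
genSimilarityPairs <- function(nPairs, seed = 1L, path = NULL, len = 8L) {
  if (nPairs < 1L) stop("nPairs must be >= 1", call. = FALSE)
  vocab <- sprintf("w%03d", 1:500)
  rows <- withr::with_seed(seed, {
    lapply(seq_len(nPairs), function(i) {
      rho <- stats::runif(1)
      shared <- ceiling(rho * len)
      a <- sample(vocab, len)
      rest <- sample(setdiff(vocab, a), len - shared)
      b <- c(a[seq_len(shared)], rest)
      data.frame(id = i, source = paste(a, collapse = " "),
                 target = paste(b, collapse = " "),
                 mark = round(5 * rho), stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  df
}

#' Generate triplet groups (parallel-sentence identification gold data)
#'
#' Each group's source draws eight tokens from a group-specific set; the
#' correct target is the source with each token independently dropped
#' with probability `dropout` (at least one token survives), and the two
#' distractors are other groups' sources, so they share no tokens with
#' the source. The correct target's position among the three candidates
#' is randomized.
#'
#' @param nGroups Number of groups (>= 2).
#' @param dropout Per-token drop probability in \[0, 1).
#' @param seed Integer seed.
#' @param path Output TSV path (`id`, `num`, `source`, `target`,
#'   `label`; three rows per group, `label` = 1-based index of the
#'   correct target); or `NULL` to skip writing.
#' @return Grouped data.frame as from [readGoldTriplets()].
#' @export
genTriplets <- function(nGroups, dropout = 0.2, seed = 1L, path = NULL) {
  if (nGroups < 2L) stop("nGroups must be >= 2 (distractors come from other groups)",
                         call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  out <- withr::with_seed(seed, {
    sources <- vapply(seq_len(nGroups), function(i)
      paste(sprintf("g%dt%d", i, 1:8), collapse = " "), character(1))
    lapply(seq_len(nGroups), function(i) {
      toks <- strsplit(sources[i], " ", fixed = TRUE)[[1L]]
      keep <- stats::runif(length(toks)) >= dropout
      if (!any(keep)) keep[1L] <- TRUE
      correct <- paste(toks[keep], collapse = " ")
      others <- sample(setdiff(seq_len(nGroups), i), 2L)
      label <- sample(1:3, 1L)
      targets <- character(3)
      targets[label] <- correct
      targets[setdiff(1:3, label)] <- sources[others]
      data.frame(group_id = i, source = sources[i],
                 target_1 = targets[1L], target_2 = targets[2L],
                 target_3 = targets[3L], label = label,
                 stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, out)
  if (!is.null(path)) {
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      data.frame(id = (i - 1L) * 3L + 1:3, num = df$group_id[i],
                 source = df$source[i],
                 target = c(df$target_1[i], df$target_2[i], df$target_3[i]),
                 label = df$label[i], stringsAsFactors = FALSE)
    }))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  df
}
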