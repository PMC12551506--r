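#' Column layout of an RRF ontology string table
#'
#' The RRF dialect is pipe-delimited with a trailing delimiter and no
#' quoting or escaping. The defaults follow the standard MRCONSO layout
#' (18 columns; CUI in column 1, language in column 2, string in column
#' 15) but every index is configurable.
#'
#' @param delimiter Single delimiter character.
#' @param trailingDelimiter Does every line end with the delimiter?
#' @param indexCui,indexLat,indexStr 1-based column indices of the
#'   concept identifier, language code and surface string.
#' @param nColumns Expected number of columns per line.
#' @return A list of class `ColumnSpec`.
#' @export
columnSpec <- function(delimiter = "|", trailingDelimiter = TRUE,
                       indexCui = 1L, indexLat = 2L, indexStr = 15L,
                       nColumns = 18L) {
  idx <- c(indexCui, indexLat, indexStr)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > nColumns))
    stop("column indices must be distinct and within 1..nColumns", call. = FALSE)
  if (nchar(delimiter) != 1L)
    stop("delimiter must be a single character", call. = FALSE)
  structure(list(delimiter = delimiter, trailingDelimiter = trailingDelimiter,
                 indexCui = as.integer(indexCui), indexLat = as.integer(indexLat),
                 indexStr = as.integer(indexStr), nColumns = as.integer(nColumns)),
            class = "ColumnSpec")
}

#' Read an ontology string table in the RRF dialect
#'
#' Each line splits into `spec$nColumns` fields; the trailing delimiter
#' produces one final empty piece which is dropped. Returns a data.frame
#' with one row per record in file order: `cui`, `lat`, `str_text`, then
#' the remaining columns in original order as `extra1`, `extra2`, ...
#' The `ColumnSpec` is attached as attribute `"spec"` so the table can be
#' written back verbatim with [writeRRF()].
#'
#' @param path Path to the RRF file (UTF-8).
#' @param spec A [columnSpec()].
#' @param langFilter Optional language code; keep only matching records.
#' @return data.frame with columns `cui`, `lat`, `str_text`, `extra*`.
#' @export
readRRF <- function(path, spec = columnSpec(), langFilter = NULL) {
  if (!file.exists(path)) stop("cannot read RRF file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- .emptyOntologyTable(spec)
    return(out)
  }
  pieces <- strsplit(lines, spec$delimiter, fixed = TRUE)
  want <- spec$nColumns
  fields <- lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    # strsplit already drops the single empty piece after a trailing
    # delimiter; interior empty fields are preserved
    if (spec$trailingDelimiter && length(p) == want + 1L && p[want + 1L] == "")
      p <- p[seq_len(want)]
    if (length(p) != want)
      stop(sprintf("malformed RRF line %d: %d fields, expected %d",
                   lineNo[i], length(p), want), call. = FALSE)
    p
  })
  m <- do.call(rbind, fields)
  cui <- m[, spec$indexCui]
  lat <- m[, spec$indexLat]
  str_text <- m[, spec$indexStr]
  if (any(!nzchar(cui)))
    stop("RRF record with empty CUI at line ", lineNo[which(!nzchar(cui))[1L]],
         call. = FALSE)
  rest <- m[, -c(spec$indexCui, spec$indexLat, spec$indexStr), drop = FALSE]
  colnames(rest) <- paste0("extra", seq_len(ncol(rest)))
  out <- data.frame(cui = cui, lat = lat, str_text = str_text,
                    rest, stringsAsFactors = FALSE)
  if (!is.null(langFilter)) out <- out[out$lat == langFilter, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

.emptyOntologyTable <- function(spec) {
  rest <- matrix(character(0), 0L, spec$nColumns - 3L)
  colnames(rest) <- paste0("extra", seq_len(ncol(rest)))
  out <- data.frame(cui = character(0), lat = character(0),
                    str_text = character(0), rest, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Write an ontology table back to the RRF dialect
#'
#' Reassembles the original column order from the `ColumnSpec` so that
#' `writeRRF(readRRF(p))` round-trips well-formed files byte-for-byte.
#'
#' @param records data.frame from [readRRF()] (or with the same columns).
#' @param path Output path.
#' @param spec A [columnSpec()]; defaults to the one attached to `records`.
#' @export
writeRRF <- function(records, path, spec = attr(records, "spec")) {
  if (is.null(spec)) spec <- columnSpec()
  m <- matrix("", nrow(records), spec$nColumns)
  m[, spec$indexCui] <- records$cui
  m[, spec$indexLat] <- records$lat
  m[, spec$indexStr] <- records$str_text
  restIdx <- setdiff(seq_len(spec$nColumns),
                     c(spec$indexCui, spec$indexLat, spec$indexStr))
  for (k in seq_along(restIdx))
    m[, restIdx[k]] <- records[[paste0("extra", k)]]
  lines <- apply(m, 1L, paste, collapse = spec$delimiter)
  if (spec$trailingDelimiter && length(lines))
    lines <- paste0(lines, spec$delimiter)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a layman lexicon TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row containing at
#' least `term` and `explanation` columns and optionally an integer
#' `rating` column on the six-point 0-5 scale. The working text of each
#' entry is the concatenation of term and explanation.
#'
#' @param path Path to the TSV.
#' @param hasRating Is a `rating` column required?
#' @param sep Separator used to join term and explanation (default one
#'   space).
#' @return data.frame with columns `term`, `explanation`, `concat_text`
#'   and, when present, `rating`.
#' @export
readLexicon <- function(path, hasRating = FALSE, sep = " ") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  need <- c("term", "explanation")
  if (hasRating) need <- c(need, "rating")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("lexicon file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(term = as.character(df$term),
                    explanation = as.character(df$explanation),
                    stringsAsFactors = FALSE)
  out$concat_text <- paste(out$term, out$explanation, sep = sep)
  if ("rating" %in% names(df)) {
    r <- suppressWarnings(as.integer(df$rating))
    if (any(is.na(r)) || any(r < 0L | r > 5L))
      stop("lexicon ratings must be integers in 0..5", call. = FALSE)
    out$rating <- r
  }
  out
}

#' Normalize free text
#'
#' Lowercases, replaces every non-alphanumeric character by a space (so
#' hyphenated compounds split into tokens rather than merging), collapses
#' whitespace runs, strips leading/trailing space, and removes stopword
#' tokens. Idempotent.
#'
#' @param text Character vector.
#' @param stopwords Character vector of tokens to drop (may be empty).
#' @return Character vector of normalized text.
#' @export
normalizeText <- function(text, stopwords = character(0)) {
  t <- tolower(text)
  t <- gsub("[^a-z0-9]+", " ", t)
  t <- trimws(gsub(" +", " ", t))
  if (length(stopwords)) {
    t <- vapply(t, function(s) {
      toks <- strsplit(s, " ", fixed = TRUE)[[1L]]
      paste(toks[!toks %in% stopwords], collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  t
}

#' Left join two record tables on the concept identifier
#'
#' Standard left-join semantics with primary row order preserved: a
#' primary row with k >= 1 matches in `aux` yields k output rows; a row
#' with no match yields one row with `NA`-marked aux fields.
#'
#' @param primary,aux data.frames each carrying a `cui` column.
#' @return data.frame; aux columns (other than `cui`) are suffixed
#'   `.aux` when their names clash with primary columns.
#' @export
leftJoinCui <- function(primary, aux) {
  stopifnot("cui" %in% names(primary), "cui" %in% names(aux))
  auxCols <- setdiff(names(aux), "cui")
  outName <- ifelse(auxCols %in% names(primary), paste0(auxCols, ".aux"), auxCols)
  matches <- lapply(primary$cui, function(k) which(aux$cui == k))
  reps <- vapply(matches, function(ix) max(1L, length(ix)), integer(1))
  out <- primary[rep(seq_len(nrow(primary)), reps), , drop = FALSE]
  auxIdx <- unlist(lapply(matches, function(ix) if (length(ix)) ix else NA_integer_))
  for (k in seq_along(auxCols))
    out[[outName[k]]] <- aux[[auxCols[k]]][auxIdx]
  rownames(out) <- NULL
  out
}

#' Read a gold similarity-pair file
#'
#' TSV with header `id`, `source`, `target`, `mark`; marks are
#' human-assigned 0-5 similarity scores.
#'
#' @param path Path to the TSV.
#' @return data.frame with those columns, `mark` numeric.
#' @export
readGoldPairs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "source", "target", "mark")
  if (!all(need %in% names(df)))
    stop("gold pair file must have columns id, source, target, mark", call. = FALSE)
  df$mark <- as.numeric(df$mark)
  df
}

#' Read a gold triplet file
#'
#' TSV with header `id`, `num`, `source`, `target`, `label`: three rows
#' per group identifier `num`, each holding one candidate target; `label`
#' is the 1-based index (within the group) of the correct target,
#' constant across the group's rows. Returns one row per group.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `group_id`, `source`, `target_1`,
#'   `target_2`, `target_3`, `label`.
#' @export
readGoldTriplets <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "num", "source", "target", "label")
  if (!all(need %in% names(df)))
    stop("gold triplet file must have columns id, num, source, target, label",
         call. = FALSE)
  groups <- split(df, factor(df$num, levels = unique(df$num)))
  rows <- lapply(groups, function(g) {
    if (nrow(g) != 3L)
      stop("triplet group ", g$num[1L], " has ", nrow(g),
           " targets; exactly 3 required", call. = FALSE)
    lab <- unique(as.integer(g$label))
    if (length(lab) != 1L || !lab %in% 1:3)
      stop("triplet group ", g$num[1L], " has an invalid label", call. = FALSE)
    data.frame(group_id = g$num[1L], source = g$source[1L],
               target_1 = g$target[1L], target_2 = g$target[2L],
               target_3 = g$target[3L], label = lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognizes the sections `input_model`, `data_config`, `evaluation`
#' and `search_strategy`; missing sections come back as empty lists.
#'
#' @param path Path ending in `.yaml`, `.yml` or `.json`.
#' @return Named list with the four sections.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sections <- c("input_model", "data_config", "evaluation", "search_strategy")
  out <- stats::setNames(lapply(sections, function(s) {
    v <- cfg[[s]]
    if (is.null(v)) list() else v
  }), sections)
  out
}
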