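# Internal helpers: stable string hashing and small validators.

# 32-bit unsigned xor on doubles in [0, 2^32).
.xor32 <- function(a, b) {
  bitwXor(a %% 65536L, b %% 65536L) +
    bitwXor(a %/% 65536L, b %/% 65536L) * 65536
}

# (a * b) mod 2^32 without double-precision overflow (b < 2^25).
.mul32 <- function(a, b) {
  lo <- (a %% 65536) * b
  hi <- ((a %/% 65536) * b) %% 65536
  (lo + hi * 65536) %% 4294967296
}

#' Stable 32-bit FNV-1a hash of a string
#'
#' Seed-independent and identical across runs and platforms: the token-id
#' map of the tokenizer must not depend on per-process hash randomization.
#'
#' @param s Character vector.
#' @return Numeric vector of hash values in `[0, 2^32)`.
#' @keywords internal
fnv1a32 <- function(s) {
  vapply(s, function(x) {
    h <- 2166136261
    for (b in as.integer(charToRaw(x))) {
      h <- .xor32(h, b)
      h <- .mul32(h, 16777619)
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.assertFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

.asMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

.relErr <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(b))
  if (s == 0) d else d / s
}
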