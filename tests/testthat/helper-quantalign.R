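# Shared helpers: a small fast encoder config for contract tests and a
# builder for rated-alignment tables.

testCfg <- function(seed = 1L, maxLen = 12L, ...) {
  encoderConfig(vocabSize = 512L, embedDim = 32L, hiddenDim = 48L,
                nLayers = 2L, maxLen = maxLen, seed = seed, ...)
}

# Study-scale encoder: package defaults at short sequence length, the
# configuration used for end-to-end experiments.
studyCfg <- function(seed = 1L) encoderConfig(maxLen = 16L, seed = seed)

ratedSet <- function(keys, targets, ratings, tag = "m") {
  data.frame(source_key = keys, target_key = targets,
             score = ratings / 5, rating = as.integer(ratings),
             model_tag = tag, stringsAsFactors = FALSE)
}

randomRatedPair <- function(seed) {
  withr::with_seed(seed, {
    nA <- sample(3:10, 1); nB <- sample(3:10, 1)
    keys <- paste0("t", 1:12)
    a <- ratedSet(sample(keys, nA), paste0("C", 1:nA), sample(0:5, nA, TRUE), "A")
    b <- ratedSet(sample(keys, nB), paste0("C", 1:nB), sample(0:5, nB, TRUE), "B")
    list(a = a, b = b)
  })
}
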