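test_that("min-max rescaling maps the observed range onto the target scale", {
  expect_equal(minmaxRescale(c(0.2, 0.6, 1.0)), c(0, 2.5, 5))
  expect_equal(minmaxRescale(c(0.9, 0.9)), c(0, 0))  # constant -> lo
  expect_equal(minmaxRescale(c(0, 5)), c(0, 5))      # identity on the bounds
  expect_error(minmaxRescale(numeric(0)), "empty")
  expect_error(minmaxRescale(c(1, 2), lo = 1, hi = 1), "exceed")

  # monotone, and idempotent once the data spans [lo, hi]
  withr::with_seed(31, {
    x <- stats::runif(20)
    y <- minmaxRescale(x)
    expect_identical(order(x), order(y))
    expect_equal(minmaxRescale(y), y)
  })
})

test_that("complementarity merge follows the descending-rating admission order", {
  a <- ratedSet(c("t1", "t2", "t3"), c("CA1", "CA2", "CA3"), c(5, 4, 3), "A")
  b <- ratedSet(c("t1", "t2", "t4"), c("CB1", "CB2", "CB4"), c(4, 5, 5), "B")
  m <- complementarityMerge(a, b)
  expect_setequal(m$source_key, c("t1", "t2", "t3", "t4"))
  got <- m[match(c("t1", "t2", "t3", "t4"), m$source_key), ]
  expect_equal(got$model_tag, c("A", "B", "A", "B"))
  expect_equal(got$rating, c(5L, 5L, 3L, 5L))
  # primary rating-5 alignments retained verbatim
  expect_equal(got$target_key[1], "CA1")
  # admission order: all rating-5 rows precede the rating-3 row
  expect_equal(m$rating, sort(m$rating, decreasing = TRUE))
})

test_that("merge edge cases: neutral element, duplicates, rating filter", {
  a <- ratedSet(c("x", "y"), c("C1", "C2"), c(2, 5), "A")
  empty <- a[0, ]
  expect_equal(complementarityMerge(a, empty)[order(match(
    complementarityMerge(a, empty)$source_key, a$source_key)), ]$target_key,
    a$target_key)

  dup <- ratedSet(c("x", "x"), c("C1", "C3"), c(1, 2), "A")
  expect_error(complementarityMerge(dup, empty), "duplicate source_key")
  expect_error(complementarityMerge(a, ratedSet("q", "C9", 9)), "0..5")

  m <- complementarityMerge(a, empty, minRating = 3L)
  expect_equal(m$source_key, "y")
})

test_that("merged coverage equals the union of source keys on random inputs", {
  for (sd in 1:15) {
    p <- randomRatedPair(sd)
    m <- complementarityMerge(p$a, p$b)
    expect_setequal(m$source_key, union(p$a$source_key, p$b$source_key))
    expect_equal(anyDuplicated(m$source_key), 0L)
    # every source appears at the highest rating either model offers it
    for (k in m$source_key) {
      offered <- c(p$a$rating[p$a$source_key == k], p$b$rating[p$b$source_key == k])
      expect_equal(m$rating[m$source_key == k], max(offered))
    }
  }
})

test_that("the Pareto frontier keeps exactly the non-dominated points", {
  pts <- data.frame(quality = c(0.9, 0.8, 0.85), cost = c(10, 5, 12))
  f <- paretoFrontier(pts)
  expect_equal(attr(f, "indices"), c(1L, 2L))  # (0.85, 12) dominated by (0.9, 10)

  one <- data.frame(quality = 0.5, cost = 3)
  expect_equal(nrow(paretoFrontier(one)), 1L)

  dup <- data.frame(quality = c(0.7, 0.7), cost = c(4, 4))
  expect_equal(nrow(paretoFrontier(dup)), 2L)  # ties are not strict domination

  expect_error(paretoFrontier(pts[0, ]), "empty")
})

test_that("the frontier equals the pairwise-dominance oracle on random instances", {
  dominanceOracle <- function(pts) {
    n <- nrow(pts)
    keep <- logical(n)
    for (i in seq_len(n)) {
      dominated <- FALSE
      for (j in seq_len(n)) {
        if (pts$quality[j] >= pts$quality[i] && pts$cost[j] <= pts$cost[i] &&
            (pts$quality[j] > pts$quality[i] || pts$cost[j] < pts$cost[i]))
          dominated <- TRUE
      }
      keep[i] <- !dominated
    }
    which(keep)
  }
  withr::with_seed(33, {
    for (i in 1:30) {
      pts <- data.frame(quality = round(stats::runif(12), 2),
                        cost = round(stats::runif(12, 1, 20), 1))
      expect_identical(attr(paretoFrontier(pts), "indices"), dominanceOracle(pts))
    }
  })
})

test_that("the exhaustive config search evaluates, filters and ranks candidates", {
  fx <- genAlignedCorpora(synthConfig(nConcepts = 12, noiseRate = 0.1, seed = 2))
  enc <- newTextEncoder(studyCfg())
  cands <- list(quantCandidate("per_channel", alpha = 0.5),
                quantCandidate("per_tensor", alpha = NULL))
  rep <- searchQuantConfigs(cands, enc, fx$lexicon, fx$ontology)
  expect_equal(nrow(rep$points), 2L)
  expect_gte(rep$points$quality[1], rep$points$quality[2])
  expect_true(all(rep$points$cost <= 0.30 * rep$fp32_bytes))
  expect_true(all(rep$points$quality >= 0 & rep$points$quality <= 1))

  # vacuous constraints admit every candidate
  rep2 <- searchQuantConfigs(cands, enc, fx$lexicon, fx$ontology,
                             quantConstraints(maxDegradation = 1, minCostReduction = 0))
  expect_true(all(rep2$points$feasible))
  expect_false(is.na(rep2$best))
  # best is the highest-quality feasible frontier point
  expect_equal(rep2$points$quality[rep2$best], max(rep2$points$quality[rep2$points$feasible]))

  # an empty feasible set is reported, not thrown
  rep3 <- searchQuantConfigs(cands, enc, fx$lexicon, fx$ontology,
                             quantConstraints(maxDegradation = 0, minCostReduction = 1))
  expect_true(all(!rep3$points$feasible))  # no payload can shrink by 100%
  expect_true(is.na(rep3$best))
  expect_true(length(rep3$frontier) >= 1L)

  expect_error(searchQuantConfigs(list(), enc, fx$lexicon, fx$ontology), "empty")
})
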