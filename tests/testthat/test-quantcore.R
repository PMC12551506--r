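test_that("per-tensor quantization matches hand-computed grids and scales", {
  qt <- quantize(c(1.0, -0.5, 0.25))
  expect_equal(as.numeric(quantGrid(qt)), c(127, -64, 32))  # half-even: -63.5 -> -64
  expect_equal(quantScales(qt), 1 / 127)

  z <- quantize(rep(0, 4))
  expect_true(all(quantGrid(z) == 0))
  expect_gt(quantScales(z), 0)

  W <- cbind(c(1, -2), c(0.1, 0.05))
  qw <- quantize(W, perChannel(2L))
  expect_equal(quantScales(qw), c(2 / 127, 0.1 / 127))

  expect_error(quantize(c(1, NA)), "non-finite")
  expect_error(quantize(c(1, Inf)), "non-finite")
})

test_that("dequantization inverts the grid up to half a step", {
  qt <- quantize(c(1.0, -0.5, 0.25))
  expect_equal(dequantize(qt), c(127, -64, 32) / 127)
  x <- c(1.0, -0.5, 0.25)
  expect_true(all(abs(x - dequantize(quantize(x))) <= (1 / 127) / 2 + 1e-12))
  expect_equal(dequantize(quantize(rep(0, 3))), rep(0, 3))
})

test_that("round-trip error is bounded by half the scale on seeded tensors", {
  withr::with_seed(11, {
    for (i in 1:100) {
      x <- matrix(stats::rnorm(60, sd = runif(1, 0.1, 10)), 6, 10)
      for (scheme in list(perTensor(), perChannel(1L), perChannel(2L))) {
        qt <- quantize(x, scheme)
        s <- quantScales(qt)
        bound <- if (scheme@granularity == "per_tensor") s / 2 else {
          if (scheme@axis == 1L) matrix(s / 2, 6, 10) else
            matrix(s / 2, 6, 10, byrow = TRUE)
        }
        expect_true(all(abs(x - dequantize(qt)) <= bound + 1e-12))
      }
    }
  })
})

test_that("per-channel weight quantization never loses to per-tensor in Frobenius error", {
  withr::with_seed(12, {
    for (i in 1:100) {
      # heterogeneous column ranges, the regime per-channel scales exist for
      W <- matrix(stats::rnorm(48), 8, 6) %*% diag(10^runif(6, -2, 1))
      ePC <- norm(W - dequantize(quantize(W, perChannel(2L))), "F")
      ePT <- norm(W - dequantize(quantize(W, perTensor())), "F")
      expect_lte(ePC, ePT + 1e-12)
    }
  })
})

test_that("quantized matmul accumulates integers exactly", {
  # hand-walked 1x2 by 2x1 case
  xq <- quantize(matrix(c(1, -1), 1, 2))
  Wq <- quantize(matrix(c(1, -2), 2, 1), perChannel(2L))
  yInt <- 127 * 64 + (-127) * (-127)
  expect_equal(as.numeric(qlinearMatmul(xq, Wq)), yInt * (1 / 127) * (2 / 127))
  # equals the product of the dequantized operands
  expect_equal(as.numeric(qlinearMatmul(xq, Wq)),
               as.numeric(dequantize(xq) %*% dequantize(Wq)))

  # zero activations give zero output
  z <- quantize(matrix(0, 2, 3))
  Wq2 <- quantize(matrix(stats::rnorm(12), 3, 4), perChannel(2L))
  expect_true(all(qlinearMatmul(z, Wq2) == 0))

  # random instances agree with the dequantized-operand product to 1e-9
  withr::with_seed(13, {
    for (i in 1:20) {
      X <- matrix(stats::rnorm(40), 5, 8)
      W <- matrix(stats::rnorm(48), 8, 6)
      y <- qlinearMatmul(quantize(X), quantize(W, perChannel(2L)))
      ref <- dequantize(quantize(X)) %*% dequantize(quantize(W, perChannel(2L)))
      expect_lt(max(abs(y - ref)) / max(abs(ref)), 1e-9)
    }
  })
})

test_that("per-channel activations are rejected as non-dequantizable", {
  X <- matrix(stats::rnorm(6), 2, 3)
  W <- matrix(stats::rnorm(12), 3, 4)
  expect_error(qlinearMatmul(quantize(X, perChannel(2L)), quantize(W, perChannel(2L))),
               "non-dequantizable scheme combination")
  expect_error(qlinearMatmul(quantize(X), quantize(W, perChannel(1L))),
               "non-dequantizable scheme combination")
  expect_error(qlinearMatmul(quantize(X), quantize(matrix(1, 5, 2), perChannel(2L))),
               "inner dimensions")
})

test_that("quantized elementwise ops follow dequantize-then-apply semantics", {
  expect_equal(qlinearElementwise(c(-1, 2), op = "relu"), c(0, 2))

  x <- c(0.8, -0.3, 0.1)
  qx <- quantize(x)
  qn <- quantize(-x)
  # x + (-x) through the quantized grids stays within one quantization step
  expect_true(all(abs(qlinearElementwise(qx, qn, "add")) <= quantScales(qx) + 1e-12))
  # additive identity preserves the dequantized value
  expect_equal(qlinearElementwise(qx, rep(0, 3), "add"), dequantize(qx))

  expect_error(qlinearElementwise(matrix(1, 2, 2), matrix(1, 3, 3), "add"),
               "shape mismatch")
})

test_that("activation statistics are columnwise maxima and permutation-invariant", {
  enc <- newTextEncoder(testCfg())
  texts <- c("alpha beta", "gamma delta epsilon", "zeta", "eta theta")
  st <- collectActivationStats(enc, texts)
  expect_length(st, 2L)
  expect_length(st[[1]]@maxabs, 32L)  # layer-1 input channels = embedDim
  expect_length(st[[2]]@maxabs, 48L)  # layer-2 input channels = hiddenDim
  expect_true(all(st[[1]]@maxabs >= 0))

  # direct oracle for layer 1: stack (embedding + positional) rows
  b <- tokenizeBatch(texts, testCfg())
  pos <- quantalign:::.posSignal(12L, 32L)
  rows <- do.call(rbind, lapply(seq_len(nrow(b@ids)), function(i)
    enc@embedding[b@ids[i, ] + 1L, , drop = FALSE] + pos))
  expect_equal(st[[1]]@maxabs, apply(abs(rows), 2, max))

  st2 <- collectActivationStats(enc, rev(texts))
  expect_equal(st[[1]]@maxabs, st2[[1]]@maxabs)
  expect_equal(st[[2]]@variance, st2[[2]]@variance)

  expect_error(collectActivationStats(enc, character(0)), "non-empty")
})

test_that("smoothing scales follow the alpha power-ratio formula", {
  st <- new("ActivationStats", maxabs = 4, variance = 1, nSamples = 10L)
  W <- matrix(c(0.25, -0.1), 1, 2)  # row maxabs 0.25
  expect_equal(computeSmoothingScales(st, W, smoothingConfig(alpha = 0.5)), 4)

  # alpha = 0 puts the whole burden on weight-side normalization
  expect_equal(computeSmoothingScales(st, W, smoothingConfig(alpha = 0)), 1 / 0.25)

  # symmetric ranges give unit scales
  st2 <- new("ActivationStats", maxabs = c(2, 3), variance = c(1, 1), nSamples = 5L)
  W2 <- rbind(c(2, -1), c(0.5, 3))
  expect_equal(computeSmoothingScales(st2, W2, smoothingConfig(alpha = 0.5)), c(1, 1))

  expect_error(computeSmoothingScales(st2, matrix(1, 3, 2)), "channel count")
})

test_that("smoothing rescales the pair without changing the product", {
  X <- matrix(stats::rnorm(20), 4, 5)
  W <- matrix(stats::rnorm(15), 5, 3)
  id <- applySmoothing(X, W, rep(1, 5))
  expect_equal(id$X, X)
  expect_equal(id$W, W)

  # X column max 4, W row max 0.25, s = 4 -> both normalized to 1
  X1 <- matrix(c(4, -2), 2, 1)
  W1 <- matrix(c(0.25, 0.1), 1, 2)
  sm <- applySmoothing(X1, W1, 4)
  expect_equal(max(abs(sm$X)), 1)
  expect_equal(max(abs(sm$W)), 1)

  withr::with_seed(14, {
    for (i in 1:20) {
      X <- matrix(stats::rnorm(30), 5, 6)
      W <- matrix(stats::rnorm(24), 6, 4)
      s <- 10^runif(6, -2, 2)
      sm <- applySmoothing(X, W, s)
      expect_lt(max(abs(sm$X %*% sm$W - X %*% W)) / max(abs(X %*% W)), 1e-6)
    }
  })
  expect_error(applySmoothing(X, W, c(-1, rep(1, 5))), "strictly positive")
})

test_that("smoothing shrinks a constructed 100x outlier channel", {
  withr::with_seed(15, {
    X <- matrix(stats::rnorm(200), 20, 10)
    X[, 4] <- X[, 4] * 100
    W <- matrix(stats::rnorm(80), 10, 8)
  })
  maxabs <- apply(abs(X), 2, max)
  st <- new("ActivationStats", maxabs = maxabs, variance = apply(X, 2, var),
            nSamples = 20L)
  s <- computeSmoothingScales(st, W, smoothingConfig(alpha = 0.5))
  Xs <- applySmoothing(X, W, s)$X
  before <- max(maxabs) / median(maxabs)
  after <- {
    m <- apply(abs(Xs), 2, max)
    max(m) / median(m)
  }
  expect_lt(after, before)
})

test_that("a quantized encoder stays close to FP32 and shrinks its payload", {
  cfg <- testCfg()
  enc <- newTextEncoder(cfg)
  calib <- c("myocardial infarction blocked flow", "influenza viral infection",
             "renal failure kidney disease", "aspirin pain relief")
  qenc <- quantizeEncoder(enc, calib)
  expect_true(isQuantized(qenc))

  b <- tokenizeBatch(calib, cfg)
  e0 <- encodeBatch(b, enc)
  e1 <- encodeBatch(b, qenc)
  cosines <- diag(cosineSimilarityMatrix(e0, e1))
  expect_true(all(cosines >= 0.99))

  expect_lte(payloadBytes(qenc), 0.30 * payloadBytes(enc))
})
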