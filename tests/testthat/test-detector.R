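test_that("flow map multiplies the five features with sign propagation", {
  J <- matrix(1, 3, 3)
  Z <- matrix(0, 3, 3)
  expect_equal(flowMap(J, J, J, J, Z), J)          # all ones off-edge
  expect_equal(flowMap(J, J, J, J, J), Z)          # edges zeroed
  Cf <- J; Cf[2, 2] <- -1
  FM <- flowMap(J, Cf, J, J, Z)
  expect_equal(FM[2, 2], -1)                       # anti-phase stays negative
  expect_error(flowMap(J, J, J, matrix(1, 2, 2), Z), "shape")
})

test_that("flow-map binarization is strictly greater than xi2", {
  FM <- matrix(c(0.2, 0.21, -0.5, 0.9), 2, 2)
  FMb <- binarizeFlowMap(FM)
  expect_equal(FMb, matrix(c(0, 1, 0, 1), 2, 2))
})

test_that("anti-phase pixels pass the correlation gate but are excluded
           from the flow set", {
  N <- 72
  tt <- (0:(N - 1)) / 9
  S <- array(rnorm(5 * 5 * N, sd = 0.05), c(5, 5, N))
  S[2, 2, ] <- sin(2 * pi * 0.8 * tt)
  S[4, 4, ] <- -S[2, 2, ]  # negated copy of the core signal
  C <- correlationMap(S, c(2, 2))
  Cbin <- binarizeCorrelation(C)
  Cf <- covarianceMap(S, prevCore = c(2, 2))
  expect_equal(Cbin[4, 4], 1)
  expect_lt(Cf[4, 4], 0)
  J <- matrix(1, 5, 5)
  FM <- flowMap(Cbin, Cf, J, J, matrix(0, 5, 5))
  expect_lt(FM[4, 4], 0)
  expect_equal(binarizeFlowMap(FM)[4, 4], 0)
})

test_that("window 1 yields the single flow-core-pixel inside the
           annotation box", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 12))
  res <- detectRfPixels(ph$video)
  expect_equal(nrow(res@pflow[[1]]), 1)
  pann <- annotationPixels(ph$annotations, frameDim(ph$video))
  expect_equal(pfMetric(res@pflow[[1]], pann), 100)
})

test_that("the flow set tracks the blob and avoids edges after window 1", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 20))
  v <- interpolateUniform(ph$video, 9)
  res <- analyzeVideo(v, keepMaps = TRUE)
  pann <- annotationPixels(ph$annotations, frameDim(v))
  sc <- aggregateScores(res, pann)
  expect_gte(sc$pf, 80)
  # Pflow never touches the gradient mask for j > 1
  for (j in 2:length(res@pflow)) {
    G <- res@maps[[j]]$features@G
    expect_equal(sum(G[res@pflow[[j]]]), 0)
  }
  # flow-core trajectory stays inside the true flow mask >= 90% of windows
  expect_gte(mean(ph$flowMask[res@coreTrajectory[-1, , drop = FALSE]]), 0.9)
})

test_that("an all-zero flow map triggers the carry-over fallback", {
  # flow suppressed in mid-segment windows: Pflow is carried unchanged
  cfg <- defaultScenes("flow_only", durationS = 24)
  cfg$apneaIntervals <- list(c(10, 19))
  ph <- generatePhantom(cfg)
  res <- detectRfPixels(ph$video)
  expect_gt(sum(res@fallback), 0)
  for (j in which(res@fallback))
    expect_identical(res@pflow[[j]], res@pflow[[j - 1]])
  # windows fully inside the suppression are fallback windows
  full <- which(res@windowStartS >= 10 & res@windowStartS + 8 <= 19)
  expect_true(all(res@fallback[full]))
  # and the RF set is never empty
  expect_true(all(vapply(res@pflow, nrow, integer(1)) > 0))
})

test_that("detection is deterministic", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 12))
  r1 <- detectRfPixels(ph$video)
  r2 <- detectRfPixels(ph$video)
  expect_identical(r1@pflow, r2@pflow)
  expect_identical(r1@coreTrajectory, r2@coreTrajectory)
  expect_identical(signalValues(rfSignal(r1)), signalValues(rfSignal(r2)))
})

test_that("RF signal is stitched sample-aligned across windows", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 15))
  v <- interpolateUniform(ph$video, 9)
  res <- analyzeVideo(v)
  nw <- length(res@pflow)
  expect_length(signalValues(rfSignal(res)), 72 + 9 * (nw - 1))
})

test_that("the MR set covers flow and motion pixels and the MR/RF signals
           agree on single-source scenes", {
  ph <- generatePhantom(defaultScenes("flow_plus_inphase_motion",
                                      durationS = 16))
  v <- interpolateUniform(ph$video, 9)
  res <- analyzeVideo(v)
  flowPx <- which(ph$flowMask, arr.ind = TRUE)
  motionPx <- which(ph$motionMask, arr.ind = TRUE)
  j <- 5
  pmKeys <- paste(res@pm[[j]][, 1], res@pm[[j]][, 2])
  covFlow <- mean(paste(flowPx[, 1], flowPx[, 2]) %in% pmKeys)
  covMotion <- mean(paste(motionPx[, 1], motionPx[, 2]) %in% pmKeys)
  expect_gte(covFlow, 0.7)
  expect_gte(covMotion, 0.7)

  ph2 <- generatePhantom(defaultScenes("flow_only", durationS = 16))
  res2 <- analyzeVideo(interpolateUniform(ph2$video, 9))
  # past window 1 (whose RF set is the single, noisier core-pixel by
  # definition) both signals average the same source
  rf <- signalValues(res2@rfSignal)[-(1:72)]
  mr <- signalValues(res2@mrSignal)[-(1:72)]
  expect_gte(cor(rf, mr), 0.95)
})

test_that("anti-correlated pixels are sign-flipped into the MR average", {
  ph <- generatePhantom(defaultScenes("flow_plus_antiphase_motion",
                                      durationS = 16))
  v <- interpolateUniform(ph$video, 9)
  flip <- analyzeVideo(v, flipAntiphase = TRUE)
  noflip <- analyzeVideo(v, flipAntiphase = FALSE)
  expect_gt(sd(signalValues(flip@mrSignal)),
            sd(signalValues(noflip@mrSignal)))
})

test_that("raising xi2 never grows the flow set", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 14))
  v <- interpolateUniform(ph$video, 9)
  lo <- analyzeVideo(v, config = runConfig(xi2 = 0.2))
  hi <- analyzeVideo(v, config = runConfig(xi2 = 0.5))
  nLo <- vapply(lo@pflow, nrow, integer(1))
  nHi <- vapply(hi@pflow, nrow, integer(1))
  expect_true(all(nHi[-1] <= nLo[-1]))
})
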