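test_that("phantom generation is seed-deterministic and validated", {
  cfg <- defaultScenes("flow_only", durationS = 10)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(frames(a$video), frames(b$video))
  expect_identical(timestamps(a$video), timestamps(b$video))

  bad <- phantomConfig(grid = c(30, 30),
                       flowBlobs = list(list(center = c(2, 15),
                                             sigmaPx = 3, ampDegC = 0.4)))
  expect_error(generatePhantom(bad), "2 sigma")
  bad2 <- phantomConfig(grid = c(30, 30),
                        flowBlobs = list(list(center = c(40, 15),
                                              sigmaPx = 3, ampDegC = 0.4)))
  expect_error(generatePhantom(bad2), "outside")
})

test_that("timestamps are uneven at ~8.7 Hz and interpolation recovers the
           sinusoid", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 30))
  ts <- timestamps(ph$video)
  rate <- (length(ts) - 1) / (ts[length(ts)] - ts[1])
  expect_lt(abs(rate - 8.7) / 8.7, 0.01)
  expect_gt(sd(diff(ts)), 0)  # genuinely uneven

  # noise-free phantom: linear interpolation recovers the blob sinusoid
  # with normalised RMS error < 2% (of the signal range)
  cfg <- defaultScenes("flow_only", durationS = 30)
  cfg$noiseSigmaDegC <- 0
  ph0 <- generatePhantom(cfg)
  u <- interpolateUniform(ph0$video, 9)
  ctr <- cfg$flowBlobs[[1]]$center
  rec <- frames(u)[ctr[1], ctr[2], ]
  truth <- mean(rec) + cfg$flowBlobs[[1]]$ampDegC *
    sin(2 * pi * cfg$rrBpm / 60 * timestamps(u))
  nrmse <- sqrt(mean((rec - truth)^2)) / diff(range(truth))
  expect_lt(nrmse, 0.02)
})

test_that("a noise-free blob breathes at the configured rate", {
  cfg <- defaultScenes("flow_only", durationS = 20)
  cfg$noiseSigmaDegC <- 0
  ph <- generatePhantom(cfg)
  u <- interpolateUniform(ph$video, 9)
  ctr <- cfg$flowBlobs[[1]]$center
  x <- bandpassPixels(frames(u)[ctr[1], ctr[2], ], 9)
  rr <- rrTrace(SignalTrace(x, 9))
  expect_true(all(abs(rr$rr_bpm - 48) <= 1.2))
})

test_that("band-passed blob-centre SNR matches the configured amp/noise
           ratio", {
  cfg <- defaultScenes("flow_only", durationS = 40)
  ph <- generatePhantom(cfg)
  u <- interpolateUniform(ph$video, 9)
  ctr <- cfg$flowBlobs[[1]]$center
  sig <- bandpassPixels(frames(u)[ctr[1], ctr[2], ], 9)
  noise <- bandpassPixels(frames(u)[ctr[1], ctr[2] + 30, ], 9)
  core <- 50:(length(sig) - 50)
  snrMeasured <- (mean(sig[core]^2) - mean(noise[core]^2)) /
    mean(noise[core]^2)
  # in-band signal power amp^2/2 over the in-band share of the noise power
  inbandNoiseVar <- var(noise[core])
  snrExpected <- (cfg$flowBlobs[[1]]$ampDegC^2 / 2) / inbandNoiseVar
  expect_lt(abs(snrMeasured - snrExpected) / snrExpected, 0.2)
})

test_that("anti-phase edges anti-covary with the blob centre", {
  cfg <- defaultScenes("flow_plus_antiphase_motion", durationS = 16)
  ph <- generatePhantom(cfg)
  u <- interpolateUniform(ph$video, 9)
  Xf <- bandpassPixels(frames(u), 9)
  ctr <- cfg$flowBlobs[[1]]$center
  edgePx <- which(ph$motionMask, arr.ind = TRUE)
  covs <- vapply(seq_len(nrow(edgePx)), function(i)
    mean(Xf[ctr[1], ctr[2], 20:120] *
           Xf[edgePx[i, 1], edgePx[i, 2], 20:120]), numeric(1))
  expect_true(all(covs < 0))
})

test_that("scene presets expose their defining structure", {
  expect_error(defaultScenes("no_such_scene"), "unknown")

  ap <- defaultScenes("apnea_10s")
  expect_equal(ap$apneaIntervals[[1]], c(25, 35))
  ph <- generatePhantom(defaultScenes("apnea_10s", durationS = 40))
  # flow amplitude exactly zero inside the interval: the blob centre
  # carries only noise there
  ctr <- ap$flowBlobs[[1]]$center
  ts <- timestamps(ph$video)
  inap <- ts >= 25 & ts < 35
  x <- frames(ph$video)[ctr[1], ctr[2], ]
  expect_lt(sd(x[inap]), 3 * ap$noiseSigmaDegC)
  expect_gt(sd(x[!inap & ts > 5 & ts < 20]), 5 * ap$noiseSigmaDegC)

  fo <- generatePhantom(defaultScenes("flow_only", durationS = 10))
  expect_equal(sum(fo$motionMask), 0)

  ne <- generatePhantom(defaultScenes("nostril_on_edge", durationS = 10))
  u <- interpolateUniform(ne$video, 9)
  G <- gradientMap(apply(frames(u)[, , 1:72], c(1, 2), mean))
  expect_gt(sum(ne$flowMask & G == 1), 0)
})

test_that("ground-truth masks mark the 20% amplitude contour", {
  cfg <- defaultScenes("flow_plus_inphase_motion")
  ph <- generatePhantom(cfg)
  b <- cfg$flowBlobs[[1]]
  r <- matrix(seq_len(60), 60, 80)
  cc <- matrix(seq_len(80), 60, 80, byrow = TRUE)
  d2 <- (r - b$center[1])^2 + (cc - b$center[2])^2
  expect_identical(ph$flowMask, exp(-d2 / (2 * b$sigmaPx^2)) >= 0.2)
  expect_gt(sum(ph$motionMask), 0)
})
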