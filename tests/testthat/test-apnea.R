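test_that("the OA simulator silences flow inside the boxes and nothing
           else", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 40))
  v <- interpolateUniform(ph$video, 9)
  oa <- simulateOa(v, ph$annotations, seed = 5)
  d <- dim(frames(v))
  pann <- annotationPixels(ph$annotations, d[1:2])
  inBox <- matrix(FALSE, d[1], d[2])
  inBox[pann] <- TRUE

  # pixels outside the boxes are bit-identical (motion pixels unaltered)
  Xv <- frames(v); dim(Xv) <- c(d[1] * d[2], d[3])
  Xo <- frames(oa); dim(Xo) <- c(d[1] * d[2], d[3])
  out <- !as.vector(inBox)
  expect_identical(Xo[out, ], Xv[out, ])
  expect_identical(timestamps(oa), timestamps(v))

  # in-band power of the mean annotated signal drops >= 90% in the hole
  iv <- videoMeta(oa)$oa_interval
  tt <- timestamps(v)
  hole <- tt >= iv[1] & tt < iv[2]
  bandPower <- function(video) {
    X <- frames(video); dim(X) <- c(d[1] * d[2], d[3])
    m <- colMeans(X[pann[, 1] + (pann[, 2] - 1) * d[1], ])
    mb <- bandpassPixels(m, 9)
    mean(mb[hole]^2)
  }
  expect_lte(bandPower(oa), 0.1 * bandPower(v))

  # the low-frequency content inside the hole follows the original
  X0 <- frames(v); dim(X0) <- c(d[1] * d[2], d[3])
  X1 <- frames(oa); dim(X1) <- c(d[1] * d[2], d[3])
  i <- pann[1, 1] + (pann[1, 2] - 1) * d[1]
  lp0 <- thermoflow:::lowpassTrace(X0[i, ], 9)
  lp1 <- thermoflow:::lowpassTrace(X1[i, ], 9)
  expect_lt(max(abs((lp1 - lp0)[hole])), 0.1)
})

test_that("OA simulation validates its preconditions", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 12))
  v <- interpolateUniform(ph$video, 9)
  expect_error(simulateOa(v, ph$annotations), "too short")
  empty <- AnnotationBoxes(NULL, "none")
  ph2 <- generatePhantom(defaultScenes("flow_only", durationS = 40))
  expect_error(simulateOa(interpolateUniform(ph2$video, 9), empty), "empty")
})

test_that("the cessation detector flags amplitude drops and nothing on
           steady signals", {
  tt <- (0:539) / 9
  steady <- sin(2 * pi * 1 * tt)
  expect_equal(sum(cobMask(cobDetect(SignalTrace(steady, 9)))), 0)

  set.seed(41)
  x <- steady
  hole <- tt >= 25 & tt < 35
  x[hole] <- rnorm(sum(hole), sd = 0.1)
  cob <- cobDetect(SignalTrace(x, 9))
  overlap <- sum(cobMask(cob) & hole) / 9
  expect_gte(overlap, 5)

  # all-zero signal: 0 < alpha * 0 is false, no detection
  expect_equal(sum(cobMask(cobDetect(SignalTrace(rep(0, 540), 9)))), 0)

  expect_error(cobDetect(SignalTrace(rnorm(90), 9)), "shorter")
})

test_that("cessation detection is amplitude-scale invariant", {
  set.seed(42)
  tt <- (0:449) / 9
  x <- sin(2 * pi * 0.9 * tt) + rnorm(450, sd = 0.1)
  x[200:280] <- 0.05 * x[200:280]
  m1 <- cobMask(cobDetect(SignalTrace(x, 9)))
  m2 <- cobMask(cobDetect(SignalTrace(37.5 * x, 9)))
  expect_identical(m1, m2)
})

test_that("time-based template metrics follow duration arithmetic", {
  rate <- 1
  tmpl <- c(rep(0, 25), rep(1, 10), rep(0, 25))

  m <- templateMetrics(tmpl, tmpl, rate)
  expect_equal(unname(m), c(100, 100, 100))

  m0 <- templateMetrics(rep(0, 60), tmpl, rate)
  expect_equal(unname(m0["se"]), 0)
  expect_equal(unname(m0["sp"]), 100)
  expect_equal(unname(m0["acc"]), 100 * 50 / 60, tolerance = 1e-10)

  shifted <- c(rep(0, 30), rep(1, 10), rep(0, 20))
  ms <- templateMetrics(shifted, tmpl, rate)
  expect_equal(unname(ms["se"]), 50)

  expect_true(is.na(templateMetrics(rep(0, 10), rep(0, 10), rate)["se"]))
  expect_error(templateMetrics(rep(0, 5), rep(0, 6), rate), "equal length")
})
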