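test_that("view merging stacks rows in order and validates column counts", {
  mk <- function(val, M = 60) ThermalVideo(array(val, c(M, 80, 3)),
                                           c(0, 0.1, 0.2))
  merged <- mergeViews(list(mk(1), mk(2), mk(3)))
  expect_equal(frameDim(merged), c(180, 80))
  expect_equal(frames(merged)[30, 1, 1], 1)
  expect_equal(frames(merged)[90, 1, 1], 2)
  expect_equal(frames(merged)[150, 1, 1], 3)

  one <- mk(7)
  expect_identical(mergeViews(list(one)), one)

  bad <- ThermalVideo(array(0, c(60, 64, 3)), c(0, 0.1, 0.2))
  expect_error(mergeViews(list(mk(1), bad)), "column count")
})

test_that("uniform resampling interpolates linearly and lands on k/rate", {
  # midpoint of a linear segment
  v <- ThermalVideo(array(c(10, 12, 14), c(1, 1, 3)),
                    c(0, 0.2222, 0.4444))
  u <- interpolateUniform(v, 9)
  expect_equal(frames(u)[1, 1, 2], 11, tolerance = 1e-3)

  # already-uniform input is unchanged at the knots
  tv <- tinyBlobVideo(Tn = 45)
  u2 <- interpolateUniform(tv, 9)
  expect_equal(frames(u2), frames(tv), tolerance = 1e-12)

  # jittered 8.7 Hz timestamps -> exact 1/9 s output spacing
  ph <- generatePhantom(phantomConfig(grid = c(8, 8), durationS = 10,
                                      flowBlobs = list(list(
                                        center = c(4, 4), sigmaPx = 1,
                                        ampDegC = 0.3)),
                                      body = list(center = c(4, 4),
                                                  semi = c(1, 1),
                                                  deltaDegC = 0),
                                      seed = 3))
  u3 <- interpolateUniform(ph$video, 9)
  expect_lt(max(abs(diff(timestamps(u3)) - 1 / 9)), 1e-9)
  expect_equal(videoMeta(u3)$uniform_rate, 9)

  expect_error(interpolateUniform(tv, -1), "positive")
})

test_that("interpolation is exact on piecewise-linear signals", {
  ts <- cumsum(c(0, runif(40, 0.08, 0.15)))
  vals <- cumsum(rnorm(41))  # piecewise linear between knots by definition
  v <- ThermalVideo(array(rep(vals, each = 4), c(2, 2, 41)), ts)
  u <- interpolateUniform(v, 9)
  expected <- approx(ts, vals, xout = timestamps(u))$y
  expect_equal(frames(u)[1, 1, ], expected, tolerance = 1e-12)
})

test_that("sliding windows follow the 8 s / 1 s hop contract", {
  mkv <- function(Tn) ThermalVideo(
    array(rnorm(4 * Tn), c(2, 2, Tn)), (seq_len(Tn) - 1) / 9,
    meta = list(uniform_rate = 9))
  expect_length(slidingWindows(mkv(72)), 1)
  expect_error(slidingWindows(mkv(71)), "shorter than 8 s")

  # enumeration oracle: count positions where a full 72-sample window fits
  Tn <- 270
  count <- 0
  start <- 1
  while (start + 71 <= Tn) {
    count <- count + 1
    start <- start + 9
  }
  expect_equal(count, 23)
  w <- slidingWindows(mkv(Tn))
  expect_length(w, count)
  expect_equal(w[[2]]@startS, 1)
  expect_equal(dim(w[[1]]@samples)[3], 72)
})

test_that("band-pass keeps 60 BPM, removes DC and attenuates drift", {
  tt <- (0:539) / 9
  x <- sin(2 * pi * 1 * tt)  # 60 BPM
  y <- bandpassPixels(x, 9)
  expect_gt(max(abs(y[100:400])), 0.95)
  expect_lt(max(abs(y[100:400])), 1.05)

  expect_lt(max(abs(bandpassPixels(rep(3.7, 540), 9))), 1e-8)

  drift <- sin(2 * pi * (5 / 60) * tt)  # 5 BPM
  yd <- bandpassPixels(drift, 9)
  # >= 20 dB attenuation, measured away from the edges
  expect_lt(max(abs(yd[100:400])), 0.1)
})

test_that("filtering is linear and commutes with windowing", {
  set.seed(7)
  x <- rnorm(180)
  expect_equal(bandpassPixels(3.5 * x, 9), 3.5 * bandpassPixels(x, 9),
               tolerance = 1e-9)

  # windows are views: filtering the segment then windowing equals
  # windowing the filtered segment
  v <- tinyBlobVideo(Tn = 99)
  filt <- bandpassPixels(frames(v), 9)
  vf <- ThermalVideo(filt, timestamps(v), meta = videoMeta(v))
  w <- slidingWindows(vf)
  expect_equal(w[[2]]@samples[, , 1], filt[, , 10], tolerance = 1e-12)
})
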