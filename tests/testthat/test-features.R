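test_that("gradient map marks steps and stays silent on flat frames", {
  expect_true(all(gradientMap(matrix(5, 20, 20)) == 0))

  step <- cbind(matrix(30, 20, 10), matrix(34, 20, 10))
  G <- gradientMap(step)
  # ones only in a band at the step column (10/11), dilated by 1
  marked <- which(G[10, ] == 1)
  expect_true(all(marked %in% 8:13))
  expect_true(any(G[, 10] == 1) && any(G[, 11] == 1))
  expect_true(all(G[, c(1:6, 15:20)] == 0))
})

test_that("gradient map catches the phantom body boundary", {
  ph <- generatePhantom(defaultScenes("flow_only", durationS = 10))
  v <- interpolateUniform(ph$video, 9)
  G <- gradientMap(apply(frames(v)[, , 1:72], c(1, 2), mean))
  inside <- thermoflow:::bodyInsideMask(ph$config)
  ring <- inside & !(thermoflow:::shiftMatrix(inside, 1, 0, TRUE) &
                     thermoflow:::shiftMatrix(inside, -1, 0, TRUE) &
                     thermoflow:::shiftMatrix(inside, 0, 1, TRUE) &
                     thermoflow:::shiftMatrix(inside, 0, -1, TRUE))
  expect_gte(mean(G[ring]), 0.95)
})

test_that("pseudo-periodicity peaks at a pure tone and degrades gracefully", {
  set.seed(11)
  M <- 10; L <- 10; N <- 72
  tt <- (0:(N - 1)) / 9
  S <- array(rnorm(M * L * N, sd = 1), c(M, L, N))
  S[4, 7, ] <- 3 * sin(2 * pi * 1 * tt)  # single pure 60 BPM pixel
  Q <- pseudoPeriodicityMap(S)
  expect_equal(which(Q == 1, arr.ind = TRUE)[1, ], c(row = 4, col = 7))
  expect_true(all(Q >= 0 & Q <= 1))

  # pure noise: normalization still tops at 1 but raw Q is near-uniform
  Sn <- array(rnorm(M * L * N), c(M, L, N))
  Qn <- pseudoPeriodicityMap(Sn)
  expect_equal(max(Qn), 1)
  expect_lt(max(Qn) / median(Qn), 3)

  expect_true(all(pseudoPeriodicityMap(array(0, c(4, 4, N))) == 0))
})

test_that("RR clusters reward coherent patches and punish isolated tones", {
  N <- 72
  tt <- (0:(N - 1)) / 9
  # whole frame at one frequency -> all ones (interior and border alike,
  # after the per-window normalization)
  S <- array(rep(sin(2 * pi * 0.8 * tt), each = 100), c(10, 10, N))
  W <- rrClustersMap(S)
  expect_true(all(W[3:8, 3:8] == 1))

  # isolated periodic pixel in noise scores below a coherent 5x5 patch
  set.seed(12)
  S2 <- array(rnorm(15 * 15 * N, sd = 0.3), c(15, 15, N))
  S2[3, 3, ] <- sin(2 * pi * 0.8 * tt)
  for (r in 9:13) for (cc in 9:13)
    S2[r, cc, ] <- sin(2 * pi * 0.8 * tt) + rnorm(N, sd = 0.1)
  W2 <- rrClustersMap(S2)
  expect_lt(W2[3, 3], W2[11, 11])

  # checkerboard of two distant frequencies: enumeration oracle says a
  # pixel agrees with at most half of its full 24-neighbourhood
  S3 <- array(0, c(12, 12, N))
  for (r in 1:12) for (cc in 1:12) {
    f <- if ((r + cc) %% 2 == 0) 36 / 60 else 100 / 60
    S3[r, cc, ] <- sin(2 * pi * f * tt)
  }
  dom <- dominantFrequencyMap(S3)
  agreeOracle <- matrix(0, 12, 12)
  for (r in 3:10) for (cc in 3:10) {
    cnt <- 0
    for (dr in -2:2) for (dc in -2:2) {
      if (dr == 0 && dc == 0) next
      if (abs(dom[r, cc] - dom[r + dr, cc + dc]) <= 7.5) cnt <- cnt + 1
    }
    agreeOracle[r, cc] <- cnt / 24
  }
  expect_true(all(agreeOracle[3:10, 3:10] <= 0.5))
  W3raw <- thermoflow:::rrClustersFromFrequencies(dom)
  expect_equal(W3raw[3:10, 3:10], agreeOracle[3:10, 3:10])
})

test_that("core-pixel selection follows the product-argmax with tie-breaks", {
  Q <- matrix(0, 5, 5); W <- matrix(1, 5, 5); G <- matrix(0, 5, 5)
  Q[2, 3] <- 1; Q[4, 1] <- 1
  expect_equal(selectCorePixel(Q, W, G), c(2, 3))  # lowest row wins
  Q2 <- matrix(0, 5, 5); Q2[3, 2] <- 1; Q2[3, 4] <- 1
  expect_equal(selectCorePixel(Q2, W, G), c(3, 2)) # then lowest column

  expect_error(selectCorePixel(Q, W, matrix(1, 5, 5)), "no candidate")
})

test_that("correlation map matches a two-pass Pearson oracle to 1e-12", {
  set.seed(13)
  S <- array(rnorm(4 * 4 * 72), c(4, 4, 72))
  S[2, 2, ] <- S[2, 2, ] + 2 * sin(2 * pi * 0.9 * (0:71) / 9)
  C <- correlationMap(S, c(2, 2))
  for (r in 1:4) for (cc in 1:4)
    expect_equal(C[r, cc], oraclePearson(S[2, 2, ], S[r, cc, ]),
                 tolerance = 1e-12)
  expect_equal(C[2, 2], 1)

  # anti-phase pixel: C = -1 but binarization keeps it
  S[3, 3, ] <- -S[2, 2, ]
  C2 <- correlationMap(S, c(2, 2))
  expect_equal(C2[3, 3], -1)
  expect_equal(binarizeCorrelation(C2)[3, 3], 1)

  # zero-variance pixel gets correlation 0
  S[1, 1, ] <- 0
  expect_equal(correlationMap(S, c(2, 2))[1, 1], 0)
})

test_that("null correlations rarely cross the 0.6 threshold at N = 72", {
  set.seed(14)
  hits <- 0
  n <- 1000
  core <- rnorm(72)
  for (i in seq_len(n)) if (abs(oraclePearson(core, rnorm(72))) > 0.6)
    hits <- hits + 1
  expect_gte((n - hits) / n, 0.99)
})

test_that("covariance map keeps sign, normalizes to [-1, 1], handles j = 1", {
  N <- 72
  expect_true(all(covarianceMap(array(rnorm(32 * N), c(4, 8, N))) == 1))

  x <- rep(c(1, -1), N / 2)
  S <- array(0, c(3, 3, N))
  S[1, 1, ] <- x
  S[2, 2, ] <- x
  S[3, 3, ] <- -x
  S[1, 2, ] <- 0.4 * x
  Cf <- covarianceMap(S, prevCore = c(1, 1))
  expect_equal(Cf[2, 2], 1)
  expect_equal(Cf[3, 3], -1)
  expect_equal(Cf[1, 2], 0.4)
  expect_true(max(abs(Cf)) == 1)

  # all-zero previous core signal -> all-zero map
  Sz <- S; Sz[1, 1, ] <- 0
  expect_true(all(covarianceMap(Sz, prevCore = c(1, 1))[2, 2] == 0))

  # sign of the covariance equals the sign of the correlation with the
  # core for zero-mean (band-passed) signals
  set.seed(15)
  Sr <- array(rnorm(5 * 5 * N), c(5, 5, N))
  for (r in 1:5) for (cc in 1:5) Sr[r, cc, ] <- Sr[r, cc, ] - mean(Sr[r, cc, ])
  Cf2 <- covarianceMap(Sr, prevCore = c(3, 3))
  for (r in 1:5) for (cc in 1:5) {
    rho <- oraclePearson(Sr[3, 3, ], Sr[r, cc, ])
    if (abs(rho) > 1e-12)
      expect_equal(sign(Cf2[r, cc]), sign(rho))
  }
})
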