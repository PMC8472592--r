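# Independent oracles used to check the package's fast paths. These are
# deliberately naive (nested loops, two-pass formulas) and share no code
# with the implementation.

# Symmetric reflection of an out-of-range index onto 1..n (edge repeated).
oracleReflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Direct "same" 2-D convolution with reflective border, nested loops.
oracleConv2 <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0 + 0i, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    acc <- 0 + 0i
    for (dr in -hr:hr) for (dc in -hc:hc) {
      rr <- oracleReflect(r - dr, nrow(x))
      cc <- oracleReflect(c - dc, ncol(x))
      acc <- acc + x[rr, cc] * kernel[dr + hr + 1, dc + hc + 1]
    }
    out[r, c] <- acc
  }
  out
}

# Two-pass Pearson correlation.
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) 0 else num / den
}

# Brute-force per-pixel membership counting for the PF / PM scores.
oraclePf <- function(pflow, pann) {
  hits <- 0
  for (i in seq_len(nrow(pflow))) {
    for (k in seq_len(nrow(pann))) {
      if (pflow[i, 1] == pann[k, 1] && pflow[i, 2] == pann[k, 2]) {
        hits <- hits + 1
        break
      }
    }
  }
  100 * hits / nrow(pflow)
}

oraclePm <- function(pflow, pm, pann) {
  inSet <- function(p, set) {
    for (k in seq_len(nrow(set)))
      if (p[1] == set[k, 1] && p[2] == set[k, 2]) return(TRUE)
    FALSE
  }
  hits <- 0
  for (i in seq_len(nrow(pflow))) {
    p <- pflow[i, ]
    if (inSet(p, pm) && !inSet(p, pann)) hits <- hits + 1
  }
  100 * hits / nrow(pflow)
}

# A tiny uniformly-sampled video with one noiseless oscillating blob,
# built directly (not via the phantom module) for low-level tests.
tinyBlobVideo <- function(M = 12, L = 12, Tn = 90, rateHz = 9,
                          freqHz = 0.8, amp = 0.5, center = c(6, 6),
                          sigma = 1.5, noise = 0, seed = 42) {
  set.seed(seed)
  tt <- (seq_len(Tn) - 1) / rateHz
  r <- matrix(seq_len(M), M, L)
  cc <- matrix(seq_len(L), M, L, byrow = TRUE)
  field <- amp * exp(-((r - center[1])^2 + (cc - center[2])^2) /
                       (2 * sigma^2))
  X <- 30 + as.vector(field) %*% t(sin(2 * pi * freqHz * tt))
  if (noise > 0) X <- X + matrix(rnorm(M * L * Tn, sd = noise), M * L, Tn)
  dim(X) <- c(M, L, Tn)
  ThermalVideo(X, tt, meta = list(uniform_rate = rateHz, unit = "C"))
}
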