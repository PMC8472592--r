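# Internal numerical helpers: symmetric boundary extension, FFT-based 2-D
# convolution, deterministic argmax. Not exported.

# Map arbitrary integer indices onto 1..n by half-sample symmetric reflection
# (edge value repeated: ..., 2, 1, 1, 2, ..., n, n, n-1, ...). Works for any
# offset, so padding wider than the image is well defined.
reflectIndex <- function(i, n) {
  p <- 2L * n
  k <- ((i - 1L) %% p + p) %% p
  ifelse(k < n, k + 1L, p - k)
}

# Reflect-pad a matrix by hr rows / hc columns on each side.
padReflect <- function(x, hr, hc) {
  ri <- reflectIndex((1L - hr):(nrow(x) + hr), nrow(x))
  ci <- reflectIndex((1L - hc):(ncol(x) + hc), ncol(x))
  x[ri, ci, drop = FALSE]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Next FFT-friendly size (products of 2, 3, 5).
goodFFTSize <- function(n) as.integer(stats::nextn(n, c(2, 3, 5)))

# "Same" 2-D convolution with reflective boundary handling, via FFT.
# kernel may be complex; its support must be odd in both dimensions.
conv2Same <- function(x, kernel) {
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) stop("kernel support must be odd")
  hr <- (kd[1] - 1L) %/% 2L
  hc <- (kd[2] - 1L) %/% 2L
  xp <- padReflect(x, hr, hc)
  nr <- goodFFTSize(nrow(xp) + kd[1] - 1L)
  nc <- goodFFTSize(ncol(xp) + kd[2] - 1L)
  X <- matrix(0, nr, nc); X[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  K <- matrix(0 + 0i, nr, nc); K[seq_len(kd[1]), seq_len(kd[2])] <- kernel
  full <- ifft2(fft2(X) * fft2(K))
  rows <- (2L * hr + 1L):(2L * hr + nrow(x))
  cols <- (2L * hc + 1L):(2L * hc + ncol(x))
  out <- full[rows, cols, drop = FALSE]
  if (is.double(kernel)) Re(out) else out
}

# Deterministic argmax over a matrix: highest value, ties broken by lowest
# row index, then lowest column index. Returns c(row, col).
argmaxPixel <- function(map) {
  mx <- max(map)
  idx <- which(map == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  as.integer(idx[1, ])
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shiftMatrix <- function(x, dr, dc, fill = NA) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

# Binary dilation with a (2r+1) x (2r+1) square structuring element.
dilateBinary <- function(x, r = 1L) {
  out <- x
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    out <- out | shiftMatrix(x, dr, dc, fill = FALSE)
  }
  out
}

# Convert a logical/binary M x L map to a 1-based (row, col) pixel matrix.
maskToPixels <- function(mask) {
  which(mask != 0, arr.ind = TRUE)[, 1:2, drop = FALSE]
}

# Key pixels for set operations (dims-independent, exact).
pixelKeys <- function(px) {
  if (is.null(px) || nrow(px) == 0) return(character(0))
  paste(px[, 1], px[, 2], sep = ",")
}

isUniformRate <- function(video, tol = 1e-6) {
  ts <- timestamps(video)
  dt <- diff(ts)
  max(abs(dt - dt[1])) < tol
}
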