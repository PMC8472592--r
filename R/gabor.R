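# Gabor filter bank: flow pixels form 2-D smooth blobs that respond for
# every orientation, motion pixels lie along (possibly curved) lines and
# drop out at some orientation, so the product of response magnitudes over
# all wavelengths and orientations singles out the flow region.

gaborSigma <- function(lambda, bandwidthOct = 1) {
  lambda / pi * sqrt(log(2) / 2) *
    (2^bandwidthOct + 1) / (2^bandwidthOct - 1)
}

# Complex (quadrature-pair) Gabor kernel. theta in degrees; x' runs along
# the carrier. Envelope: Gaussian with sigma set from lambda via a
# one-octave half-response spatial-frequency bandwidth, aspect ratio gamma.
gaborKernel <- function(lambda, thetaDeg, bandwidthOct = 1, gamma = 0.5) {
  sigma <- gaborSigma(lambda, bandwidthOct)
  half <- ceiling(2.5 * sigma / gamma)
  g <- seq(-half, half)
  cols <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)  # x: columns
  rows <- matrix(g, 2 * half + 1, 2 * half + 1)                # y: rows
  th <- thetaDeg * pi / 180
  xp <- cols * cos(th) + rows * sin(th)
  yp <- -cols * sin(th) + rows * cos(th)
  exp(-(xp^2 + (gamma * yp)^2) / (2 * sigma^2)) *
    exp(1i * 2 * pi * xp / lambda)
}

#' Build a Gabor filter bank
#'
#' One complex kernel per (wavelength, orientation) pair. The defaults --
#' wavelengths 3..8 pixels/cycle, orientations 10..170 degrees in steps of
#' 10 -- give 102 kernels; multiple wavelengths let the bank match both the
#' small flow regions at the nostrils and the larger ones on textiles. The
#' Gaussian envelope uses a one-octave half-response spatial-frequency
#' bandwidth and aspect ratio 0.5 (the common defaults of standard Gabor
#' implementations); both are configurable.
#'
#' @param lambdas wavelengths in pixels per cycle (positive).
#' @param thetas orientations in degrees.
#' @param bandwidthOct spatial-frequency bandwidth in octaves.
#' @param gamma spatial aspect ratio of the envelope.
#' @return A \code{\linkS4class{GaborBank}}.
#' @examples
#' length(makeGaborBank()@kernels)  # 6 x 17 = 102
#' @export
makeGaborBank <- function(lambdas = 3:8, thetas = seq(10, 170, by = 10),
                          bandwidthOct = 1, gamma = 0.5) {
  if (length(lambdas) == 0 || length(thetas) == 0)
    stop("need at least one wavelength and one orientation")
  if (any(lambdas <= 0)) stop("wavelengths must be positive")
  kernels <- list()
  for (lam in lambdas) for (th in thetas)
    kernels[[length(kernels) + 1L]] <- gaborKernel(lam, th, bandwidthOct,
                                                   gamma)
  new("GaborBank", kernels = kernels, lambdas = as.numeric(lambdas),
      thetas = as.numeric(thetas))
}

# Precompute kernel FFTs at a shared padded size for an M x L input, so the
# per-window cost is one forward FFT plus one inverse FFT per kernel.
gaborPrecompute <- function(bank, M, L) {
  halfs <- vapply(bank@kernels, function(k) (nrow(k) - 1L) %/% 2L,
                  integer(1))
  hmax <- max(halfs)
  NR <- goodFFTSize(M + 4L * hmax)
  NC <- goodFFTSize(L + 4L * hmax)
  kf <- lapply(bank@kernels, function(k) {
    K <- matrix(0 + 0i, NR, NC)
    K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    fft2(K)
  })
  list(kf = kf, halfs = halfs, hmax = hmax, NR = NR, NC = NC, M = M, L = L)
}

gaborForward <- function(map, pre) {
  xp <- padReflect(map, pre$hmax, pre$hmax)
  X <- matrix(0, pre$NR, pre$NC)
  X[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  fft2(X)
}

gaborOneResponse <- function(Fx, pre, i) {
  full <- ifft2(Fx * pre$kf[[i]])
  h <- pre$halfs[i]
  rows <- (pre$hmax + h + 1L):(pre$hmax + h + pre$M)
  cols <- (pre$hmax + h + 1L):(pre$hmax + h + pre$L)
  Mod(full[rows, cols, drop = FALSE])
}

#' Gabor response magnitudes of a binary flow map
#'
#' Convolves the input map with every kernel of the bank ("same" output,
#' reflective border) and returns the response magnitudes
#' \eqn{\Psi(\lambda, \theta) = |map \otimes \Gamma(\lambda, \theta)|}.
#' Border handling matters because an argmax near the frame edge depends on
#' it; reflective padding avoids the artificial step a zero border would
#' create.
#'
#' @param map numeric M x L matrix (the binarized flow map).
#' @param bank a \code{\linkS4class{GaborBank}}.
#' @return List of non-negative M x L matrices, one per kernel, in bank
#'   order (lambda-major).
#' @export
gaborResponses <- function(map, bank = makeGaborBank()) {
  pre <- gaborPrecompute(bank, nrow(map), ncol(map))
  Fx <- gaborForward(map, pre)
  lapply(seq_along(pre$kf), function(i) gaborOneResponse(Fx, pre, i))
}

#' Select the flow-core-pixel from Gabor responses
#'
#' Multiplies all response magnitudes elementwise and returns the position
#' of the highest value -- the pixel that responds for every wavelength and
#' orientation, i.e. the most isotropically smooth blob. The product of 102
#' factors underflows doubles, so it is accumulated in log space with a
#' floor of 1e-30 per factor; the argmax is unchanged. Ties break to the
#' lowest row, then column.
#'
#' @param responses list of non-negative response maps (from
#'   \code{\link{gaborResponses}}).
#' @return List with \code{pos} (integer \code{c(row, col)}) and
#'   \code{logResponse} (value of the log-product at \code{pos}).
#' @export
selectFlowCorePixel <- function(responses) {
  if (length(responses) == 0) stop("empty response list")
  acc <- matrix(0, nrow(responses[[1]]), ncol(responses[[1]]))
  for (r in responses) acc <- acc + log(pmax(r, 1e-30))
  if (max(acc) - min(acc) == 0)
    stop("no isotropic response (product map is flat)")
  pos <- argmaxPixel(acc)
  list(pos = pos, logResponse = acc[pos[1], pos[2]])
}

# Fused per-window path used by the engine: forward FFT once, accumulate
# the log product kernel by kernel. Returns NULL when the product map is
# flat (no isotropic response -- caller falls back).
gaborArgmax <- function(map, pre) {
  Fx <- gaborForward(map, pre)
  acc <- matrix(0, pre$M, pre$L)
  for (i in seq_along(pre$kf))
    acc <- acc + log(pmax(gaborOneResponse(Fx, pre, i), 1e-30))
  if (max(acc) - min(acc) == 0) return(NULL)
  argmaxPixel(acc)
}
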