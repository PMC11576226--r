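# Separable Gaussian smoothing with zero-padded boundaries, the masked
# (renormalized) variant used for log-FCD maps, and the frequency-domain
# bandpass utility for BOLD series.

# 1D zero-padded convolution matrices per axis for a given FWHM.
# sigma (voxels) = fwhm / (voxelSize * 2 * sqrt(2 * log(2))).
convolutionMatrices <- function(grid, fwhmMm) {
  lapply(1:3, function(ax) {
    n <- grid@shape[ax]
    sigma <- fwhmMm / (grid@voxelSize[ax] * 2 * sqrt(2 * log(2)))
    if (sigma < 1e-12) return(diag(n))
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[o + r + 1L]
    }
    K
  })
}

convolveSeparable <- function(arr, Ks) {
  d <- dim(arr)
  # axis 1
  m <- matrix(arr, d[1L], d[2L] * d[3L])
  arr <- array(Ks[[1L]] %*% m, d)
  # axis 2
  a <- aperm(arr, c(2L, 1L, 3L))
  m <- matrix(a, d[2L], d[1L] * d[3L])
  arr <- aperm(array(Ks[[2L]] %*% m, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  # axis 3
  a <- aperm(arr, c(3L, 1L, 2L))
  m <- matrix(a, d[3L], d[1L] * d[2L])
  aperm(array(Ks[[3L]] %*% m, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with per-axis sigma =
#' `fwhmMm / (voxelSize * 2 * sqrt(2 * log(2)))` and zero padding at the
#' volume boundary (the kernel is not renormalized there, so boundary
#' voxels are attenuated; quantitative use should stay on interior
#' voxels). `fwhmMm = 0` returns the input unchanged. Missing voxels are
#' not allowed here; use the masked smoothing inside [smoothLogFcd()] for
#' maps with missing values.
#'
#' @param vol a [Volume3D] (or subclass).
#' @param fwhmMm kernel full width at half maximum, mm (>= 0).
#' @return a [Volume3D] on the same grid.
#' @export
gaussianSmooth <- function(vol, fwhmMm) {
  stopifnot(is(vol, "Volume3D"))
  if (length(fwhmMm) != 1L || is.na(fwhmMm) || fwhmMm < 0)
    stop("fwhmMm must be a single nonnegative number")
  if (fwhmMm == 0) return(new("Volume3D", grid = vol@grid, values = vol@values))
  if (anyNA(vol@values))
    stop("gaussianSmooth does not accept missing voxels; use masked smoothing")
  Ks <- convolutionMatrices(vol@grid, fwhmMm)
  new("Volume3D", grid = vol@grid, values = convolveSeparable(vol@values, Ks))
}

# Masked Gaussian smoothing: kernel weights renormalized over present
# voxels; absent voxels stay absent. Shared by smoothLogFcd and the
# pipeline's SUVR smoothing-inside-mask is NOT this (SUVR follows the
# plain zero-padded convention before restriction).
maskedGaussianSmooth <- function(values, grid, fwhmMm) {
  present <- !is.na(values)
  if (!any(present)) stop("no present voxels to smooth")
  Ks <- convolutionMatrices(grid, fwhmMm)
  filled <- values
  filled[!present] <- 0
  num <- convolveSeparable(filled, Ks)
  den <- convolveSeparable(array(as.double(present), dim(values)), Ks)
  out <- array(NA_real_, dim(values))
  out[present] <- num[present] / den[present]
  out
}

#' Temporal bandpass filter for BOLD series
#'
#' Frequency-domain filter with unit gain on `[lowHz, highHz]`, a raised-
#' cosine roll-off over one frequency bin on either side, and zero gain
#' elsewhere (the mean/0 Hz component is always removed). Components
#' outside the band are attenuated by at least 20 dB and components well
#' inside by at most 1 dB, matching the conventional 0.01-0.08 Hz
#' resting-state passband at the default arguments.
#'
#' @param bold a [BoldSeries] with at least 16 timepoints.
#' @param lowHz,highHz passband edges; requires
#'   `0 <= lowHz < highHz < 1 / (2 * samplingInterval)`.
#' @return a filtered [BoldSeries].
#' @export
bandpassFilter <- function(bold, lowHz = 0.01, highHz = 0.08) {
  stopifnot(is(bold, "BoldSeries"))
  d <- dim(bold@data)
  nt <- d[4L]
  if (nt < 16L) stop("bandpass requires at least 16 timepoints")
  nyq <- 1 / (2 * bold@samplingInterval)
  if (!(lowHz >= 0 && lowHz < highHz && highHz < nyq))
    stop(sprintf("need 0 <= low < high < Nyquist (%.4g Hz)", nyq))
  m <- matrix(bold@data, prod(d[1:3]), nt)
  filt <- t(bandpassMatrix(t(m), bold@samplingInterval, lowHz, highHz))
  new("BoldSeries", grid = bold@grid, data = array(filt, d),
      samplingInterval = bold@samplingInterval)
}

# Core frequency-domain filter on a (time x series) matrix.
bandpassMatrix <- function(tm, tr, lowHz, highHz) {
  nt <- nrow(tm)
  df <- 1 / (nt * tr)
  k <- 0:(nt - 1L)
  f <- pmin(k, nt - k) * df      # two-sided frequency magnitude per bin
  g <- numeric(nt)
  inBand <- f >= lowHz & f <= highHz
  g[inBand] <- 1
  rollLo <- f > lowHz - df & f < lowHz
  g[rollLo] <- 0.5 * (1 + cos(pi * (lowHz - f[rollLo]) / df))
  rollHi <- f > highHz & f < highHz + df
  g[rollHi] <- 0.5 * (1 + cos(pi * (f[rollHi] - highHz) / df))
  g[1L] <- 0                     # always remove the mean
  ft <- stats::mvfft(tm)
  Re(stats::mvfft(ft * g, inverse = TRUE)) / nt
}
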