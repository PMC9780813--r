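# Wavelet-threshold denoising: single-level discrete wavelet decomposition
# with the biorthogonal bior3.1 filter pair and periodized boundaries,
# noise-level estimation from the coefficients, a universal
# (sigma * sqrt(2 ln n)) threshold, coefficient thresholding, and perfect
# inverse reconstruction.

#' Wavelet analysis/synthesis filters
#'
#' Returns the decomposition and reconstruction filter pairs. Only the
#' biorthogonal spline wavelet bior3.1 is built in; its taps are exact
#' multiples of sqrt(2)/8.
#'
#' @param wavelet Wavelet name; only `"bior3.1"` is supported.
#' @return List with numeric vectors `decLo`, `decHi`, `recLo`, `recHi`.
#' @export
waveletFilters <- function(wavelet = "bior3.1") {
  if (!identical(wavelet, "bior3.1"))
    stop("unsupported wavelet '", wavelet, "'; only bior3.1 is built in")
  s <- sqrt(2) / 8
  list(
    decLo = c(-2, 6, 6, -2) * s,
    decHi = c(-1, 3, -3, 1) * s,
    recLo = c(1, 3, 3, 1) * s,
    recHi = c(-2, -6, 6, 2) * s
  )
}

# periodized filter-downsample: c[k] = sum_i f[i] * x[(2k + 2 - i) mod N],
# k = 0 .. N/2 - 1 (0-based); N must be even
.periodicAnalysis <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  k <- seq_len(half) - 1L
  out <- numeric(half)
  for (i in seq_along(f)) {
    idx <- (2L * k + 2L - (i - 1L)) %% n + 1L
    out <- out + f[i] * x[idx]
  }
  out
}

#' Single-level discrete wavelet decomposition
#'
#' Periodized single-level DWT. Odd-length inputs are extended by one
#' repeated end sample before analysis (and trimmed again on
#' reconstruction), so both coefficient arrays have length `ceiling(n/2)`.
#'
#' @param x Numeric signal; must be at least as long as the wavelet filter.
#' @param wavelet Wavelet name (see [waveletFilters()]).
#' @param mode Boundary rule; only `"periodic"` periodization is supported.
#' @return A [WaveletDecomposition-class].
#' @export
dwtDecompose <- function(x, wavelet = "bior3.1", mode = "periodic") {
  filt <- waveletFilters(wavelet)
  if (!identical(mode, "periodic"))
    stop("unsupported boundary mode '", mode, "'; only 'periodic' is built in")
  n <- length(x)
  if (n < length(filt$decLo))
    stop("signal length ", n, " is shorter than the wavelet filter (",
         length(filt$decLo), ")")
  xp <- if (n %% 2L == 1L) c(x, x[n]) else x
  new("WaveletDecomposition",
      approx = .periodicAnalysis(xp, filt$decLo),
      detail = .periodicAnalysis(xp, filt$decHi),
      wavelet = wavelet, mode = mode, n = as.integer(n))
}

#' Inverse single-level discrete wavelet transform
#'
#' Exact inverse of [dwtDecompose()]: with unmodified coefficients the
#' round trip reproduces the input to floating-point accuracy.
#'
#' @param decomp A [WaveletDecomposition-class].
#' @return Numeric vector of length `decomp@n`.
#' @export
dwtReconstruct <- function(decomp) {
  filt <- waveletFilters(decomp@wavelet)
  half <- length(decomp@approx)
  n <- 2L * half
  upA <- numeric(n); upA[seq(1L, n, by = 2L)] <- decomp@approx
  upD <- numeric(n); upD[seq(1L, n, by = 2L)] <- decomp@detail
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (i in seq_along(filt$recLo)) {
    idx <- (idx0 + 1L - (i - 1L)) %% n + 1L
    out <- out + filt$recLo[i] * upA[idx] + filt$recHi[i] * upD[idx]
  }
  out[seq_len(decomp@n)]
}

#' Estimate the noise level from wavelet coefficients
#'
#' `sigma = deviation(c) / 0.6745`, where the deviation is taken over the
#' concatenation of the approximation and detail arrays. The
#' `median_abs_dev` estimator (median absolute deviation about the median;
#' 0.6745 is its Gaussian consistency constant) is the default; the
#' `mean_abs_dev` variant (mean absolute deviation about the mean over the
#' same constant) is also available.
#'
#' @param decomp A [WaveletDecomposition-class].
#' @param estimator `"median_abs_dev"` (default) or `"mean_abs_dev"`.
#' @return Non-negative sigma estimate in signal units.
#' @export
estimateSigma <- function(decomp,
                          estimator = c("median_abs_dev", "mean_abs_dev")) {
  estimator <- match.arg(estimator)
  coeffs <- c(decomp@approx, decomp@detail)
  if (!length(coeffs)) stop("empty coefficient arrays")
  dev <- switch(estimator,
    median_abs_dev = median(abs(coeffs - median(coeffs))),
    mean_abs_dev = mean(abs(coeffs - mean(coeffs))))
  dev / 0.6745
}

#' Universal threshold from a sigma estimate
#'
#' Default is the universal (VisuShrink) threshold
#' `sigma * sqrt(2 * ln(n))`; with `useSqrt = FALSE` the square root is
#' dropped, giving `sigma * 2 * ln(n)`.
#'
#' @param sigma Non-negative noise-level estimate.
#' @param n Length of the original signal (>= 1).
#' @param useSqrt Logical, default `TRUE`.
#' @return Non-negative threshold in signal units.
#' @export
computeThreshold <- function(sigma, n, useSqrt = TRUE) {
  if (n < 1) stop("'n' must be >= 1")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (useSqrt) sigma * sqrt(2 * log(n)) else sigma * 2 * log(n)
}

#' Threshold wavelet coefficients
#'
#' Applies hard (default) or soft thresholding to both the approximation
#' and detail arrays, or to the detail array only. Hard keeps coefficients
#' whose magnitude exceeds the threshold and zeroes the rest; soft shrinks
#' every coefficient toward zero by the threshold.
#'
#' @param decomp A [WaveletDecomposition-class].
#' @param thresh Non-negative threshold.
#' @param rule `"hard"` (default) or `"soft"`.
#' @param bands `"both"` (default, all coefficients) or `"detail"`.
#' @return A [WaveletDecomposition-class] with thresholded coefficients.
#' @export
thresholdCoeffs <- function(decomp, thresh, rule = c("hard", "soft"),
                            bands = c("both", "detail")) {
  rule <- match.arg(rule)
  bands <- match.arg(bands)
  if (thresh < 0) stop("threshold must be >= 0")
  shrink <- switch(rule,
    soft = function(c) sign(c) * pmax(abs(c) - thresh, 0),
    hard = function(c) ifelse(abs(c) > thresh, c, 0))
  new("WaveletDecomposition",
      approx = if (bands == "both") shrink(decomp@approx) else decomp@approx,
      detail = shrink(decomp@detail),
      wavelet = decomp@wavelet, mode = decomp@mode, n = decomp@n)
}

#' Denoising configuration
#'
#' @param wavelet Wavelet name.
#' @param mode Boundary mode.
#' @param estimator Sigma estimator (see [estimateSigma()]).
#' @param useSqrt Use the square root in the threshold formula
#'   (see [computeThreshold()]).
#' @param rule Thresholding rule (see [thresholdCoeffs()]).
#' @param bands Coefficient bands to threshold.
#' @return List of class `"DenoiseConfig"`.
#' @export
denoiseConfig <- function(wavelet = "bior3.1", mode = "periodic",
                          estimator = "median_abs_dev", useSqrt = TRUE,
                          rule = "hard", bands = "both") {
  structure(list(wavelet = wavelet, mode = mode, estimator = estimator,
                 useSqrt = useSqrt, rule = rule, bands = bands),
            class = "DenoiseConfig")
}

#' Wavelet-threshold denoising of a signal
#'
#' Pipeline: decompose, estimate sigma, compute the universal threshold,
#' threshold the coefficients, reconstruct. Output length equals input
#' length.
#'
#' @param x Numeric signal.
#' @param config A [denoiseConfig()].
#' @return List with `signal` (denoised samples), `coeffs` (the thresholded
#'   [WaveletDecomposition-class]), `sigma` and `threshold`.
#' @examples
#' rec <- generateRecord(seed = 1, snrDb = 10)
#' v1 <- selectLead(rec, "v1")$samples
#' out <- denoiseSignal(v1)
#' signalSnr(cleanComponent(rec, "v1"), out$signal)  # > input SNR
#' @export
denoiseSignal <- function(x, config = denoiseConfig()) {
  decomp <- dwtDecompose(x, config$wavelet, config$mode)
  sigma <- estimateSigma(decomp, config$estimator)
  thresh <- computeThreshold(sigma, length(x), config$useSqrt)
  kept <- thresholdCoeffs(decomp, thresh, config$rule, config$bands)
  list(signal = dwtReconstruct(kept), coeffs = kept,
       sigma = sigma, threshold = thresh)
}
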