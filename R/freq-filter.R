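# Fourier-domain data reduction: compute the FFT, *delete* (not zero) the
# bins above the cutoff frequency, and invert the shortened spectrum, so
# the output is a genuinely shorter time series. Default cutoff 2 Hz keeps
# only the baseline content of an ECG.

#' Signed FFT bin frequencies
#'
#' Standard FFT layout: DC, positive frequencies, then negative
#' frequencies. Computed as `index * fs / n` to keep grid frequencies
#' exact where `index * fs` is.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `n`, bin spacing `fs/n`.
#' @export
fftBinFrequencies <- function(n, fs) {
  idx <- c(0:((n - 1L) %/% 2L), -((n %/% 2L):1L))
  idx * fs / n
}

#' Complex spectrum of a signal
#'
#' @param x Numeric vector (non-empty).
#' @param fs Sampling rate in Hz.
#' @return List of class `"SpectrumView"` with `xt` (complex FFT), `freqs`
#'   (signed bin frequencies), `fs` and `n`.
#' @export
spectrumView <- function(x, fs) {
  if (!length(x)) stop("cannot take the spectrum of an empty signal")
  structure(list(xt = fft(x), freqs = fftBinFrequencies(length(x), fs),
                 fs = fs, n = length(x)),
            class = "SpectrumView")
}

.retainedIndex <- function(n, fs, cutoff, mode = c("symmetric",
                                                   "positive_only")) {
  mode <- match.arg(mode)
  f <- fftBinFrequencies(n, fs)
  if (mode == "symmetric") abs(f) <= cutoff | seq_len(n) == 1L
  else f <= cutoff   # strict > cutoff deleted; negative bins always kept
}

#' Number of bins retained by frequency deletion
#'
#' @param n Input length.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (> 0); bins exactly at the cutoff
#'   are retained (strict `>` deletion).
#' @param mode `"symmetric"` (default, delete `|f| > cutoff`) or
#'   `"positive_only"` (delete `f > cutoff`, keep all negative bins).
#' @return Integer count `k`, `1 <= k <= n`.
#' @export
countRetainedBins <- function(n, fs, cutoff,
                              mode = c("symmetric", "positive_only")) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  sum(.retainedIndex(n, fs, cutoff, match.arg(mode)))
}

#' Frequency-deletion data reduction
#'
#' Deletes FFT bins above the cutoff and inverse-transforms the remaining
#' spectrum at its reduced length `k`, yielding a shorter series. In the
#' default `"symmetric"` mode the retained set is conjugate-symmetric, so
#' the real part loses nothing; `"positive_only"` deletes only
#' positive-frequency bins (keeping every negative bin). With
#' `normalize = TRUE` samples are rescaled by `k/n` so that DC amplitude
#' is preserved; the default leaves the standard length-`k` inverse
#' untouched.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (> 0).
#' @param mode Deletion mode (see [countRetainedBins()]).
#' @param normalize Logical, default `FALSE`.
#' @return List of class `"ReducedSignal"` with `samples` (real,
#'   length `k`), `k`, `n`, `cutoff`, `mode`, `normalize` and `fs`.
#' @examples
#' x <- rnorm(1000)                      # 10 s at 100 Hz
#' red <- filterFrequencies(x, fs = 100, cutoff = 2)
#' red$k                                 # 41 retained bins
#' @export
filterFrequencies <- function(x, fs, cutoff = 2,
                              mode = c("symmetric", "positive_only"),
                              normalize = FALSE) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!length(x)) stop("cannot filter an empty signal")
  n <- length(x)
  keep <- .retainedIndex(n, fs, cutoff, mode)
  xclean <- fft(x)[keep]
  k <- length(xclean)
  out <- Re(fft(xclean, inverse = TRUE)) / k
  if (normalize) out <- out * (k / n)
  structure(list(samples = out, k = k, n = n, cutoff = cutoff, mode = mode,
                 normalize = normalize, fs = fs),
            class = "ReducedSignal")
}
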