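# Shared fixtures and independent oracles. Expensive objects (cohorts,
# trained models) are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small separable cohort: 45 records per class, 10 s at 100 Hz, 10 dB SNR
smallCohort <- function() memo("smallCohort", {
  generateCohort(synthCohortSpec(nPerClass = 45, seed = 21, snrDb = 10))
})

smallSets <- function() memo("smallSets", {
  co <- smallCohort()
  imgs <- buildImageDataset(co$records, co$labels)
  splitImageSet(imgs, splitSpec(fraction = 1/3, seed = 21))
})

smallTrainConfig <- function(lr = 0.001, epochs = 10, seed = 21) {
  trainConfig(lr = lr, batchSize = 32, epochs = epochs,
              stepsPerEpoch = NULL, seed = seed)
}

smallFit <- function() memo("smallFit", {
  sets <- smallSets()
  trainModel(buildModel(cnnModelSpec(), seed = 21), sets$train,
             sets$validation, smallTrainConfig())
})

# independent periodized analysis oracle: plain convolution + downsampling
bruteDwt <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  vapply(seq_len(half) - 1L, function(k) {
    sum(f * x[((2L * k + 2L - (seq_along(f) - 1L)) %% n) + 1L])
  }, 0)
}

# independent straight-line re-implementation of the five denoising steps
bruteDenoise <- function(x, estimator = "median_abs_dev", rule = "hard",
                         bands = "both", useSqrt = TRUE) {
  filt <- waveletFilters("bior3.1")
  xp <- if (length(x) %% 2L == 1L) c(x, x[length(x)]) else x
  cA <- bruteDwt(xp, filt$decLo)
  cD <- bruteDwt(xp, filt$decHi)
  allc <- c(cA, cD)
  dev <- if (estimator == "median_abs_dev")
    median(abs(allc - median(allc))) else mean(abs(allc - mean(allc)))
  sigma <- dev / 0.6745
  thr <- if (useSqrt) sigma * sqrt(2 * log(length(x))) else
    sigma * 2 * log(length(x))
  sh <- if (rule == "soft") function(c) sign(c) * pmax(abs(c) - thr, 0) else
    function(c) ifelse(abs(c) > thr, c, 0)
  cA2 <- if (bands == "both") sh(cA) else cA
  cD2 <- sh(cD)
  n <- 2L * length(cA2)
  upA <- numeric(n); upA[seq(1L, n, 2L)] <- cA2
  upD <- numeric(n); upD[seq(1L, n, 2L)] <- cD2
  out <- numeric(n)
  for (i in seq_along(filt$recLo)) {
    idx <- ((seq_len(n) - 1L + 1L - (i - 1L)) %% n) + 1L
    out <- out + filt$recLo[i] * upA[idx] + filt$recHi[i] * upD[idx]
  }
  out[seq_along(x)]
}

# O(k^2) direct inverse DFT of the retained bins (independent of fft())
bruteFilterFrequencies <- function(x, fs, cutoff, mode = "symmetric") {
  n <- length(x)
  X <- vapply(0:(n - 1L), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1L)) / n))
  }, complex(1))
  idx <- c(0:((n - 1L) %/% 2L), -((n %/% 2L):1L))
  f <- idx * fs / n
  keep <- if (mode == "symmetric") abs(f) <= cutoff else f <= cutoff
  Xk <- X[keep]
  k <- length(Xk)
  Re(vapply(0:(k - 1L), function(t) {
    sum(Xk * exp(2i * pi * t * (0:(k - 1L)) / k)) / k
  }, complex(1)))
}

# denoising SNR improvement over the v1 lead of a cohort, in dB per record
snrImprovements <- function(cohort, config = denoiseConfig()) {
  vapply(cohort$records, function(r) {
    x <- selectLead(r, "v1")$samples
    cl <- cleanComponent(r, "v1")
    signalSnr(cl, denoiseSignal(x, config)$signal) - signalSnr(cl, x)
  }, 0)
}
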