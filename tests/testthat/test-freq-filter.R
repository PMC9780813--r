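test_that("spectra follow the standard FFT layout and invert exactly", {
  cst <- spectrumView(rep(3, 50), 100)
  expect_equal(Mod(cst$xt[1]), 150)
  expect_lt(max(Mod(cst$xt[-1])), 1e-10)
  imp <- spectrumView(c(1, numeric(7)), 8)
  expect_true(all(abs(imp$xt - 1) < 1e-12))
  sv <- spectrumView(rnorm(1000), 100)
  expect_equal(sv$freqs[2] - sv$freqs[1], 0.1)
  expect_equal(sv$freqs[21], 2.0)   # bin 20 (0-based) sits at 2 Hz
  expect_error(spectrumView(numeric(0), 100), "empty")
})

test_that("retained-bin counts match grid enumeration", {
  expect_equal(countRetainedBins(1000, 100, 2, "symmetric"), 41L)
  expect_equal(countRetainedBins(1000, 100, 2, "positive_only"), 521L)
  expect_equal(countRetainedBins(1000, 100, 50, "symmetric"), 1000L)
  # independent enumeration oracle over random grids
  set.seed(20)
  for (i in 1:40) {
    n <- sample(10:300, 1)
    fs <- runif(1, 20, 500)
    cutoff <- runif(1, 0.5, fs / 2)
    idx <- c(0:((n - 1) %/% 2), -((n %/% 2):1))
    f <- idx * fs / n
    expect_equal(countRetainedBins(n, fs, cutoff, "symmetric"),
                 sum(abs(f) <= cutoff))
    expect_equal(countRetainedBins(n, fs, cutoff, "positive_only"),
                 sum(f <= cutoff))
  }
  expect_error(countRetainedBins(100, 100, 0), "cutoff")
})

test_that("k is monotone in the cutoff and matches the output length", {
  x <- rnorm(200)
  ks <- vapply(c(1, 2, 5, 10, 20, 50),
               function(co) filterFrequencies(x, 100, co)$k, 0L)
  expect_true(all(diff(ks) >= 0))
  for (co in c(2, 7)) {
    r <- filterFrequencies(x, 100, co)
    expect_equal(r$k, countRetainedBins(200, 100, co))
    expect_length(r$samples, r$k)
  }
})

test_that("cutoff at or above Nyquist is the identity", {
  set.seed(21)
  x <- rnorm(500)
  r <- filterFrequencies(x, 100, 50)
  expect_equal(r$k, 500L)
  expect_lt(sqrt(mean((r$samples - x)^2)), 1e-9)
})

test_that("a pure tone above the cutoff is removed completely", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 10 * t)
  r <- filterFrequencies(x, 100, 2)
  expect_lt(sqrt(mean(r$samples^2)), 1e-9 * sqrt(mean(x^2)))
})

test_that("symmetric deletion of real input stays real", {
  set.seed(22)
  x <- rnorm(301)
  keep <- abs(fftBinFrequencies(301L, 100)) <= 7
  xc <- fft(x)[keep]
  resid <- Im(fft(xc, inverse = TRUE)) / length(xc)
  expect_lt(max(abs(resid)), 1e-9 * sqrt(mean(x^2)))
})

test_that("the reduced spectrum is exactly the retained source bins", {
  set.seed(23)
  t <- (0:499) / 50
  x <- sin(2 * pi * 1.5 * t) + sin(2 * pi * 12 * t) + rnorm(500, sd = 0.1)
  r <- filterFrequencies(x, 50, 3)
  # spectrum of the reduced series == source spectrum at the kept bins;
  # nothing above the cutoff survives because those bins no longer exist
  fsRed <- r$k / 10                # reduced series spans the same 10 s
  sp <- spectrumView(r$samples, fsRed)
  keep <- abs(fftBinFrequencies(500L, 50)) <= 3
  expect_equal(sp$xt, fft(x)[keep], tolerance = 1e-9)
  expect_lte(max(abs(sp$freqs)), 3)
  expect_equal(length(sp$freqs), r$k)
})

test_that("deletion equals the brute-force direct-DFT oracle", {
  set.seed(24)
  for (i in 1:12) {
    n <- sample(10:120, 1)
    fs <- runif(1, 10, 200)
    cutoff <- runif(1, fs / 20, fs / 2)
    mode <- sample(c("symmetric", "positive_only"), 1)
    x <- rnorm(n)
    got <- filterFrequencies(x, fs, cutoff, mode)$samples
    ref <- bruteFilterFrequencies(x, fs, cutoff, mode)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("normalization preserves DC amplitude", {
  x <- rep(4.2, 100) + c(0.1 * sin(2 * pi * 30 * (0:99) / 100))
  r <- filterFrequencies(x, 100, 2, normalize = TRUE)
  expect_lt(max(abs(r$samples - 4.2)), 1e-9)
})
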