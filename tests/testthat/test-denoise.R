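mkDecomp <- function(co) new("WaveletDecomposition", approx = co[1],
                             detail = co[2], wavelet = "bior3.1",
                             mode = "periodic", n = 2L)

test_that("decomposition matches the filter-bank convolution oracle", {
  set.seed(10)
  filt <- waveletFilters()
  for (n in c(16L, 1000L)) {
    x <- rnorm(n)
    d <- dwtDecompose(x)
    expect_length(d@approx, n %/% 2L)
    expect_equal(d@approx, bruteDwt(x, filt$decLo), tolerance = 1e-12)
    expect_equal(d@detail, bruteDwt(x, filt$decHi), tolerance = 1e-12)
  }
  z <- dwtDecompose(numeric(100))
  expect_true(all(z@approx == 0) && all(z@detail == 0))
  expect_error(dwtDecompose(c(1, 2)), "shorter than the wavelet filter")
})

test_that("round trip reconstruction is exact without thresholding", {
  set.seed(11)
  for (n in c(8L, 15L, 101L, 1000L)) {
    x <- rnorm(n)
    expect_lt(sqrt(mean((dwtReconstruct(dwtDecompose(x)) - x)^2)), 1e-10)
  }
})

test_that("sigma estimation divides the chosen deviation by 0.6745", {
  mk <- function(co) new("WaveletDecomposition",
                         approx = co[seq_len(length(co) / 2)],
                         detail = co[-seq_len(length(co) / 2)],
                         wavelet = "bior3.1", mode = "periodic",
                         n = length(co))
  expect_equal(estimateSigma(mk(numeric(8))), 0)
  d <- mk(c(0.6745, -0.6745, 0.6745, -0.6745))
  expect_equal(estimateSigma(d, "mean_abs_dev"), 1.0)
  set.seed(12)
  g <- mk(rnorm(10000, sd = 2))
  expect_lt(abs(estimateSigma(g, "median_abs_dev") - 2) / 2, 0.05)
})

test_that("universal threshold follows sigma * sqrt(2 ln n)", {
  expect_equal(computeThreshold(0, 500), 0)
  expect_equal(computeThreshold(1, 1), 0)
  expect_equal(computeThreshold(1, 1, useSqrt = FALSE), 0)
  expect_equal(computeThreshold(1, 1000), sqrt(2 * log(1000)))
  expect_equal(computeThreshold(1.5, 1000, useSqrt = FALSE),
               1.5 * 2 * log(1000))
  expect_error(computeThreshold(1, 0), "n")
})

test_that("thresholding rules match their elementwise definitions", {
  set.seed(13)
  x <- rnorm(64)
  d <- dwtDecompose(x)
  t0 <- thresholdCoeffs(d, 0, rule = "soft")
  expect_equal(t0@approx, d@approx)
  expect_equal(t0@detail, d@detail)
  soft <- thresholdCoeffs(d, 0.8, rule = "soft")
  expect_equal(soft@approx, sign(d@approx) * pmax(abs(d@approx) - 0.8, 0))
  expect_equal(soft@detail, sign(d@detail) * pmax(abs(d@detail) - 0.8, 0))
  hard <- thresholdCoeffs(d, 0.8, rule = "hard")
  expect_equal(hard@detail, ifelse(abs(d@detail) > 0.8, d@detail, 0))
  dOnly <- thresholdCoeffs(d, 0.8, rule = "hard", bands = "detail")
  expect_identical(dOnly@approx, d@approx)
  expect_error(thresholdCoeffs(d, -1), "threshold")
  # point values from the rule definition
  expect_equal(thresholdCoeffs(mkDecomp(c(5, -1.5)), 2, "soft")@approx[1], 3)
  expect_equal(thresholdCoeffs(mkDecomp(c(5, -1.5)), 2, "soft")@detail[1], 0)
})

test_that("soft thresholding is non-expansive and energy decreasing", {
  set.seed(14)
  d <- dwtDecompose(rnorm(200))
  prev <- c(d@approx, d@detail)
  for (thr in c(0.1, 0.5, 1, 2)) {
    cur <- thresholdCoeffs(d, thr, rule = "soft")
    cc <- c(cur@approx, cur@detail)
    expect_true(all(abs(cc) <= abs(prev) + 1e-15))
    expect_lte(sum(cc^2), sum(c(d@approx, d@detail)^2))
    prev <- cc
  }
})

test_that("the zero signal is a fixed point of the full pipeline", {
  out <- denoiseSignal(numeric(500))
  expect_equal(out$sigma, 0)
  expect_equal(out$threshold, 0)
  expect_true(all(out$signal == 0))
  expect_length(out$signal, 500L)
})

test_that("full pipeline equals the straight-line five-step oracle", {
  set.seed(15)
  x <- rnorm(512) + sin(2 * pi * (1:512) / 64)
  for (cfg in list(denoiseConfig(),
                   denoiseConfig(rule = "soft"),
                   denoiseConfig(estimator = "mean_abs_dev"),
                   denoiseConfig(bands = "detail", useSqrt = FALSE))) {
    got <- denoiseSignal(x, cfg)$signal
    ref <- bruteDenoise(x, cfg$estimator, cfg$rule, cfg$bands, cfg$useSqrt)
    expect_lt(sqrt(mean((got - ref)^2)), 1e-10)
    expect_length(got, length(x))
  }
})

test_that("denoising raises the SNR of noisy synthetic records", {
  r <- generateRecord(seed = 41, snrDb = 10)
  x <- selectLead(r, "v1")$samples
  cl <- cleanComponent(r, "v1")
  expect_gt(signalSnr(cl, denoiseSignal(x)$signal), signalSnr(cl, x))
})
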