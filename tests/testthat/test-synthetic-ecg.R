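test_that("noise-free generation is strictly periodic with the right length", {
  rec <- generateRecord(noise = noiseSpec(0, 0, 0, 0, 0), duration = 10,
                        fs = 100, seed = 1)
  v1 <- selectLead(rec, "v1")$samples
  expect_length(v1, 1000L)
  # 1 beat per second: ten identical cycles of 100 samples
  cycles <- matrix(v1, nrow = 100)
  for (j in 2:10) expect_equal(cycles[, j], cycles[, 1], tolerance = 1e-12)
})

test_that("identical spec and seed give bit-identical records", {
  a <- generateRecord(seed = 7)
  b <- generateRecord(seed = 7)
  expect_identical(signalMatrix(a), signalMatrix(b))
  d <- generateRecord(seed = 8)
  expect_false(identical(signalMatrix(a), signalMatrix(d)))
  expect_identical(dim(signalMatrix(a)), dim(signalMatrix(d)))
})

test_that("non-integral sample counts are rejected", {
  expect_error(generateRecord(duration = 10.3, fs = 33),
               "integer number of samples")
  expect_error(synthCohortSpec(nPerClass = 2, duration = 10.3, fs = 33),
               "integer number of samples")
})

test_that("SNR targeting hits the requested ratio on the analysis lead", {
  rec <- generateRecord(seed = 3, snrDb = 10)
  v1 <- match("v1", leadNames(rec))
  measured <- 10 * log10(mean(rec@components$clean[, v1]^2) /
                           mean(rec@components$noise[, v1]^2))
  expect_lt(abs(measured - 10), 0.5)
  # and the contaminated lead really is clean + noise
  expect_equal(signalMatrix(rec)[, v1],
               rec@components$clean[, v1] + rec@components$noise[, v1])
})

test_that("cohorts are balanced, labelled and deterministic", {
  spec <- synthCohortSpec(nPerClass = 5, seed = 3)
  co <- generateCohort(spec)
  expect_length(co$records, 10L)
  expect_equal(nrow(co$labels), 10L)
  expect_equal(as.vector(table(co$labels$class)), c(5L, 5L))
  expect_false(anyDuplicated(co$labels$record_id) > 0)
  co2 <- generateCohort(spec)
  expect_identical(signalMatrix(co$records[[3]]),
                   signalMatrix(co2$records[[3]]))
})

test_that("noise terms add power approximately independently", {
  pw <- function(n) {
    r <- generateRecord(noise = n, seed = 31)
    mean(selectLead(r, "v1")$samples^2)
  }
  p0 <- pw(noiseSpec(0, 0, 0, 0, 0))
  pbw <- pw(noiseSpec(0.075, 0.25, 0, 0, 0)) - p0
  ppl <- pw(noiseSpec(0, 0, 0.075, 50, 0)) - p0
  pwh <- pw(noiseSpec(0, 0, 0, 0, 0.025)) - p0
  ptot <- pw(noiseSpec())
  expect_lt(abs(ptot - (p0 + pbw + ppl + pwh)) / ptot, 0.01)
})

test_that("class contrast concentrates below 2 Hz", {
  co <- generateCohort(synthCohortSpec(nPerClass = 15, seed = 7))
  lead <- function(r) selectLead(r, "v1")$samples
  mN <- rowMeans(vapply(co$records[1:15], lead, numeric(1000)))
  mA <- rowMeans(vapply(co$records[16:30], lead, numeric(1000)))
  D <- Mod(fft(mA - mN))^2
  f <- abs(fftBinFrequencies(1000L, 100))
  expect_gt(sum(D[f <= 2]) / sum(D), 0.8)
})

test_that("zero separation makes the classes identical in distribution", {
  # same seed, both classes: with separation 0 the signals coincide exactly
  a <- generateRecord(classLabel = "NORM", seed = 5, separation = 0)
  b <- generateRecord(classLabel = "ASMI", seed = 5, separation = 0)
  expect_identical(signalMatrix(a), signalMatrix(b))
})

test_that("template validation rejects degenerate parameters", {
  expect_error(beatTemplate(widths = c(P = 0, Q = 0.01, R = 0.01,
                                       S = 0.01, T = 0.04)), "widths")
  expect_error(beatTemplate(period = 0.2), "period")
  expect_error(noiseSpec(bwAmp = -1), "amplitudes")
})
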