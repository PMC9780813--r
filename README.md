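# ecgspectro

Classification of single-lead ECG records via reduced spectrogram images,
for signal-processing and ML researchers working with PhysioNet-style
WFDB data. The package implements the full chain as tested R functions:

1. **Wavelet denoising** — single-level bior3.1 decomposition with
   periodized boundaries, noise level `σ̂ = dev(coeffs)/0.6745`, the
   universal threshold `T = σ̂·√(2 ln n)`, hard thresholding of both
   coefficient bands, exact inverse reconstruction.
2. **Frequency-deletion reduction** — FFT, *deletion* (not zeroing) of
   all bins with `|f| > 2 Hz`, inverse transform at the reduced length:
   a 10 s record at 100 Hz (1000 samples) collapses to 41 samples.
3. **Spectrogram imaging** — STFT with 9-point segments and FFTs,
   overlap ⌊9/2⌋ = 4, rendered as 64×64 8-bit grayscale PNGs without
   axes; a raw-signal line-plot raster is available as the comparison
   representation.
4. **Dataset assembly** — minority-class balancing by horizontal flip,
   mild contrast enhancement and seeded duplication; stratified
   train/validation splits.
5. **Compact CNN** — 64×64×1 input; four conv blocks (3×3, ReLU, bias,
   2×2 max-pool) with 64/128/256/64 filters and dropout 0.25 on blocks
   1, 3, 4; flatten; dense(8); dense(1, sigmoid) with an L1 activity
   regularizer. Unpadded convolutions give a 2×2×64 = 256-wide flattened
   feature and exactly **519,249 trainable parameters (0.52 M)**.
   Training is seeded Adam on binary cross-entropy, implemented
   in-package with RcppArmadillo convolution kernels.
6. **Synthetic two-class generator** — seeded lead-V1 beat model (P-QRS-T
   Gaussian bumps) plus baseline wander, powerline and white noise; the
   abnormal class differs only in a sub-2-Hz ST-like baseline offset, so
   class contrast survives the 2 Hz deletion. Everything downstream is
   testable with no external data.

WFDB format-16 `.hea`/`.dat` pairs (the 100 Hz PTB-XL dialect) are read
and written natively, and `parseLabels()` maps a `record_id`/`scp_codes`
metadata table to the binary ASMI/NORM labelling (records coded ASMI are
positive; every other record goes to NORM, with a `strictNorm` option to
keep only explicitly normal records).

## Worked example

```r
library(ecgspectro)

# 60 synthetic records (30 per class), 10 s at 100 Hz, 10 dB input SNR
cohort <- generateCohort(synthCohortSpec(nPerClass = 30, seed = 21,
                                         snrDb = 10))

# one record through the preprocessing chain
sel <- selectLead(cohort$records[[1]], "v1")
den <- denoiseSignal(sel$samples)
red <- filterFrequencies(den$signal, sel$fs, cutoff = 2)
c(input = length(sel$samples), reduced = red$k)
#>   input reduced
#>    1000      41

# images, split, train
imgs <- buildImageDataset(cohort$records, cohort$labels)
sets <- splitImageSet(imgs, splitSpec(fraction = 1/3, seed = 21))
fit <- trainModel(buildModel(cnnModelSpec(), seed = 21),
                  sets$train, sets$validation,
                  trainConfig(lr = 0.001, batchSize = 32, epochs = 6,
                              stepsPerEpoch = NULL, seed = 21))
fit$metrics
#> accuracy 1.0000 | sensitivity 1 | specificity 1 | precision 1 | loss 0.4611
#> confusion: TP 10 FP 0 TN 10 FN 0
```

The denoised, frequency-deleted record keeps only the DC bin and the
twenty 0.1 Hz-spaced bins on each side of it — the baseline content in
which the abnormal class encodes its ST-like offset — and the network
separates the two classes on the held-out third of the cohort. At
`separation = 0` the classes are identical in distribution and validation
accuracy stays at chance; the test suite asserts both behaviours, along
with the 519,249-parameter count, the 41-bin reduction, the STFT segment
arithmetic, and a ≥ 3 dB mean SNR gain from denoising at 10 dB input.

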