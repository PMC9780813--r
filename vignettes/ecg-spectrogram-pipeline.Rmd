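---
title: "From single-lead ECG to spectrogram images: the ecgspectro pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-lead ECG to spectrogram images: the ecgspectro pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgspectro)
```

## The problem

Anteroseptal myocardial infarction (ASMI) leaves a signature in the
*baseline* of the chest-lead ECG — ST-segment deviation and slow
repolarization changes — rather than in the sharp QRS deflections. This
package implements a classification pipeline built around that
observation: denoise the lead-V1 waveform, keep only the spectral content
at or below 2 Hz (discarding the bins *and their storage*, not merely
zeroing them), render the short-time Fourier transform of the reduced
series as a small grayscale image, and classify the images with a compact
convolutional network. Because the class signal is slow, aggressive
frequency deletion both shrinks the data and preserves separability.

The pipeline stages map onto the package functions as:

| Stage | Function(s) |
|---|---|
| Synthetic two-class records | `generateRecord()`, `generateCohort()` |
| WFDB format-16 input/output | `readRecord()`, `writeRecord()` |
| Lead selection, resampling | `selectLead()`, `resampleSignal()` |
| Wavelet denoising | `denoiseSignal()` and its step functions |
| Frequency deletion | `filterFrequencies()`, `countRetainedBins()` |
| Spectrogram images | `stftMatrix()`, `renderSpectrogram()`, `renderRawSignal()` |
| Dataset assembly | `balanceClasses()`, `splitImageSet()` |
| CNN | `buildModel()`, `trainModel()`, `evaluateModel()` |
| Experiment grid | `sweepLearningRates()`, `sweepSamplingRates()`, `compareRepresentations()` |

## Wavelet denoising

`denoiseSignal()` runs a five-step procedure on a single lead:

1. single-level discrete wavelet decomposition with the biorthogonal
   spline wavelet **bior3.1** and periodized boundaries
   (`dwtDecompose()`; the filter taps are exact multiples of
   $\sqrt2/8$, and reconstruction is exact to floating point);
2. noise-level estimation $\hat\sigma = \mathrm{dev}(c)/0.6745$ over the
   concatenated approximation and detail coefficients
   (`estimateSigma()`);
3. the universal (VisuShrink) threshold
   $T = \hat\sigma\sqrt{2\ln n}$ (`computeThreshold()`);
4. coefficient thresholding over both bands (`thresholdCoeffs()`);
5. inverse transform (`dwtReconstruct()`).

Two choices were genuinely open and deserve their rationale:

* **Thresholding rule — hard by default.** The procedure is described in
  the source material as *keeping only the coefficients whose magnitude
  exceeds the threshold*, which is hard thresholding. It is also the only
  self-consistent choice when the approximation band is thresholded: soft
  thresholding subtracts $T$ from *every* retained coefficient, which
  distorts the large approximation coefficients carrying the QRS complex
  and measurably lowers the output SNR instead of raising it. Soft
  shrinkage remains available (`rule = "soft"`), and is the sensible
  companion to `bands = "detail"`.
* **Deviation estimator — median-based by default.** The constant 0.6745
  is the Gaussian consistency factor of the *median* absolute deviation.
  A mean-based deviation over coefficients that still contain signal is
  badly inflated (the estimate tracks the QRS energy, not the noise
  floor), which drives the threshold far above the signal scale. The
  mean-based variant is kept as `estimator = "mean_abs_dev"`.

A `useSqrt = FALSE` flag reproduces the literal
$T = \hat\sigma\cdot 2\ln n$ variant, roughly 3.7× the universal
threshold for 1000-sample records; it zeroes essentially everything and
is provided for comparison only. The natural logarithm is used
throughout, and a single decomposition level is taken, matching the
procedure being implemented.

With the generator defaults (below), hard/median/both-bands denoising
gains 3–4 dB mean SNR on 10 dB-input cohorts; the dominant residual is
noise retained beneath the beats themselves, which a single-level
transform cannot reach without damaging the waveform.

## Frequency deletion

`filterFrequencies()` computes the FFT, *deletes* every bin above the
cutoff, and inverse-transforms the shortened spectrum at its reduced
length $k$, so a 1000-sample record at 100 Hz collapses to
$k = 41$ samples at the default 2 Hz cutoff (DC plus 20 bins on each
side at 0.1 Hz spacing). Design points:

* the default `symmetric` mode deletes $|f| > f_c$; the retained set is
  conjugate-symmetric and the inverse is real. The `positive_only`
  mode (delete only $f > f_c$, keep all negative bins, $k = 521$ for the
  canonical grid) reproduces a literal reading of the deletion predicate
  and yields a complex series whose real part is taken;
* the comparison is strict, so bins exactly at the cutoff survive; bin
  frequencies are computed as `index * fs / n` to keep grid frequencies
  exact in floating point;
* the standard length-$k$ inverse leaves amplitudes scaled by $n/k$
  relative to the input; `normalize = TRUE` rescales by $k/n$ so DC
  amplitude is preserved. The default leaves it untouched, since the
  later min–max image normalization absorbs any global gain.

## Spectrograms and rasters

`stftMatrix()` slides a 9-sample window (Hann by default; rectangular
available, and pinned by a Parseval identity in the tests) with overlap
$\lfloor 9/2\rfloor = 4$, i.e. step 5, and stores two-sided FFT
magnitudes; the segment count is
$\lfloor (L-9)/5\rfloor + 1$ (7 segments for the 41-sample reduced
series). `renderSpectrogram()` converts to dB
($10\log_{10}(m^2+10^{-12})$; linear optional), min–max normalizes to
0–255, orients low frequencies to the bottom row, and resizes to 64×64
by nearest neighbour (deterministic across platforms; bilinear behind a
flag). A constant matrix has no dynamic range and maps to mid-gray 128.
`renderRawSignal()` rasterizes the denoised waveform as a dark polyline
on a light 64×64 ground with an exactly mirror-symmetric value-to-row
mapping; a constant series degenerates to a two-pixel middle line.
No axes, margins or labels appear in either raster.

## The synthetic cohort

The generator exists so that every stage, including training, is testable
without downloads. One cardiac cycle is a sum of Gaussian bumps with
lead-V1 morphology — small P (0.05 mV), rS complex (r 0.25 mV, S
−1.0 mV), small inverted T (−0.15 mV) — repeated strictly periodically at
60 bpm, projected onto 12 leads through fixed gains. Noise defaults are
wander-and-mains dominated, as in raw surface ECG: sinusoidal baseline
wander 0.075 mV at 0.25 Hz, powerline 0.075 mV at 50 Hz, white noise
0.025 mV. The `snrDb` argument rescales the clean component so the
**analysis lead** hits an exact input SNR.

The abnormal class adds a per-beat ST-segment pedestal: a wide Gaussian
bump (σ = 0.08 s) centred 0.15 s after the R wave, 0.2 mV at
`separation = 1` — the guideline ST-elevation magnitude for the anterior
chest leads. Its width keeps over 90 % of the pedestal's harmonic energy
at or below 2 Hz, so the class contrast deliberately survives the
frequency deletion; `separation = 0` makes the two classes exactly
identical in distribution. What the generator does **not** emulate:
heart-rate variability, beat-to-beat morphology changes, electrode
artifacts, pathologies other than an ST-type offset, and inter-patient
morphology variation. Passing tests therefore demonstrate pipeline
correctness and end-to-end learnability of a baseline-coded class signal,
not clinical performance on real records.

## The classifier

`cnnModelSpec()` describes the fixed architecture: 64×64×1 input, four
convolutional blocks of 64/128/256/64 filters (3×3 kernels with biases,
ReLU, 2×2 max pooling; dropout 0.25 on blocks 1, 3 and 4), flatten,
dense(8, ReLU), dense(1, sigmoid) with an L1 activity regularizer
(coefficient 1e-4 by default; it does not change the parameter count).
With unpadded convolutions the feature map shrinks
64→62→31→29→14→12→6→4→2, the flattened feature has 2·2·64 = 256
elements, and `countParameters()` gives exactly **519,249** (0.52
million) — the same-padding alternative gives 525,393, which is why
`"valid"` is the default. The realized weight tensors always sum to the
closed-form count; a property test sweeps specs and paddings to pin this.

Training is seeded mini-batch Adam on binary cross-entropy, written
in-package (the convolution and pooling inner loops are compiled via
RcppArmadillo and dispatch to BLAS; backpropagation is verified against
central finite differences in the tests). All randomness — weight
initialization, shuffling, dropout, splits — flows through explicit
seeds, and training is bit-reproducible on a given BLAS. The reference
configuration (batch 256, 500 epochs, 10 steps per epoch, lr 0.001) is
kept as the documented `trainConfig()` default; tests and the desk-scale
experiments train 200 images for up to 30 epochs at batch 32, sizes
chosen so the whole experiment grid runs comfortably on a laptop-class
single core. A sigmoid threshold of 0.5 assigns classes; metrics with a
zero denominator are reported as `NA` rather than 0.

## Experiments at desk scale

`sweepLearningRates()` and `sweepSamplingRates()` vary exactly one factor
with everything else (data, seeds, architecture) held fixed;
`compareRepresentations()` trains the spectrogram arm and the raw-signal
arm on identical record sets and measures both accuracy and on-disk PNG
bytes. On the synthetic cohort the expected qualitative pattern — coarse
learning rates (0.1) underperform 0.001, and sub-2 Hz class contrast
survives 25 Hz resampling — is asserted by the tests. On-disk bytes of
the two synthetic image datasets come out within roughly 10 % of each
other: both rasters are tiny deterministic 64×64 PNGs whose size tracks
raster entropy rather than underlying sample count, so the large
real-data size gap between representations does not reproduce at this
scale. Corpus-scale accuracy figures likewise require
the external PTB-XL corpus, for which the WFDB reader, `parseLabels()`
(with its verbatim "rest→NORM" rule and a `strictNorm` escape hatch) and
the full-run training defaults are provided.

## Numerical and degenerate-input policy

* Odd-length signals are decomposed by repeating the final sample once;
  reconstruction trims back, preserving exactness.
* Empty signals, unknown leads, malformed WFDB headers, truncated signal
  files, non-binary labels and out-of-range fractions are rejected with
  specific messages rather than propagated.
* The dB conversion uses ε = 1e-12 under the logarithm; min–max
  normalization of a constant image maps to 128.
* Contrast augmentation rounds half away from zero and clips to 0–255;
  its default gain 1.2 is intentionally mild so augmented copies stay
  close to their originals, and augmented items derive only from
  original minority images, never from other augmented copies.
* `balanceClasses()` never removes items and never touches the majority
  class; the deficit fills as flips, then contrast copies (each stage
  capped by the number of minority originals), then seeded duplicates.
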