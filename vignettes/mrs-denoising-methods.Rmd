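---
title: "Methods: simulating, corrupting and denoising 1H-MRS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, corrupting and denoising 1H-MRS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
decisions behind `mrsdenoise` — the things a maintainer or a sceptical
reviewer would want written down. It states no measured results; the
package's tests and `scripts/acceptance.R` compute those.

## 1. Clean-spectrum model

A metabolite is represented by a peak table: integer peak labels, chemical
shifts in ppm, and relative intensities (max-referenced to 1000, the
convention of metabolome-database exports). A clean spectrum is the
intensity-weighted sum of Voigt profiles on a uniform grid — by default
1024 points spanning 0–10 ppm, the physiologically relevant ¹H range, at a
spectrometer frequency of 63.885 MHz (a 1.5 T clinical system), giving a
spectral width of 638.85 Hz.

The Voigt profile (Gaussian ⊛ Lorentzian) has no elementary closed form;
it is evaluated through the real part of the Faddeeva function
`w(z) = exp(-z²)·erfc(-iz)` with `z = (x + iγ)/(σ√2)`. We implement `w`
with Weideman's rational approximation (36 terms, accurate to ~1e-12 on
the upper half-plane); the degenerate cases σ = 0 and γ = 0 fall back to
the exact Lorentzian and Gaussian densities. A brute-force numerical
convolution of the two densities serves as the independent oracle in the
test suite (agreement to 1e-4 relative).

Default linewidths are `gauss_width = lorentz_width = 0.005` ppm. At the
canonical grid spacing of ~0.0098 ppm this yields lines a few bins wide —
comparable to what a well-shimmed low-field spectrum shows — while keeping
all 14 cholesterol resonances resolvable. Both widths are per-call
arguments, not constants.

Normalization is global min–max to [0, 1]. A constant spectrum maps to
all zeros with a warning rather than an error: inside a batch augmentation
loop a degenerate draw should be survivable. Peaks outside the grid are
skipped with a message (database exports can list resonances beyond
10 ppm); an empty table is an error.

## 2. The cholesterol reference bundle

`cholesterol_reference()` returns the 14 characteristic cholesterol ¹H
resonances (HMDB entry 2491; 0.678–5.35 ppm). Six entries carry positions
(and, for the dominant peak, the intensity 1000) quoted in the published
assignment summary: peaks 1 and 3 at 0.678 and 0.876 ppm, peak 5 at
1.007 ppm, peak 9 at 1.854 ppm, peak 13 at 3.5 ppm and peak 14 at
5.35 ppm. The complete appendix table is not publicly printed, so the
remaining eight entries are placeholders placed inside the stated region
for their peak group (e.g. peaks 6–8 in 1.1–1.5 ppm) with plausible
intensities; each row's `provenance` column says `printed` or
`placeholder`. The olefinic resonance is variously quoted as 5.348, 5.35
and 5.356 ppm; the bundle stores 5.35. Conclusions that depend on the
placeholder rows (e.g. the exact number of matched peaks) should be read
with that provenance in mind.

## 3. FID synthesis and the noise model

Each clean spectrum is treated as a zero-phase absorptive-mode signal and
inverse-Fourier-transformed into a complex synthetic FID. Conventions,
none of which are physically observable but all of which must be fixed:

* orthonormal DFT scaling (1/√N both ways), so Parseval's identity holds
  with no extra factors and time/frequency powers can be compared
  directly;
* time axis `t_k = k·dwell`, `dwell = 1/spectral_width` (638.85 Hz ⇒
  1.565 ms) — the standard NMR sampling convention;
* zero-fill factor 2 by default when returning to the frequency domain
  (the factor is configuration, {1, 2, 4}); the finer spectrum is linearly
  resampled back onto the canonical 1024-point grid so every downstream
  array has the same shape. With no perturbation the round trip is the
  identity to ~1e-11.

Corruption stages, in pipeline order:

1. **Apodization** `FID(t)·e^(−π·LB·t)`, LB drawn uniformly from
   0.5–3 Hz. This broadens every line by LB Hz (FWHM) — the Lorentzian
   line-broadening real acquisitions show; the tests verify the FWHM
   growth against an FFT linewidth fit.
2. **Thermal noise**: independent zero-mean Gaussians on the real and
   imaginary channels with per-channel variance σ² = P_signal/(2·SNR),
   P_signal = mean |FID|², SNR drawn uniformly from 5–15 dB (linear
   ratio). The total injected complex-noise power is then P_signal/SNR,
   i.e. the FID-domain SNR equals the target exactly in expectation — the
   convention the variance formula implies. Note that on the *retained
   real part* of the spectrum the measured SNR is ~3 dB above target,
   because discarding the imaginary channel discards half the circular
   noise power; the tests therefore check the FID-domain quantity.
3. **Pink (1/f) noise**, synthesized in the frequency domain (magnitude
   ∝ 1/√f, uniform random phases, DC bin zeroed since 1/f diverges at
   f = 0) and inverse-transformed to give correlated temporal drift;
   independent processes on the two channels, each scaled to 0.5× the
   thermal σ.
4. Back to the frequency domain; the real part is kept.
5. **Baseline**: a random polynomial of degree ≤ 3 ("low-order", emulating
   B₀-inhomogeneity curvature) rescaled so its maximum magnitude is a
   uniform draw up to 10% of the spectrum maximum, plus Gaussian-smoothed
   white noise (width 25 bins, up to 5%) for slow undulating drift. The
   spec of the configuration object lists a single baseline amplitude; we
   expose the drift cap as its own field (`drift_amplitude`) so either
   term can be switched off independently — needed both for testing and
   for ablations.
6. **RF spikes**: 0–3 single-bin impulses at uniformly drawn positions,
   amplitudes 5–20% of the spectrum maximum, applied in the frequency
   domain (transient interference appears as narrow spectral features).
7. Min–max normalization.

The paired training target is the min–max-normalized clean spectrum,
untouched by every noise stage.

The SNR/LB/amplitude ranges above are implementer choices (the underlying
ranges are not published); they were fixed once, before any benchmarking,
to produce spectra that look like low-field in vivo acquisitions —
visible noise floor, wandering baseline, occasional interference — while
leaving the denoising task learnable. They are all fields of
`noise_config()`.

**What the generator does not emulate:** J-coupling multiplets,
macromolecular background humps, water/solvent residuals, coil-loading
and eddy-current effects, frequency drift between averages, and
phase errors (the zero-phase assumption is baked in). Passing the
package's tests therefore demonstrates correct recovery under *this*
noise family, not performance on real scanner data; transfer to measured
FIDs is explicitly out of scope.

**Seeding.** Every stochastic function takes a seed and restores the
caller's RNG state. Dataset builds derive one seed per (table, variant)
pair from the master seed via a MINSTD-style modular hash (exact in
doubles, always a valid 32-bit seed), so a dataset is bit-reproducible
and insensitive to generation order.

## 4. The 1D U-Net

Architecture (defaults; all in `unet_config()`): three encoder levels of
two Conv1D+ReLU layers each (kernel 9, 'same' zero padding, channels 16 →
32 → 64), factor-2 max-pooling between levels, a two-conv 128-channel
bottleneck, and a symmetric decoder using factor-2 linear-interpolation
upsampling, skip concatenation with the matching encoder output, and two
Conv1D+ReLU layers per level; a final kernel-1 linear convolution projects
to one channel. Input length must be divisible by 2³ (1024 is). The
published description fixes the depth, the paired Conv1D–ReLU structure
and the skip connections; channel widths, kernel size, padding and the
pooling/upsampling operators are unstated, so the defaults above were
chosen as the smallest configuration that trains stably at this problem
size, and all are configurable.

Training (`train_config()`): Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8),
learning rate 1e-3, batch 32, MSE loss with MAE monitored, 15% validation
split, 150 epochs by default. The published account is ambiguous about
whether MAE was optimized or merely monitored, and reports both "150
epochs" and "80 epochs" in different places; we optimize MSE only and
default to 150, with the count configurable (the desk-scale benchmark
uses 30). The returned model carries the weights of the epoch with the
best validation MSE, not the last epoch. Weight init is He-scaled
Gaussian; init, split and shuffling all derive from the training seed, so
training is bit-reproducible.

There is no deep-learning runtime in the dependency stack: forward,
backpropagation and the optimizer are implemented in RcppArmadillo, with
each 'same'-padded convolution lowered to k accumulated single-precision
BLAS GEMM calls on shifted column ranges (no im2col buffer). Analytic
gradients are verified against finite differences in the test suite; the
finite-difference check for biases runs in a regime where all rectifiers
are active, because at a ReLU kink the loss is only piecewise smooth and
central differences are not trustworthy. Inference is deterministic;
single-precision arithmetic bounds reproducibility across BLAS builds,
while within one build results are bit-identical.

## 5. Classical baselines and metrics

The four comparison filters use the published parameters as defaults:
Gaussian kernel smoothing σ = 1.5 bins (truncation radius ⌈4σ⌉,
reflection at the boundaries, kernel normalized to unit sum);
Savitzky–Golay window 21, order 3 (via `signal::sgolayfilt`, polynomial
fits truncated at the edges); sliding median, kernel 5 (reflection
padding); and db4 wavelet shrinkage at decomposition level 3 with soft
thresholding. No R wavelet package is in the dependency stack, so the
periodized db4 filter bank is implemented directly and cross-checked
against reference coefficients in the tests. The threshold magnitude is
unpublished; we use the universal threshold T = σ̂·√(2·ln N) with σ̂ =
median |finest detail| / 0.6745, the standard soft-shrinkage choice,
applied with the same T at every level.

Metrics, computed per spectrum against the normalized clean reference:
SNR = 10·log₁₀(mean(clean²)/mean((est−clean)²)); PSNR with MAX = 1; SSIM
in its *global-statistics* form (population moments over the whole
1024-point signal, k₁ = 0.01, k₂ = 0.03, L = 1 — the printed formula, not
a sliding window); RMSE; MAE; Pearson r. A zero residual would make
SNR/PSNR infinite, so both are capped at 300 dB to keep aggregation
finite. Pearson correlation on a zero-variance signal is an error, not a
silent NA. Paired t-tests are two-sided with the spectrum as the pairing
unit and no multiple-testing correction (the published comparison reports
raw p-values); a comparison whose per-spectrum differences are all equal
is flagged degenerate and reported as p = 1.

One consequence of the pipeline worth stating: because noisy spectra are
min–max normalized *after* baseline and spikes are added, their affine
scale differs from the clean target's, and a filter that only smooths
(all four classical baselines) cannot correct that offset — their error
is dominated by the baseline/scale mismatch, while the U-Net learns to
remove it. This mirrors the published pipeline's preprocessing and is the
main reason the gap between the U-Net and the classical methods is as
large as it is on this benchmark.

## 6. Peak identification

Detection: local maxima with topographic prominence at least a fraction
(default 1%) of the spectrum maximum, position refined by three-point
parabolic interpolation (sub-bin accuracy; the refined apex of an
isolated Voigt line lands well within half a grid bin). Matching to a
reference table is greedy nearest-neighbour on |Δppm| with both sides
used at most once and pairs kept only within the tolerance (default
0.05 ppm ≈ 5 grid bins — tight enough to separate all distinct reference
assignments, loose enough for interpolation error). Ties break toward
smaller ppm; at these peak spacings greedy and optimal assignment
coincide, and greedy is auditable. Shrinking the tolerance can only
remove matches (tested property). Peaks closer than about two linewidths
can merge into one detected apex, which is why the recovery contract for
the 14-peak reference is "at least 12" rather than all 14 at arbitrary
widths.

## 7. Problem sizes and reproducibility

The package's desk-scale benchmark — used by both the acceptance script
and the heavyweight test — builds 2000 training pairs and 50 holdout
pairs from the cholesterol table at the default noise configuration and
trains for 30 epochs: sizes chosen so a complete from-scratch run
(simulate → corrupt → train → benchmark → test) finishes in roughly a
quarter of an hour on a single CPU while still training the full-size
default architecture on full-length spectra. All quantities reported by
`scripts/acceptance.R` are recomputed at run time from the `--seed`
argument; nothing is cached or looked up.

## 8. Known limitations

* Single-metabolite training data (the bundled cholesterol table) makes
  the mapping close to a prototype-restoration task; the framework
  accepts arbitrary lists of peak tables, but the shipped benchmark does
  not probe multi-metabolite generalization.
* Eight of the 14 reference entries are documented placeholders
  (section 2).
* The noise family omits the structured artifacts listed in section 3;
  no claim is made about real scanner FIDs.
* The wavelet baseline's threshold policy (universal, per-level, soft) is
  one defensible reading of an under-specified method; other choices
  would shift that baseline's numbers.
* SSIM here is the global form; windowed SSIM implementations will give
  different values on the same signals.
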