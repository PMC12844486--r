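# mrsdenoise

Deep-learning denoising for proton magnetic-resonance spectroscopy
(¹H-MRS), end to end in R: simulate clean metabolite spectra from peak
lists, corrupt them with a physics-motivated noise model in the FID (time)
domain, train a 1D U-Net to map noisy spectra back to clean ones, benchmark
it against four classical filters, and identify cholesterol resonances in
denoised spectra by chemical-shift matching.

The package targets spectroscopists and methods researchers who want a
fully reproducible, desk-scale testbed for MRS denoising — for example for
low-field (1.5 T) spectra of atherosclerotic plaque lipids, where faint
cholesteryl-ester resonances sit at or below the noise floor.

## The model in brief

**Clean spectra.** A metabolite peak list {(δᵢ, Iᵢ)} is rendered on a
1024-point grid over 0–10 ppm as a sum of Voigt lineshapes,

  S(δ) = Σᵢ Iᵢ · V(δ − δᵢ; σ, γ),  V = Gaussian(σ) ⊛ Lorentzian(γ),

evaluated through the Faddeeva function, then min–max normalized to [0, 1].

**Noise model.** Each clean spectrum is treated as a zero-phase absorptive
signal; its inverse DFT gives a synthetic FID. Corruption happens where the
physics happens: exponential apodization FID(t)·e^(−π·LB·t) (line
broadening LB in Hz), complex Gaussian thermal noise with per-channel
variance σ² = P_signal/(2·SNR) at a target SNR drawn from 5–15 dB, and pink
(1/f) drift noise. The perturbed FID is Fourier-transformed back
(zero-filled), and the real part receives a random polynomial-plus-drift
baseline and transient single-bin RF spikes before renormalization.

**Denoiser.** A 1D U-Net: three encoder levels of paired Conv1D+ReLU
(16→32→64 channels, kernel 9) with factor-2 max-pooling, a 128-channel
bottleneck, and a symmetric decoder with linear-interpolation upsampling
and skip concatenations (1024→512→256→128 and back). Trained with Adam on
MSE over paired (noisy, clean) spectra; MAE is monitored alongside. The
network (forward, backpropagation, optimizer) is implemented natively in
RcppArmadillo on single-precision BLAS — no deep-learning runtime is
required.

**Evaluation.** Six metrics against the clean reference — SNR, PSNR,
global-statistics SSIM, RMSE, MAE, Pearson r — plus two-sided paired
t-tests of the U-Net against Gaussian smoothing (σ = 1.5), Savitzky–Golay
(window 21, order 3), sliding median (kernel 5) and db4 level-3
soft-threshold wavelet shrinkage.

## Worked example

```r
library(mrsdenoise)

## clean cholesterol spectrum from the bundled 14-peak reference table
grid  <- make_grid(1024, 0, 10, 63.885)
clean <- peaks_to_spectrum(cholesterol_reference(), grid)
grid_axis(grid)[which.max(clean$values)]
#> [1] 1.006843        # the dominant aliphatic envelope at ~1.007 ppm

## paired training data: 2000 noisy variants at the default noise config
train_data <- build_dataset(cholesterol_reference(), 2000,
                            noise_config(seed = 101))
holdout    <- build_dataset(cholesterol_reference(), 50,
                            noise_config(seed = 202))

## train the default 3-level U-Net for 30 epochs (~12 min on one CPU)
model <- train_denoiser(build_model(seed = 7), train_data,
                        train_config(epochs = 30, seed = 7))
min(model$history$val_mse)
#> [1] 9.529342e-06    # validation MSE at the selected epoch

## benchmark against the four classical filters
bm <- benchmark_methods(holdout, model)
bm
#> <mrs_benchmark> mean metrics over 50 spectra:
#>          method snr_db psnr_db    ssim     rmse      mae pearson_r
#>            unet 25.662   50.89 0.99797 0.003172 0.001446    0.9980
#>        gaussian -8.964   16.26 0.11018 0.161718 0.154372    0.7375
#>  savitzky_golay -9.138   16.09 0.09262 0.164233 0.155368    0.5988
#>          median -8.887   16.34 0.11209 0.160699 0.153552    0.7446
#>         wavelet -8.947   16.28 0.11112 0.161637 0.154203    0.7366

max(paired_ttests(bm)$p_value[paired_ttests(bm)$method != "unet"])
#> [1] 1.466947e-26    # U-Net better on every metric, p << 0.01

## identify cholesterol peaks in a denoised spectrum
noisy    <- new_spectrum(holdout$noisy[1, ], grid, "noisy", normalized = TRUE)
denoised <- denoise(model, noisy)
match_to_reference(detect_peaks(denoised, 0.01), cholesterol_reference())
```

(The numbers shown are from a run with master seed 1; other seeds give
closely similar values.)

A thin command-line interface over the same functions ships in
`inst/cli/mrsdenoise` (subcommands `simulate`, `augment`, `train`,
`denoise`, `baseline`, `evaluate`, `match-peaks`).

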