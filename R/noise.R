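#' Stochastic-corruption configuration
#'
#' Bundles every parameter of the noise model used to manufacture noisy
#' variants of clean spectra. Defaults emulate a low-field in vivo-like
#' acquisition: thermal SNR drawn from 5--15 dB, 0.5--3 Hz exponential line
#' broadening, pink (1/f) drift at half the thermal noise scale, a low-order
#' polynomial baseline plus smoothed stochastic drift of up to 10% / 5% of
#' the signal maximum, and 0--3 single-bin RF spikes of up to 20% of the
#' signal maximum.
#'
#' @param target_snr_db Length-2 range (dB) from which each variant's
#'   thermal SNR target is drawn uniformly.
#' @param lb_range_hz Length-2 range (Hz) of exponential line broadening.
#' @param pink_amplitude Pink-noise scale, as a multiple of the thermal
#'   noise standard deviation.
#' @param baseline_order Maximum random-polynomial degree (>= 0).
#' @param baseline_amplitude Polynomial baseline cap, fraction of signal max.
#' @param drift_amplitude Smoothed stochastic drift cap, fraction of signal
#'   max.
#' @param drift_smoothing Gaussian smoothing width of the stochastic drift,
#'   in grid bins.
#' @param spike_count_range Integer range of RF spike counts per spectrum.
#' @param spike_amplitude_range Spike amplitude range, fraction of signal
#'   max.
#' @param zero_fill_factor Zero-fill factor used when transforming the
#'   perturbed FID back to the frequency domain (1, 2 or 4).
#' @param seed Master RNG seed recorded in every dataset manifest.
#' @return An object of class `mrs_noise_config`.
#' @export
noise_config <- function(target_snr_db = c(5, 15),
                         lb_range_hz = c(0.5, 3),
                         pink_amplitude = 0.5,
                         baseline_order = 3L,
                         baseline_amplitude = 0.1,
                         drift_amplitude = 0.05,
                         drift_smoothing = 25,
                         spike_count_range = c(0L, 3L),
                         spike_amplitude_range = c(0.05, 0.2),
                         zero_fill_factor = 2L,
                         seed = 1L) {
  rng2 <- function(x, name, lower = -Inf, allow_inf = FALSE) {
    if (length(x) == 1L) x <- c(x, x)
    finite_ok <- if (allow_inf) !any(is.na(x)) else all(is.finite(x))
    if (length(x) != 2L || !finite_ok || x[1] > x[2] || x[1] < lower) {
      stop_invalid("`", name, "` must be a range [lo, hi] with lo <= hi",
                   if (is.finite(lower)) paste0(" and lo >= ", lower))
    }
    as.numeric(x)
  }
  cfg <- list(
    # +Inf switches thermal noise off entirely (identity-pipeline testing)
    target_snr_db = rng2(target_snr_db, "target_snr_db", allow_inf = TRUE),
    lb_range_hz = rng2(lb_range_hz, "lb_range_hz", lower = 0),
    pink_amplitude = check_number(pink_amplitude, "pink_amplitude", lower = 0),
    baseline_order = as.integer(check_number(baseline_order, "baseline_order",
                                             lower = 0)),
    baseline_amplitude = check_number(baseline_amplitude, "baseline_amplitude",
                                      lower = 0),
    drift_amplitude = check_number(drift_amplitude, "drift_amplitude",
                                   lower = 0),
    drift_smoothing = check_number(drift_smoothing, "drift_smoothing",
                                   lower = 0),
    spike_count_range = as.integer(rng2(spike_count_range,
                                        "spike_count_range", lower = 0)),
    spike_amplitude_range = rng2(spike_amplitude_range,
                                 "spike_amplitude_range", lower = 0),
    zero_fill_factor = as.integer(zero_fill_factor),
    seed = as.integer(seed)
  )
  structure(cfg, class = "mrs_noise_config")
}

#' Add complex Gaussian thermal noise to an FID at a target SNR
#'
#' Noise variance is scaled to the clean FID power: each of the real and
#' imaginary channels receives independent zero-mean Gaussian noise of
#' variance `sigma^2 = P_signal / (2 * SNR)` with
#' `P_signal = mean(|samples|^2)`, so the total injected complex noise power
#' is `P_signal / SNR` and the FID-domain SNR equals the target exactly in
#' expectation.
#'
#' @param fid An `mrs_fid`.
#' @param target_snr_linear Target SNR as a linear power ratio (> 0).
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return The noisy `mrs_fid`.
#' @export
thermal_noise <- function(fid, target_snr_linear, seed = NULL) {
  stopifnot(inherits(fid, "mrs_fid"))
  check_number(target_snr_linear, "target_snr_linear", lower = 0, strict = TRUE)
  n <- length(fid$samples)
  p_signal <- mean(Mod(fid$samples)^2)
  sigma <- sqrt(p_signal / (2 * target_snr_linear))
  noise <- with_seed(seed, complex(real = rnorm(n, sd = sigma),
                                   imaginary = rnorm(n, sd = sigma)))
  out <- fid
  out$samples <- fid$samples + noise
  out
}

#' Complex pink (1/f) noise
#'
#' Synthesized in the frequency domain with magnitude proportional to
#' `1/sqrt(f)` (so power spectral density ~ 1/f) and uniform random phases,
#' then inverse-transformed to give correlated temporal fluctuations. The DC
#' bin is zeroed (1/f diverges at f = 0) and each channel is centred and
#' rescaled, so real and imaginary parts are independent pink processes of
#' standard deviation `amplitude`.
#'
#' @param n Number of samples (>= 2).
#' @param amplitude Per-channel standard deviation (>= 0).
#' @param seed Optional seed.
#' @return Complex vector of length `n`.
#' @export
pink_noise <- function(n, amplitude, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(amplitude, "amplitude", lower = 0)
  n <- as.integer(n)
  if (amplitude == 0) return(complex(real = rep(0, n)))
  with_seed(seed, {
    channel <- function() {
      nf <- (n - 1L) %/% 2L
      X <- complex(real = rep(0, n))
      mag <- 1 / sqrt(seq_len(nf))
      ph <- runif(nf, 0, 2 * pi)
      X[2L:(nf + 1L)] <- mag * exp(1i * ph)
      X[n + 1L - seq_len(nf)] <- Conj(X[2L:(nf + 1L)])
      if (n %% 2L == 0L) X[n / 2L + 1L] <- rnorm(1) / sqrt(n / 2)
      x <- Re(stats::fft(X, inverse = TRUE)) / n
      x <- x - mean(x)
      x * amplitude / stats::sd(x)
    }
    re <- channel()
    im <- channel()
    complex(real = re, imaginary = im)
  })
}

#' Random smooth baseline: polynomial plus smoothed stochastic drift
#'
#' Sum of (a) a random polynomial of degree <= `baseline_order` whose
#' coefficients are rescaled so its maximum absolute value is a uniform draw
#' in `[0, baseline_amplitude]`, emulating B0-inhomogeneity curvature, and
#' (b) Gaussian-smoothed white noise (smoothing width `drift_smoothing`
#' bins) rescaled so its maximum absolute value is a uniform draw in
#' `[0, drift_amplitude]`, emulating slow undulating drifts.
#'
#' Amplitudes here are fractions; callers scale by the signal maximum.
#'
#' @param grid An `mrs_grid` (sets the length).
#' @param config An [noise_config()].
#' @param seed Optional seed.
#' @return Numeric vector of length `grid$n_points`.
#' @export
baseline_drift <- function(grid, config, seed = NULL) {
  stopifnot(inherits(grid, "mrs_grid"), inherits(config, "mrs_noise_config"))
  n <- grid$n_points
  with_seed(seed, {
    x <- seq(-1, 1, length.out = n)
    poly <- numeric(n)
    if (config$baseline_amplitude > 0) {
      coefs <- runif(config$baseline_order + 1L, -1, 1)
      p <- numeric(n)
      for (c_k in coefs) p <- p * x + c_k
      peak <- max(abs(p))
      if (peak > 0) poly <- p * runif(1, 0, config$baseline_amplitude) / peak
    }
    drift <- numeric(n)
    if (config$drift_amplitude > 0 && config$drift_smoothing > 0) {
      w <- rnorm(n)
      drift <- gaussian_smooth(w, config$drift_smoothing)
      peak <- max(abs(drift))
      if (peak > 0) drift <- drift * runif(1, 0, config$drift_amplitude) / peak
    }
    poly + drift
  })
}

## Gaussian smoothing with reflected boundaries (kernel radius 4 sigma).
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  reflect_filter(x, k)
}

## Convolve with a centred kernel under reflect padding.
reflect_filter <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
  out <- stats::convolve(pad, rev(kernel), type = "filter")
  # convolve(type = "filter") returns length(pad) - length(kernel) + 1
  out
}

#' Transient RF spikes
#'
#' Draws `k ~ Uniform{spike_count_range}` positions without replacement and
#' places single-bin impulses with amplitudes drawn uniformly from
#' `spike_amplitude_range` (fraction units; callers scale by the signal
#' maximum). Models transient radio-frequency interference.
#'
#' @param grid An `mrs_grid`.
#' @param config An [noise_config()].
#' @param seed Optional seed.
#' @return Numeric vector of length `grid$n_points`, zero outside the
#'   spike bins.
#' @export
rf_spikes <- function(grid, config, seed = NULL) {
  stopifnot(inherits(grid, "mrs_grid"), inherits(config, "mrs_noise_config"))
  n <- grid$n_points
  if (config$spike_count_range[2] > n) {
    stop_invalid("spike count exceeds number of grid points")
  }
  with_seed(seed, {
    lo <- config$spike_count_range[1]
    hi <- config$spike_count_range[2]
    k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    out <- numeric(n)
    if (k > 0) {
      pos <- sample.int(n, k)
      out[pos] <- runif(k, config$spike_amplitude_range[1],
                        config$spike_amplitude_range[2])
    }
    out
  })
}

#' Corrupt a clean spectrum into a paired noisy variant
#'
#' The full physics-motivated pipeline, in order: synthesize a zero-phase
#' FID; apodize with a drawn line broadening; add complex thermal noise at a
#' drawn target SNR; add pink 1/f noise (scale = `pink_amplitude` times the
#' thermal sigma); transform back (zero-filled FFT, real part); add the
#' polynomial + drift baseline and RF spikes (both scaled by the spectrum
#' maximum); min-max normalize. The paired target is the min-max-normalized
#' clean spectrum, untouched by any noise stage.
#'
#' @param clean A clean `mrs_spectrum` on the canonical grid.
#' @param config An [noise_config()].
#' @param seed Seed for this variant (default: the config's master seed).
#' @return List with elements `noisy` (normalized noisy spectrum),
#'   `clean_norm` (normalized clean spectrum) and `draws` (the sampled SNR
#'   (dB), line broadening (Hz) and seed).
#' @export
augment_pair <- function(clean, config = noise_config(), seed = config$seed) {
  stopifnot(inherits(clean, "mrs_spectrum"),
            inherits(config, "mrs_noise_config"))
  with_seed(seed, {
    snr_db <- if (is.infinite(config$target_snr_db[1])) Inf else
      runif(1, config$target_snr_db[1], config$target_snr_db[2])
    lb <- runif(1, config$lb_range_hz[1], config$lb_range_hz[2])
    fid <- spectrum_to_fid(clean)
    fid <- apodize(fid, lb)
    sigma <- 0
    if (is.finite(snr_db)) {
      p_signal <- mean(Mod(fid$samples)^2)
      sigma <- sqrt(p_signal / (2 * 10^(snr_db / 10)))
      fid <- thermal_noise(fid, 10^(snr_db / 10))
    }
    if (config$pink_amplitude > 0 && sigma > 0) {
      fid$samples <- fid$samples +
        pink_noise(length(fid$samples), config$pink_amplitude * sigma)
    }
    spec <- fid_to_spectrum(fid, config$zero_fill_factor)
    smax <- max(abs(spec$values))
    spec$values <- spec$values +
      smax * baseline_drift(clean$grid, config) +
      smax * rf_spikes(clean$grid, config)
    list(noisy = minmax_normalize(spec),
         clean_norm = minmax_normalize(clean),
         draws = list(snr_db = snr_db, lb_hz = lb, seed = seed))
  })
}

#' Build a paired clean/noisy training dataset
#'
#' Renders each peak table once, then generates `n_variants` noisy variants
#' per table with [augment_pair()]. Per-pair seeds are derived
#' deterministically from `(config$seed, table index, variant index)` via
#' [derive_seed()], so datasets are bit-reproducible and independent of
#' generation order.
#'
#' @param tables A single `mrs_peak_table` or a list of them.
#' @param n_variants Noisy variants per table (>= 1).
#' @param config An [noise_config()].
#' @param grid Canonical grid, see [make_grid()].
#' @param params Voigt widths for rendering, see [voigt_params()].
#' @return An object of class `mrs_dataset`: list with matrices `clean` and
#'   `noisy` (`n_pairs x n_points`, values in [0, 1]), data frame
#'   `manifest` (source label, drawn SNR/LB, per-pair seed) and the echoed
#'   `config`, `grid`, `params`.
#' @export
build_dataset <- function(tables, n_variants, config = noise_config(),
                          grid = make_grid(), params = voigt_params()) {
  if (inherits(tables, "mrs_peak_table")) tables <- list(tables)
  if (!length(tables)) stop_invalid("`tables` must be non-empty")
  check_number(n_variants, "n_variants", lower = 1)
  n_variants <- as.integer(n_variants)
  n_pairs <- length(tables) * n_variants
  clean_mat <- matrix(0, n_pairs, grid$n_points)
  noisy_mat <- matrix(0, n_pairs, grid$n_points)
  manifest <- data.frame(pair = seq_len(n_pairs), source = "", table_index = 0L,
                         variant = 0L, snr_db = 0, lb_hz = 0, seed = 0L,
                         stringsAsFactors = FALSE)
  row <- 1L
  for (ti in seq_along(tables)) {
    clean <- peaks_to_spectrum(tables[[ti]], grid, params)
    label <- attr(tables[[ti]], "source_label")
    if (is.null(label) || !nzchar(label)) label <- paste0("table_", ti)
    for (vi in seq_len(n_variants)) {
      s <- derive_seed(config$seed, ti, vi)
      pair <- augment_pair(clean, config, seed = s)
      clean_mat[row, ] <- pair$clean_norm$values
      noisy_mat[row, ] <- pair$noisy$values
      manifest[row, c("source", "table_index", "variant", "snr_db",
                      "lb_hz", "seed")] <-
        list(label, ti, vi, pair$draws$snr_db, pair$draws$lb_hz, s)
      row <- row + 1L
    }
  }
  structure(list(clean = clean_mat, noisy = noisy_mat, manifest = manifest,
                 config = config, grid = grid, params = params),
            class = "mrs_dataset")
}

#' @export
print.mrs_dataset <- function(x, ...) {
  cat(sprintf("<mrs_dataset> %d paired spectra x %d points (%d source table(s), master seed %d)\n",
              nrow(x$clean), ncol(x$clean), length(unique(x$manifest$table_index)),
              x$config$seed))
  invisible(x)
}
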