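test_that("thermal noise hits the sigma^2 = P/(2 SNR) law", {
  g <- make_grid(1e6, 0, 10, 63.885)
  fid <- structure(list(samples = complex(real = rep(1, 1e6)),
                        dwell_time = 1 / g$spectral_width_hz, grid = g),
                   class = "mrs_fid")
  ## P_signal = 1, SNR = 10: total complex noise power should be 0.1
  noisy <- thermal_noise(fid, 10, seed = 99)
  noise <- noisy$samples - fid$samples
  expect_equal(mean(Mod(noise)^2), 0.1, tolerance = 0.02)
  expect_equal(mean(Re(noise)^2), 0.05, tolerance = 0.05)  # per channel
  expect_equal(mean(Im(noise)^2), 0.05, tolerance = 0.05)

  ## SNR -> infinity leaves the FID untouched
  quiet <- thermal_noise(fid, 1e12, seed = 1)
  expect_lt(max(Mod(quiet$samples - fid$samples)), 1e-5)
  expect_error(thermal_noise(fid, 0), "target_snr_linear")
})

test_that("measured FID-domain SNR matches the drawn target within 1 dB", {
  clean <- peaks_to_spectrum(cholesterol_reference(), default_grid())
  cfg <- noise_config(pink_amplitude = 0, baseline_amplitude = 0,
                      drift_amplitude = 0, spike_count_range = c(0, 0),
                      seed = 5)
  ## replay the pipeline's exact RNG stream (seed -> SNR, LB, noise draws)
  ## and measure the achieved FID-domain SNR against the drawn target
  err_db <- vapply(1:100, function(i) {
    s <- derive_seed(5, 1, i)
    set.seed(s)
    snr_db <- runif(1, cfg$target_snr_db[1], cfg$target_snr_db[2])
    lb <- runif(1, cfg$lb_range_hz[1], cfg$lb_range_hz[2])
    fid <- apodize(spectrum_to_fid(clean), lb)
    noisy <- thermal_noise(fid, 10^(snr_db / 10))
    p_sig <- mean(Mod(fid$samples)^2)
    p_nse <- mean(Mod(noisy$samples - fid$samples)^2)
    10 * log10(p_sig / p_nse) - snr_db
  }, 0)
  expect_lt(abs(mean(err_db)), 1)
})

test_that("pink noise: zeros at zero amplitude, zero mean, 1/f PSD slope", {
  expect_equal(pink_noise(64, 0), complex(real = rep(0, 64)))

  x <- pink_noise(2^16, 1, seed = 8)
  expect_equal(mean(Re(x)), 0, tolerance = 1e-10)
  expect_equal(sd(Re(x)), 1, tolerance = 1e-10)
  expect_lt(abs(cor(Re(x), Im(x))), 0.15)  # channels independent

  ## periodogram log-log slope
  n <- 2^16
  p <- Mod(fft(Re(x)))^2
  f <- 1:(n / 2 - 1)
  slope <- coef(lm(log(p[f + 1]) ~ log(f)))[2]
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)

  means <- vapply(1:100, function(i) mean(Re(pink_noise(256, 1, seed = i))), 0)
  expect_lt(abs(mean(means)), 3 / sqrt(100))
})

test_that("baseline drift: degenerate configs and smoothness of the drift term", {
  g <- make_grid(1024, 0, 10, 63.885)
  flat <- noise_config(baseline_order = 0, baseline_amplitude = 0.2,
                       drift_amplitude = 0)
  b <- baseline_drift(g, flat, seed = 3)
  expect_equal(diff(range(b)), 0, tolerance = 1e-12)  # constant offset

  off <- noise_config(baseline_amplitude = 0, drift_amplitude = 0)
  expect_equal(baseline_drift(g, off, seed = 3), rep(0, 1024))

  cap <- noise_config(baseline_amplitude = 0.1, drift_amplitude = 0.05)
  bb <- baseline_drift(g, cap, seed = 17)
  expect_lte(max(abs(bb)), 0.15)

  ## drift is far smoother than the white noise it came from
  drift_only <- noise_config(baseline_amplitude = 0, drift_amplitude = 1,
                             drift_smoothing = 25)
  d <- baseline_drift(g, drift_only, seed = 5)
  w <- with(list(), { set.seed(5); rnorm(1024) })
  roughness <- function(v) mean(abs(diff(diff(v / max(abs(v))))))
  expect_lt(roughness(d) / roughness(w), 0.2)
})

test_that("RF spikes: counts honoured and positions uniform", {
  g <- make_grid(1024, 0, 10, 63.885)
  none <- noise_config(spike_count_range = c(0, 0))
  expect_equal(rf_spikes(g, none, seed = 1), rep(0, 1024))

  three <- noise_config(spike_count_range = c(3, 3))
  s <- rf_spikes(g, three, seed = 2)
  expect_equal(sum(s != 0), 3)
  expect_true(all(s[s != 0] >= 0.05 & s[s != 0] <= 0.2))

  one <- noise_config(spike_count_range = c(1, 1))
  pos <- vapply(1:10000, function(i) which(rf_spikes(g, one, seed = i) != 0), 0L)
  bins <- cut(pos, breaks = seq(0, 1024, length.out = 11))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("augmentation with every noise source disabled is the identity", {
  clean <- peaks_to_spectrum(cholesterol_reference(), default_grid())
  cfg <- noise_config(target_snr_db = c(Inf, Inf), lb_range_hz = c(0, 0),
                      pink_amplitude = 0, baseline_amplitude = 0,
                      drift_amplitude = 0, spike_count_range = c(0, 0))
  pair <- augment_pair(clean, cfg, seed = 21)
  expect_lt(max(abs(pair$noisy$values - pair$clean_norm$values)), 1e-6)
})

test_that("augmentation is deterministic under a seed and lands in [0,1]", {
  clean <- peaks_to_spectrum(cholesterol_reference(), default_grid())
  a <- augment_pair(clean, noise_config(), seed = 33)
  b <- augment_pair(clean, noise_config(), seed = 33)
  expect_identical(a$noisy$values, b$noisy$values)
  expect_identical(a$draws, b$draws)
  expect_equal(min(a$noisy$values), 0)
  expect_equal(max(a$noisy$values), 1)
  c <- augment_pair(clean, noise_config(), seed = 34)
  expect_false(identical(a$noisy$values, c$noisy$values))
})

test_that("dataset building: pair counts, reproducibility, clean channel untouched", {
  tab <- cholesterol_reference()
  d1 <- build_dataset(list(tab, toy_table(), tab), 5, noise_config(seed = 2))
  expect_equal(dim(d1$clean), c(15L, 1024L))
  expect_equal(nrow(d1$manifest), 15L)
  expect_true(all(d1$noisy >= 0 & d1$noisy <= 1))

  d2 <- build_dataset(list(tab, toy_table(), tab), 5, noise_config(seed = 2))
  expect_identical(d1$noisy, d2$noisy)
  d3 <- build_dataset(list(tab, toy_table(), tab), 5, noise_config(seed = 3))
  expect_false(identical(d1$noisy, d3$noisy))

  clean_norm <- minmax_normalize(peaks_to_spectrum(tab, d1$grid, d1$params))
  expect_identical(d1$clean[1, ], clean_norm$values)
  expect_identical(d1$clean[1, ], d1$clean[15, ])
  expect_error(build_dataset(list(), 5), "tables")
})
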