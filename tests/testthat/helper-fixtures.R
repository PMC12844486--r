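## Shared fixtures: everything is generated in code at test time.

default_grid <- function() make_grid(1024, 0, 10, 63.885)

## A tiny two-peak table for fast rendering tests.
toy_table <- function() {
  peak_table(peak_id = 1:2, ppm = c(3, 7), intensity = c(1000, 500),
             source_label = "toy")
}

## Deterministic 64-point signal pair used for the frozen metric oracle.
oracle_signals <- function() {
  i <- seq_len(64)
  x <- 0.5 + 0.3 * sin(2 * pi * i / 16)
  y <- x + 0.05 * cos(2 * pi * i / 8) + 0.02 * sin(2 * pi * i / 5)
  list(x = x, y = y)
}

## A reproducible noisy spectrum for filter cross-checks.
seeded_noisy_spectrum <- function(seed = 11) {
  clean <- peaks_to_spectrum(cholesterol_reference(), default_grid())
  augment_pair(clean, noise_config(), seed = seed)$noisy
}
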