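test_that("baseline specs validate their parameters", {
  expect_error(baseline_spec("savitzky_golay", window_length = 20), "odd")
  expect_error(baseline_spec("savitzky_golay", window_length = 3,
                             poly_order = 3), "odd|poly")
  expect_error(baseline_spec("median", kernel_size = 4), "odd")
  expect_error(baseline_spec("wavelet", family = "sym8"), "db4")
  expect_error(baseline_spec("gaussian", sigma = 0), "sigma")
})

test_that("gaussian smoothing preserves DC and its kernel is normalized", {
  spec <- baseline_spec("gaussian")  # sigma = 1.5
  x <- rep(3.7, 200)
  expect_equal(apply_classical(spec, x), x, tolerance = 1e-12)
  ## kernel weights sum to 1
  r <- ceiling(4 * 1.5)
  k <- exp(-(seq(-r, r))^2 / (2 * 1.5^2))
  expect_equal(sum(k / sum(k)), 1, tolerance = 1e-12)
})

test_that("gaussian smoothing matches a direct windowed-sum oracle", {
  x <- seeded_noisy_spectrum(7)$values
  got <- apply_classical(baseline_spec("gaussian"), x)
  ## oracle: explicit double loop with reflected indices
  r <- ceiling(4 * 1.5)
  k <- exp(-(seq(-r, r))^2 / (2 * 1.5^2)); k <- k / sum(k)
  n <- length(x)
  reflect <- function(i) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  want <- vapply(seq_len(n), function(i)
    sum(k * x[reflect(i + seq(-r, r))]), 0)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("Savitzky-Golay (21, 3) reproduces cubics exactly and matches a least-squares oracle", {
  x <- seq(0, 1, length.out = 200)
  cubic <- 2 - x + 3 * x^2 - 0.5 * x^3
  got <- apply_classical(baseline_spec("savitzky_golay"), cubic)
  interior <- 11:190
  expect_equal(got[interior], cubic[interior], tolerance = 1e-8)

  ## interior agreement with an explicit local cubic fit
  y <- seeded_noisy_spectrum(8)$values
  sg <- apply_classical(baseline_spec("savitzky_golay"), y)
  oracle_at <- function(i) {
    w <- (i - 10):(i + 10)
    fit <- lm(y[w] ~ poly(w, 3, raw = TRUE))
    unname(predict(fit, data.frame(w = i)))
  }
  probe <- c(50, 300, 700, 1000)
  expect_equal(sg[probe], vapply(probe, oracle_at, 0), tolerance = 1e-6)
})

test_that("median filter rejects single-bin impulses and matches a sliding-median oracle", {
  x <- rep(0, 100); x[40] <- 1
  expect_equal(apply_classical(baseline_spec("median"), x), rep(0, 100))

  y <- seeded_noisy_spectrum(9)$values
  got <- apply_classical(baseline_spec("median"), y)
  n <- length(y)
  reflect <- function(i) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  want <- vapply(seq_len(n), function(i)
    median(y[reflect(i + (-2:2))]), 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("db4 analysis matches reference coefficients and reconstructs perfectly", {
  ## expected values computed with PyWavelets (db4, mode="periodization")
  x <- c(1, 2, -1, 0.5, 3, -2, 0, 1.5, 2.5, -0.5, 1, 0, -1.5, 2, 0.5, -1)
  st <- dwt_step_db4(x)
  expect_equal(st$approx,
               c(-0.26094733024797945, 1.7074547788339622,
                 0.3742987682550687, 0.7674794118452282,
                 0.5558609921075566, 1.8034642426517393,
                 0.23950397205139717, 0.46973941399540764),
               tolerance = 1e-12)
  expect_equal(st$detail,
               c(0.3597601949258591, -3.483964987533626,
                 1.1405061955626588, -2.372609172099603,
                 0.26372174236312773, 2.3343358753026675,
                 -1.6247688350134517, 1.2616986429327246),
               tolerance = 1e-12)
  expect_equal(idwt_step_db4(st$approx, st$detail), x, tolerance = 1e-12)

  set.seed(12)
  z <- rnorm(1024)
  s1 <- dwt_step_db4(z)
  expect_equal(idwt_step_db4(s1$approx, s1$detail), z, tolerance = 1e-12)
})

test_that("soft thresholding shrinks by exactly the threshold and wavelet denoising fixes zero", {
  x <- c(-3, -0.5, 0, 0.2, 1.7)
  expect_equal(soft_threshold(x, 1), c(-2, 0, 0, 0, 0.7))
  expect_equal(apply_classical(baseline_spec("wavelet"), rep(0, 64)),
               rep(0, 64))
})

test_that("wavelet shrinkage removes most white noise from a smooth signal", {
  set.seed(3)
  t <- seq(0, 1, length.out = 1024)
  signal <- exp(-((t - 0.3) / 0.02)^2) + 0.6 * exp(-((t - 0.7) / 0.05)^2)
  noisy <- signal + rnorm(1024, sd = 0.05)
  den <- apply_classical(baseline_spec("wavelet"), noisy)
  expect_lt(mean((den - signal)^2), 0.35 * mean((noisy - signal)^2))
})

test_that("all four filters are shift-equivariant away from the boundaries", {
  y <- seeded_noisy_spectrum(10)$values
  ## multiple of 2^3 so the level-3 decimated wavelet transform commutes
  ## with the (circular) shift as well
  shift <- 40
  y_shift <- c(y[(shift + 1):length(y)], y[1:shift])
  for (spec in default_baselines()) {
    a <- apply_classical(spec, y)
    b <- apply_classical(spec, y_shift)
    interior <- 100:800
    expect_equal(b[interior], a[interior + shift], tolerance = 1e-6,
                 label = spec$method)
  }
})
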