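test_that("grid construction gives even spacing, inclusive endpoints and Hz width", {
  g <- make_grid(1024, 0, 10, 63.885)
  expect_equal(g$n_points, 1024L)
  expect_equal(g$spacing, 10 / 1023)
  ax <- grid_axis(g)
  expect_equal(ax[1], 0)
  expect_equal(ax[1024], 10)
  expect_equal(max(abs(diff(ax) - g$spacing)), 0, tolerance = 1e-12)

  g2 <- make_grid(2, 0, 10, 63.885)
  expect_equal(grid_axis(g2), c(0, 10))
  expect_equal(make_grid(11, 0, 10, 100)$spectral_width_hz, 1000)

  expect_error(make_grid(1, 0, 10, 63.885), "n_points")
  expect_error(make_grid(1024, 10, 0, 63.885), "ppm_max")
  expect_error(make_grid(1024, 0, 10, -1), "spectrometer_freq")
})

test_that("voigt profile hits the Gaussian and Lorentzian limits at the apex", {
  s <- 0.01
  expect_equal(voigt_profile(0, voigt_params(s, 0)), 1 / (s * sqrt(2 * pi)))
  g <- 0.01
  expect_equal(voigt_profile(0, voigt_params(0, g)), 1 / (pi * g))
  expect_error(voigt_params(0, 0), "both")
})

test_that("voigt profile matches a brute-force Gaussian x Lorentzian convolution", {
  ## independent oracle: discretized convolution of the two densities
  s <- 0.004; g <- 0.007
  dx <- 1e-4
  xx <- seq(-0.6, 0.6, by = dx)
  gauss <- dnorm(xx, sd = s)
  lor <- g / (pi * (xx^2 + g^2))
  conv <- convolve(gauss, rev(lor), type = "open") * dx
  mid <- (length(conv) + 1) / 2  # offset zero
  probe_idx <- mid + round(seq(-0.05, 0.05, by = 0.005) / dx)
  probe_x <- (probe_idx - mid) * dx
  expected <- conv[probe_idx]
  got <- voigt_profile(probe_x, voigt_params(s, g))
  expect_lt(max(abs(got - expected) / expected), 1e-4)
})

test_that("voigt profile is symmetric, non-negative and unit-area", {
  p <- voigt_params(0.005, 0.005)
  x <- seq(-3, 3, length.out = 20001)
  v <- voigt_profile(x, p)
  expect_true(all(v >= 0))
  expect_equal(v, rev(v))
  area <- sum((v[-1] + v[-length(v)]) / 2) * diff(x)[1] # trapezoid
  expect_equal(area, 1, tolerance = 0.01)
})

test_that("rendering is linear in the peak table and peaks superpose", {
  g <- make_grid(256, 0, 10, 63.885)
  vp <- voigt_params(0.05, 0.05)
  a <- peak_table(1, 3, 700)
  b <- peak_table(1, 7, 300)
  ab <- peak_table(1:2, c(3, 7), c(700, 300))
  sa <- peaks_to_spectrum(a, g, vp)$values
  sb <- peaks_to_spectrum(b, g, vp)$values
  sab <- peaks_to_spectrum(ab, g, vp)$values
  expect_equal(sab, sa + sb, tolerance = 1e-10)

  dup <- peak_table(1:2, c(3, 3), c(700, 700))
  expect_equal(peaks_to_spectrum(dup, g, vp)$values, 2 * sa, tolerance = 1e-10)
})

test_that("rendering the cholesterol reference puts the global maximum at 1.007 ppm", {
  g <- default_grid()
  sp <- peaks_to_spectrum(cholesterol_reference(), g)
  apex_ppm <- grid_axis(g)[which.max(sp$values)]
  expect_lt(abs(apex_ppm - 1.007), g$spacing / 2)
  ## robust across moderate linewidth choices
  for (w in c(0.002, 0.01, 0.02)) {
    spw <- peaks_to_spectrum(cholesterol_reference(), g, voigt_params(w, w))
    expect_lt(abs(grid_axis(g)[which.max(spw$values)] - 1.007), g$spacing / 2)
  }
})

test_that("empty tables error and out-of-range peaks are skipped with a message", {
  g <- make_grid(128, 0, 10, 63.885)
  expect_error(peaks_to_spectrum(peak_table(integer(0), numeric(0),
                                            numeric(0) + 1)[0, ], g))
  mixed <- peak_table(1:2, c(5, 12), c(100, 100))
  expect_message(sp <- peaks_to_spectrum(mixed, g, voigt_params(0.05, 0.05)),
                 "skipping")
  only_in <- peaks_to_spectrum(peak_table(1, 5, 100), g,
                               voigt_params(0.05, 0.05))
  expect_equal(sp$values, only_in$values)
})

test_that("min-max normalization maps to [0,1], is idempotent and handles constants", {
  g <- make_grid(3, 0, 10, 63.885)
  s <- new_spectrum(c(2, 4, 6), g)
  n1 <- minmax_normalize(s)
  expect_equal(n1$values, c(0, 0.5, 1))
  expect_true(n1$normalized)
  expect_equal(minmax_normalize(n1)$values, n1$values)
  expect_warning(z <- minmax_normalize(new_spectrum(c(5, 5, 5), g)),
                 "constant")
  expect_equal(z$values, c(0, 0, 0))
})

test_that("interpolation onto the grid is exact for identity and affine inputs", {
  g <- make_grid(101, 0, 10, 63.885)
  ax <- grid_axis(g)
  v <- sin(ax)
  expect_equal(interpolate_to_grid(ax, v, g)$values, v)

  coarse <- seq(0, 10, length.out = 11)
  ramp <- 2 * coarse + 1
  got <- interpolate_to_grid(coarse, ramp, g)$values
  expect_equal(got, 2 * ax + 1, tolerance = 1e-12)

  src <- seq(2, 8, length.out = 50)
  got2 <- interpolate_to_grid(src, rep(1, 50), g)$values
  expect_true(all(got2[ax < 2 | ax > 8] == 0))
  expect_true(all(got2[ax >= 2 & ax <= 8] == 1))

  expect_error(interpolate_to_grid(c(1, 3, 2), c(1, 2, 3), g), "monotone")
  desc <- interpolate_to_grid(rev(ax), rev(v), g)$values
  expect_equal(desc, v)
})
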