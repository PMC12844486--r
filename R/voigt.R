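## Voigt lineshape via the Faddeeva function.
##
## The Voigt profile (convolution of a Gaussian with a Lorentzian) has no
## elementary closed form; it is V(x; sigma, gamma) =
## Re[w(z)] / (sigma * sqrt(2*pi)) with z = (x + i*gamma) / (sigma*sqrt(2)),
## where w is the Faddeeva (scaled complex error) function. w is evaluated
## with Weideman's rational approximation, which is accurate to ~1e-12 over
## the whole upper half-plane at N = 36 terms.

.voigt_cache <- new.env(parent = emptyenv())

weideman_coeffs <- function(N) {
  key <- as.character(N)
  if (!is.null(.voigt_cache[[key]])) return(.voigt_cache[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  f <- c(f[(M + 1L):M2], f[1L:M]) # fftshift, even length
  a <- Re(stats::fft(f)) / M2
  coef <- rev(a[2L:(N + 1L)])
  .voigt_cache[[key]] <- coef
  coef
}

#' Faddeeva function w(z) on the upper half-plane
#'
#' `w(z) = exp(-z^2) * erfc(-i z)`, evaluated by Weideman's rational series.
#' Only `Im(z) >= 0` is supported (all that lineshape work needs).
#'
#' @param z Complex vector with non-negative imaginary part.
#' @param n_terms Number of series terms (accuracy ~1e-12 at the default).
#' @return Complex vector of `w(z)` values.
#' @keywords internal
#' @export
faddeeva_w <- function(z, n_terms = 36L) {
  a <- weideman_coeffs(n_terms)
  L <- sqrt(n_terms / sqrt(2))
  iz <- 1i * z
  Z <- (L + iz) / (L - iz)
  p <- complex(real = 0, imaginary = 0)
  for (ck in a) p <- p * Z + ck
  2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
}

#' Voigt lineshape parameters
#'
#' @param gauss_width Gaussian standard deviation (ppm), >= 0.
#' @param lorentz_width Lorentzian half-width at half-maximum (ppm), >= 0.
#'   The two widths must not both be zero.
#' @return An object of class `mrs_voigt_params`.
#' @export
voigt_params <- function(gauss_width = 0.005, lorentz_width = 0.005) {
  check_number(gauss_width, "gauss_width", lower = 0)
  check_number(lorentz_width, "lorentz_width", lower = 0)
  if (gauss_width == 0 && lorentz_width == 0) {
    stop_invalid("Voigt widths must not both be zero")
  }
  structure(list(gauss_width = gauss_width, lorentz_width = lorentz_width),
            class = "mrs_voigt_params")
}

#' Unit-area Voigt profile
#'
#' Evaluates the Voigt lineshape at the given offsets from line centre.
#' Degenerates exactly to a Gaussian density when `lorentz_width = 0` and to
#' a Lorentzian (Cauchy) density when `gauss_width = 0`.
#'
#' @param offsets Numeric vector of offsets from the line centre (ppm).
#' @param params An [voigt_params()] object.
#' @return Non-negative profile values; the profile integrates to 1 over
#'   infinite support.
#' @examples
#' voigt_profile(0, voigt_params(0.01, 0))   # 1/(0.01*sqrt(2*pi))
#' voigt_profile(0, voigt_params(0, 0.01))   # 1/(pi*0.01)
#' @export
voigt_profile <- function(offsets, params) {
  stopifnot(inherits(params, "mrs_voigt_params"))
  s <- params$gauss_width
  g <- params$lorentz_width
  if (s == 0) {
    return(g / (pi * (offsets^2 + g^2)))
  }
  if (g == 0) {
    return(stats::dnorm(offsets, sd = s))
  }
  z <- complex(real = offsets, imaginary = g) / (s * sqrt(2))
  Re(faddeeva_w(z)) / (s * sqrt(2 * pi))
}
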