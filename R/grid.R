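#' Create a uniform chemical-shift grid
#'
#' A spectral grid is the canonical frequency axis every spectrum in the
#' pipeline lives on: `n_points` evenly spaced chemical shifts from
#' `ppm_min` to `ppm_max` inclusive. The spectrometer frequency (MHz)
#' converts between ppm and Hz, which fixes the spectral width and hence
#' the dwell time of synthetic FIDs derived from the grid.
#'
#' The default pipeline uses a 1024-point grid over 0--10 ppm at
#' 63.885 MHz (a 1.5 T system), giving a spectral width of 638.85 Hz.
#'
#' @param n_points Number of grid points (>= 2).
#' @param ppm_min,ppm_max Grid bounds in ppm, `ppm_max > ppm_min`.
#' @param spectrometer_freq Spectrometer frequency in MHz (> 0).
#' @return An object of class `mrs_grid` with fields `n_points`, `ppm_min`,
#'   `ppm_max`, `spectrometer_freq`, `spacing` (ppm per bin) and
#'   `spectral_width_hz`.
#' @examples
#' g <- make_grid(1024, 0, 10, 63.885)
#' g$spacing            # 10/1023 ppm
#' g$spectral_width_hz  # 638.85 Hz
#' @export
make_grid <- function(n_points = 1024L, ppm_min = 0, ppm_max = 10,
                      spectrometer_freq = 63.885) {
  check_number(n_points, "n_points", lower = 2)
  check_number(ppm_min, "ppm_min")
  check_number(ppm_max, "ppm_max")
  check_number(spectrometer_freq, "spectrometer_freq", lower = 0, strict = TRUE)
  if (ppm_max <= ppm_min) stop_invalid("`ppm_max` must exceed `ppm_min`")
  n_points <- as.integer(n_points)
  structure(list(
    n_points = n_points,
    ppm_min = ppm_min,
    ppm_max = ppm_max,
    spectrometer_freq = spectrometer_freq,
    spacing = (ppm_max - ppm_min) / (n_points - 1L),
    spectral_width_hz = (ppm_max - ppm_min) * spectrometer_freq
  ), class = "mrs_grid")
}

#' Chemical-shift axis of a grid
#'
#' @param grid An `mrs_grid`.
#' @return Numeric vector of length `grid$n_points`, ascending, endpoints
#'   exactly `ppm_min` and `ppm_max`.
#' @export
grid_axis <- function(grid) {
  stopifnot(inherits(grid, "mrs_grid"))
  ax <- grid$ppm_min + (seq_len(grid$n_points) - 1L) * grid$spacing
  ax[grid$n_points] <- grid$ppm_max # exact endpoint despite rounding
  ax
}

#' @export
print.mrs_grid <- function(x, ...) {
  cat(sprintf("<mrs_grid> %d points, %.4g-%.4g ppm @ %.3f MHz (SW %.2f Hz)\n",
              x$n_points, x$ppm_min, x$ppm_max, x$spectrometer_freq,
              x$spectral_width_hz))
  invisible(x)
}

grids_equal <- function(a, b) {
  a$n_points == b$n_points &&
    isTRUE(all.equal(a$ppm_min, b$ppm_min)) &&
    isTRUE(all.equal(a$ppm_max, b$ppm_max)) &&
    isTRUE(all.equal(a$spectrometer_freq, b$spectrometer_freq))
}
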