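## Frequency <-> time domain conversion for synthetic FIDs.
##
## Convention: orthonormal discrete Fourier transforms (both directions
## scaled by 1/sqrt(N)), so Parseval's identity holds without extra factors:
## sum(|FID|^2) == sum(spectrum^2). Time axis t_k = k * dwell_time with
## dwell_time = 1 / spectral_width_hz -- the usual NMR sampling convention.

fft_ortho <- function(x) stats::fft(x) / sqrt(length(x))
ifft_ortho <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Synthesize a zero-phase FID from a spectrum
#'
#' Treats the real spectrum as a zero-phase absorptive-mode signal and takes
#' its inverse discrete Fourier transform, yielding a complex time-domain
#' free induction decay whose forward transform reproduces the spectrum
#' exactly (no added phase roll).
#'
#' @param s An `mrs_spectrum`.
#' @return An object of class `mrs_fid` with fields `samples` (complex,
#'   length `n_points`), `dwell_time` (s) and `grid` (the source grid).
#' @export
spectrum_to_fid <- function(s) {
  stopifnot(inherits(s, "mrs_spectrum"))
  samples <- ifft_ortho(as.complex(s$values))
  structure(list(samples = samples,
                 dwell_time = 1 / s$grid$spectral_width_hz,
                 grid = s$grid),
            class = "mrs_fid")
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf("<mrs_fid> %d complex samples, dwell %.4g s (SW %.2f Hz)\n",
              length(x$samples), x$dwell_time, 1 / x$dwell_time))
  invisible(x)
}

#' Transform an FID back to a spectrum
#'
#' Zero-fills the FID to `zero_fill_factor` times its length, Fourier
#' transforms, retains the real (absorptive-mode) component, and resamples
#' onto the FID's canonical grid via [interpolate_to_grid()] so downstream
#' arrays stay uniform. With factor 1 and an unperturbed FID this is the
#' exact inverse of [spectrum_to_fid()].
#'
#' @param fid An `mrs_fid`.
#' @param zero_fill_factor One of 1, 2, 4.
#' @param provenance Provenance tag for the result (default `"noisy"`, the
#'   augmentation-pipeline case).
#' @return An `mrs_spectrum` on the canonical grid.
#' @export
fid_to_spectrum <- function(fid, zero_fill_factor = 1L, provenance = "noisy") {
  stopifnot(inherits(fid, "mrs_fid"))
  if (!zero_fill_factor %in% c(1L, 2L, 4L)) {
    stop_invalid("`zero_fill_factor` must be 1, 2 or 4")
  }
  n <- length(fid$samples)
  f <- as.integer(zero_fill_factor)
  padded <- c(fid$samples, complex(real = rep(0, n * (f - 1L))))
  # Orthonormal scaling uses the *original* length so amplitudes are
  # preserved: the zero-padded DFT samples the same underlying spectrum on a
  # grid f times finer.
  fine <- Re(stats::fft(padded)) / sqrt(n)
  if (f == 1L) {
    return(new_spectrum(fine, fid$grid, provenance = provenance))
  }
  fine_axis <- fid$grid$ppm_min +
    (seq_len(n * f) - 1L) * fid$grid$spacing / f
  out <- interpolate_to_grid(fine_axis, fine, fid$grid)
  out$provenance <- provenance
  out
}

#' Exponential apodization (line broadening)
#'
#' Multiplies the FID by `exp(-pi * lb * t)` with `t = k * dwell_time`,
#' which broadens every spectral line by `lb` Hz (Lorentzian full width at
#' half maximum added). `lb = 0` is the identity; successive applications
#' compose additively in `lb`.
#'
#' @param fid An `mrs_fid`.
#' @param lb Line broadening in Hz, >= 0.
#' @return The apodized `mrs_fid`.
#' @export
apodize <- function(fid, lb) {
  stopifnot(inherits(fid, "mrs_fid"))
  check_number(lb, "lb", lower = 0)
  t <- (seq_along(fid$samples) - 1L) * fid$dwell_time
  out <- fid
  out$samples <- fid$samples * exp(-pi * lb * t)
  out
}
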