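#' Construct a spectrum on a grid
#'
#' A spectrum is a real intensity vector on an [make_grid()] axis, carrying
#' provenance (`"clean"`, `"noisy"`, `"denoised"` or `"external"`) and a flag
#' saying whether it has been min-max normalized to [0, 1].
#'
#' @param values Numeric vector, length `grid$n_points`.
#' @param grid An `mrs_grid`.
#' @param provenance One of `"clean"`, `"noisy"`, `"denoised"`, `"external"`.
#' @param normalized Logical flag.
#' @return An object of class `mrs_spectrum`.
#' @export
new_spectrum <- function(values, grid,
                         provenance = c("clean", "noisy", "denoised", "external"),
                         normalized = FALSE) {
  stopifnot(inherits(grid, "mrs_grid"))
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (length(values) != grid$n_points) {
    stop_invalid("`values` has length ", length(values),
                 " but the grid has ", grid$n_points, " points")
  }
  if (any(!is.finite(values))) stop_invalid("`values` must be finite")
  structure(list(values = values, grid = grid, provenance = provenance,
                 normalized = isTRUE(normalized)),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %s%s, %d points, %.3g-%.3g ppm, range [%.4g, %.4g]\n",
              x$provenance, if (x$normalized) " (normalized)" else "",
              x$grid$n_points, x$grid$ppm_min, x$grid$ppm_max,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Render a peak table into a clean spectrum
#'
#' Each resonance contributes `intensity * voigt_profile(axis - ppm)`; the
#' spectrum is the sum over all peaks and is therefore linear in the table's
#' intensities. Peaks falling outside the grid bounds are skipped with a
#' message (metabolite exports may list resonances beyond the rendered
#' window).
#'
#' @param table An [peak_table()] object.
#' @param grid An [make_grid()] grid.
#' @param params Voigt widths, see [voigt_params()].
#' @return An unnormalized `mrs_spectrum` with provenance `"clean"`.
#' @examples
#' sp <- peaks_to_spectrum(cholesterol_reference(), make_grid())
#' grid_axis(sp$grid)[which.max(sp$values)] # ~1.007 ppm
#' @export
peaks_to_spectrum <- function(table, grid = make_grid(),
                              params = voigt_params()) {
  stopifnot(inherits(table, "mrs_peak_table"), inherits(grid, "mrs_grid"))
  if (nrow(table) == 0L) stop_invalid("peak table is empty")
  axis <- grid_axis(grid)
  values <- numeric(grid$n_points)
  inside <- table$ppm >= grid$ppm_min & table$ppm <= grid$ppm_max
  if (any(!inside)) {
    msg_log("skipping ", sum(!inside), " peak(s) outside [",
            grid$ppm_min, ", ", grid$ppm_max, "] ppm: ",
            paste(format(table$ppm[!inside]), collapse = ", "))
  }
  for (i in which(inside)) {
    values <- values + table$intensity[i] *
      voigt_profile(axis - table$ppm[i], params)
  }
  new_spectrum(values, grid, provenance = "clean")
}

#' Min-max normalize a spectrum to [0, 1]
#'
#' Order-preserving affine map sending the minimum to 0 and the maximum
#' to 1. A constant spectrum maps to all zeros with a warning (so batch
#' augmentation pipelines survive degenerate draws rather than aborting).
#'
#' @param s An `mrs_spectrum`.
#' @return The normalized spectrum (`normalized = TRUE`); provenance is
#'   preserved. Idempotent.
#' @export
minmax_normalize <- function(s) {
  stopifnot(inherits(s, "mrs_spectrum"))
  lo <- min(s$values)
  hi <- max(s$values)
  if (hi == lo) {
    warning("constant spectrum: min-max normalization returns all zeros",
            call. = FALSE)
    v <- rep(0, length(s$values))
  } else {
    v <- (s$values - lo) / (hi - lo)
  }
  out <- s
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Linearly interpolate (ppm, intensity) samples onto a grid
#'
#' Resamples a spectrum given on an arbitrary strictly monotone ppm axis
#' onto the canonical grid by linear interpolation; grid points outside the
#' source range are filled with 0.
#'
#' @param axis Strictly monotone ppm vector (ascending or descending).
#' @param values Intensities, same length as `axis`.
#' @param grid Target [make_grid()] grid.
#' @param provenance Provenance tag for the resulting spectrum.
#' @return An `mrs_spectrum` on `grid`.
#' @export
interpolate_to_grid <- function(axis, values, grid, provenance = "external") {
  stopifnot(inherits(grid, "mrs_grid"))
  if (length(axis) != length(values)) {
    stop_invalid("`axis` and `values` lengths differ")
  }
  d <- diff(axis)
  if (length(axis) < 2L || !(all(d > 0) || all(d < 0))) {
    stop_invalid("`axis` must be strictly monotone with >= 2 points")
  }
  if (d[1] < 0) { # canonicalize ascending
    axis <- rev(axis)
    values <- rev(values)
  }
  out <- stats::approx(axis, values, xout = grid_axis(grid),
                       method = "linear", yleft = 0, yright = 0)$y
  new_spectrum(out, grid, provenance = provenance)
}
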