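#' Specify a classical denoising baseline
#'
#' The four traditional filters used for head-to-head comparison with the
#' U-Net, with their standard parameters as defaults: Gaussian smoothing
#' (`sigma = 1.5` bins), Savitzky-Golay (window 21, polynomial order 3),
#' sliding median (kernel 5), and db4 wavelet shrinkage (decomposition
#' level 3, soft thresholding).
#'
#' @param method One of `"gaussian"`, `"savitzky_golay"`, `"median"`,
#'   `"wavelet"`.
#' @param ... Method parameters overriding the defaults: `sigma` (gaussian);
#'   `window_length`, `poly_order` (savitzky_golay); `kernel_size` (median);
#'   `family`, `level`, `threshold_mode` (wavelet; only `"db4"` and
#'   `"soft"` are implemented).
#' @return An object of class `mrs_baseline_spec`.
#' @export
baseline_spec <- function(method = c("gaussian", "savitzky_golay", "median",
                                     "wavelet"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    gaussian = list(sigma = 1.5),
    savitzky_golay = list(window_length = 21L, poly_order = 3L),
    median = list(kernel_size = 5L),
    wavelet = list(family = "db4", level = 3L, threshold_mode = "soft")
  )
  params <- modifyList(defaults, list(...))
  if (method == "gaussian") {
    check_number(params$sigma, "sigma", lower = 0, strict = TRUE)
  } else if (method == "savitzky_golay") {
    if (params$window_length %% 2L != 1L ||
        params$window_length <= params$poly_order) {
      stop_invalid("`window_length` must be odd and > `poly_order`")
    }
  } else if (method == "median") {
    if (params$kernel_size %% 2L != 1L || params$kernel_size < 1L) {
      stop_invalid("`kernel_size` must be odd and >= 1")
    }
  } else {
    if (!identical(params$family, "db4")) {
      stop_invalid("only the db4 wavelet family is implemented")
    }
    if (!identical(params$threshold_mode, "soft")) {
      stop_invalid("only soft thresholding is implemented")
    }
    check_number(params$level, "level", lower = 1)
  }
  structure(list(method = method, params = params),
            class = "mrs_baseline_spec")
}

#' Apply a classical denoiser to a spectrum
#'
#' Boundary handling: Gaussian and median filters reflect the signal at the
#' edges (kernel radius `ceiling(4*sigma)` for the Gaussian, whose weights
#' are normalized to sum to 1); Savitzky-Golay fits truncated windows at the
#' edges (polynomial extrapolation); the wavelet transform uses periodized
#' boundaries. The wavelet threshold is the universal threshold
#' `T = sigma_hat * sqrt(2*log(N))` with `sigma_hat` the median absolute
#' deviation of the finest detail level divided by 0.6745, applied softly to
#' every detail level.
#'
#' @param spec A [baseline_spec()].
#' @param s An `mrs_spectrum` or numeric vector.
#' @return Same type as the input; spectra get provenance `"denoised"`.
#' @export
apply_classical <- function(spec, s) {
  stopifnot(inherits(spec, "mrs_baseline_spec"))
  if (inherits(s, "mrs_spectrum")) {
    out <- s
    out$values <- apply_classical(spec, s$values)
    out$provenance <- "denoised"
    return(out)
  }
  x <- as.numeric(s)
  p <- spec$params
  switch(spec$method,
    gaussian = gaussian_filter(x, p$sigma),
    savitzky_golay = as.numeric(signal::sgolayfilt(x, p = p$poly_order,
                                                   n = p$window_length)),
    median = median_filter(x, p$kernel_size),
    wavelet = wavelet_denoise(x, level = p$level)
  )
}

## Gaussian kernel smoothing, reflect boundary, radius ceil(4 sigma).
gaussian_filter <- function(x, sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_filter(x, k)
}

## Sliding median, reflect boundary.
median_filter <- function(x, kernel_size) {
  if (kernel_size == 1L) return(x)
  r <- (kernel_size - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
  out <- stats::runmed(pad, kernel_size, endrule = "keep")
  as.numeric(out[(r + 1L):(r + n)])
}

## Daubechies-4 (8-tap, 4 vanishing moments) filter bank.
db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- rev(db4_dec_lo) * c(-1, 1, -1, 1, -1, 1, -1, 1)
db4_rec_lo <- rev(db4_dec_lo)
db4_rec_hi <- rev(db4_dec_hi)

#' One-level periodized db4 analysis step
#'
#' Splits a signal of even length N into N/2 approximation and N/2 detail
#' coefficients using circular (periodized) convolution.
#'
#' @param x Numeric vector of even length.
#' @return List with `approx` and `detail` coefficient vectors.
#' @keywords internal
#' @export
dwt_step_db4 <- function(x) {
  n <- length(x)
  if (n %% 2L != 0L) stop_invalid("signal length must be even")
  half <- n %/% 2L
  idx <- outer(2 * seq_len(half) + 2, seq_len(8L) - 1L, "-") %% n + 1L
  xm <- matrix(x[idx], half, 8L)
  list(approx = as.numeric(xm %*% db4_dec_lo),
       detail = as.numeric(xm %*% db4_dec_hi))
}

#' One-level periodized db4 synthesis step (inverse of [dwt_step_db4()])
#'
#' @param approx,detail Coefficient vectors of equal length.
#' @return Reconstructed signal of twice the coefficient length.
#' @keywords internal
#' @export
idwt_step_db4 <- function(approx, detail) {
  half <- length(approx)
  n <- 2L * half
  up_a <- numeric(n)
  up_d <- numeric(n)
  up_a[seq(1, n, by = 2)] <- approx
  up_d[seq(1, n, by = 2)] <- detail
  idx <- outer(seq_len(n) + 2, seq_len(8L) - 1L, "-") %% n + 1L
  am <- matrix(up_a[idx], n, 8L)
  dm <- matrix(up_d[idx], n, 8L)
  as.numeric(am %*% db4_rec_lo + dm %*% db4_rec_hi)
}

#' Soft thresholding
#'
#' Shrinks each coefficient toward zero by `threshold`; values within the
#' threshold are zeroed: `sign(c) * max(|c| - T, 0)`.
#'
#' @param x Numeric vector.
#' @param threshold Non-negative threshold.
#' @return Shrunk vector.
#' @export
soft_threshold <- function(x, threshold) {
  check_number(threshold, "threshold", lower = 0)
  sign(x) * pmax(abs(x) - threshold, 0)
}

## db4 shrinkage: decompose to `level`, soft-threshold details with the
## universal threshold (sigma from the finest detail's MAD), reconstruct.
wavelet_denoise <- function(x, level = 3L) {
  n <- length(x)
  if (n %% 2L^level != 0L) {
    stop_invalid("signal length must be divisible by 2^level")
  }
  approx <- x
  details <- vector("list", level)
  for (l in seq_len(level)) {
    st <- dwt_step_db4(approx)
    approx <- st$approx
    details[[l]] <- st$detail
  }
  sigma_hat <- stats::median(abs(details[[1]])) / 0.6745
  thr <- sigma_hat * sqrt(2 * log(n))
  details <- lapply(details, soft_threshold, threshold = thr)
  for (l in rev(seq_len(level))) {
    approx <- idwt_step_db4(approx, details[[l]])
  }
  approx
}
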