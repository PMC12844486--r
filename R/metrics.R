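#' SSIM stabilization constants
#'
#' Standard constants for the structural similarity index on signals with
#' dynamic range `L`: `C1 = (k1*L)^2`, `C2 = (k2*L)^2`. Spectra here are
#' min-max normalized, so `L = 1`.
#'
#' @param k1,k2 Stabilization factors (defaults 0.01, 0.03).
#' @param dynamic_range Signal dynamic range `L` (default 1).
#' @return An object of class `mrs_ssim_constants` with `C1`, `C2`.
#' @export
ssim_constants <- function(k1 = 0.01, k2 = 0.03, dynamic_range = 1) {
  check_number(k1, "k1", lower = 0, strict = TRUE)
  check_number(k2, "k2", lower = 0, strict = TRUE)
  check_number(dynamic_range, "dynamic_range", lower = 0, strict = TRUE)
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 C1 = (k1 * dynamic_range)^2, C2 = (k2 * dynamic_range)^2),
            class = "mrs_ssim_constants")
}

## Cap for SNR/PSNR when the residual is exactly zero, so aggregation over
## spectra stays finite.
.db_cap <- 300

#' Six-way quality metrics for a reconstructed spectrum
#'
#' Computes, against the clean reference `x` for an estimate `y`:
#' * `snr_db = 10*log10(mean(x^2) / mean((y-x)^2))` -- signal power over
#'   residual power;
#' * `psnr_db = 10*log10(MAX^2 / MSE)` with `MAX = dynamic_range` (1 after
#'   normalization);
#' * `ssim`: global-statistics structural similarity
#'   `((2*mu_x*mu_y + C1)*(2*cov_xy + C2)) /
#'    ((mu_x^2 + mu_y^2 + C1)*(var_x + var_y + C2))`;
#' * `rmse`, `mae`: root-mean-square and mean absolute error;
#' * `pearson_r`: Pearson correlation.
#'
#' A zero residual makes SNR/PSNR infinite; both are capped at 300 dB.
#' Variances/covariance in the SSIM use the population (1/N) convention.
#'
#' @param clean Reference `mrs_spectrum` or numeric vector.
#' @param estimate Estimate of the same length.
#' @param constants An [ssim_constants()] object.
#' @return A one-row data frame of class `mrs_metric_report` with columns
#'   `snr_db`, `psnr_db`, `ssim`, `rmse`, `mae`, `pearson_r`.
#' @examples
#' compute_metrics(c(0, 1, 0.5), c(0, 0.9, 0.6))
#' @export
compute_metrics <- function(clean, estimate, constants = ssim_constants()) {
  x <- if (inherits(clean, "mrs_spectrum")) clean$values else as.numeric(clean)
  y <- if (inherits(estimate, "mrs_spectrum")) estimate$values else
    as.numeric(estimate)
  if (length(x) != length(y)) stop_invalid("signal lengths differ")
  stopifnot(inherits(constants, "mrs_ssim_constants"))
  n <- length(x)
  mse <- mean((y - x)^2)
  p_sig <- mean(x^2)
  snr <- if (mse == 0) .db_cap else min(10 * log10(p_sig / mse), .db_cap)
  psnr <- if (mse == 0) .db_cap else
    min(10 * log10(constants$dynamic_range^2 / mse), .db_cap)
  mu_x <- mean(x)
  mu_y <- mean(y)
  var_x <- mean((x - mu_x)^2)
  var_y <- mean((y - mu_y)^2)
  cov_xy <- mean((x - mu_x) * (y - mu_y))
  ssim <- ((2 * mu_x * mu_y + constants$C1) * (2 * cov_xy + constants$C2)) /
    ((mu_x^2 + mu_y^2 + constants$C1) * (var_x + var_y + constants$C2))
  if (var_x == 0 || var_y == 0) {
    stop_invalid("Pearson correlation undefined for zero-variance input")
  }
  r <- cov_xy / sqrt(var_x * var_y)
  out <- data.frame(snr_db = snr, psnr_db = psnr, ssim = ssim,
                    rmse = sqrt(mse), mae = mean(abs(y - x)), pearson_r = r)
  class(out) <- c("mrs_metric_report", "data.frame")
  out
}

metric_names <- c("snr_db", "psnr_db", "ssim", "rmse", "mae", "pearson_r")

## Higher-is-better orientation per metric.
metric_higher_better <- c(snr_db = TRUE, psnr_db = TRUE, ssim = TRUE,
                          rmse = FALSE, mae = FALSE, pearson_r = TRUE)

#' Benchmark denoising methods on a holdout dataset
#'
#' Runs the U-Net and each classical baseline over every pair of a holdout
#' dataset, computes the six metrics against the clean reference per
#' spectrum, and aggregates mean and standard deviation per method. The
#' per-spectrum metric arrays are retained for paired significance testing.
#'
#' @param data Holdout `mrs_dataset` (disjoint from the training pairs).
#' @param model A trained `mrs_denoiser`, or NULL to skip the U-Net row.
#' @param baselines List of [baseline_spec()] objects; the default is the
#'   standard four (Gaussian sigma 1.5, Savitzky-Golay 21/3, median 5,
#'   db4 level-3 soft wavelet).
#' @param constants [ssim_constants()].
#' @param include_noisy Also report the raw noisy input as a "none" row.
#' @return An object of class `mrs_benchmark`: list with `table` (data
#'   frame: method, metric, mean, sd) and `per_spectrum` (named list of
#'   n_spectra x 6 matrices).
#' @export
benchmark_methods <- function(data, model = NULL,
                              baselines = default_baselines(),
                              constants = ssim_constants(),
                              include_noisy = FALSE) {
  if (!is.list(data) || is.null(data$noisy)) stop_invalid("`data` must be an mrs_dataset")
  n <- nrow(data$noisy)
  outputs <- list()
  if (!is.null(model)) outputs[["unet"]] <- denoise(model, data$noisy)
  for (bs in baselines) {
    outputs[[bs$method]] <- t(apply(data$noisy, 1, function(v)
      apply_classical(bs, v)))
  }
  if (include_noisy) outputs[["none"]] <- data$noisy
  per_spectrum <- lapply(outputs, function(est) {
    m <- matrix(0, n, length(metric_names),
                dimnames = list(NULL, metric_names))
    for (i in seq_len(n)) {
      m[i, ] <- as.numeric(compute_metrics(data$clean[i, ], est[i, ],
                                           constants))
    }
    m
  })
  rows <- do.call(rbind, lapply(names(per_spectrum), function(method) {
    m <- per_spectrum[[method]]
    data.frame(method = method, metric = metric_names,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               row.names = NULL)
  }))
  structure(list(table = rows, per_spectrum = per_spectrum),
            class = "mrs_benchmark")
}

#' The four standard classical baselines
#'
#' @return List of [baseline_spec()]: Gaussian (sigma 1.5), Savitzky-Golay
#'   (window 21, order 3), median (kernel 5), wavelet (db4, level 3, soft).
#' @export
default_baselines <- function() {
  list(baseline_spec("gaussian"), baseline_spec("savitzky_golay"),
       baseline_spec("median"), baseline_spec("wavelet"))
}

#' @export
print.mrs_benchmark <- function(x, ...) {
  wide <- stats::reshape(x$table[, c("method", "metric", "mean")],
                         idvar = "method", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  cat("<mrs_benchmark> mean metrics over",
      nrow(x$per_spectrum[[1]]), "spectra:\n")
  print(format(wide, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Paired t-tests of a reference method against the others
#'
#' Two-sided paired t-tests on the per-spectrum metric values, pairing unit
#' = spectrum, for every (other method, metric) combination. Degenerate
#' cases (all per-spectrum differences identical to machine precision, e.g.
#' a method against itself) are flagged and reported with p = 1.
#'
#' @param benchmark An [benchmark_methods()] result.
#' @param reference_method Method name to compare against (default
#'   `"unet"`).
#' @return Data frame with columns `method`, `metric`, `mean_diff`
#'   (reference minus method), `p_value`, `degenerate`.
#' @export
paired_ttests <- function(benchmark, reference_method = "unet") {
  stopifnot(inherits(benchmark, "mrs_benchmark"))
  ref <- benchmark$per_spectrum[[reference_method]]
  if (is.null(ref)) stop_invalid("no such method: ", reference_method)
  if (nrow(ref) < 2L) stop_invalid("need at least 2 spectra for paired tests")
  others <- names(benchmark$per_spectrum)
  out <- do.call(rbind, lapply(others, function(method) {
    m <- benchmark$per_spectrum[[method]]
    do.call(rbind, lapply(metric_names, function(metric) {
      d <- ref[, metric] - m[, metric]
      degenerate <- stats::sd(d) <= .Machine$double.eps * (1 + abs(mean(d)))
      p <- if (degenerate) 1 else
        stats::t.test(ref[, metric], m[, metric], paired = TRUE)$p.value
      data.frame(method = method, metric = metric, mean_diff = mean(d),
                 p_value = p, degenerate = degenerate)
    }))
  }))
  out
}
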