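#' Write / read a spectrum as two-column text
#'
#' Plain tab-separated text with header `ppm  intensity`, plus a JSON
#' sidecar (`<path>.json`) recording the grid parameters, provenance and
#' normalization flag so a round trip preserves the full object.
#'
#' @param s An `mrs_spectrum`.
#' @param path Output file path.
#' @param sidecar Write the JSON manifest next to the file (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sidecar = TRUE) {
  stopifnot(inherits(s, "mrs_spectrum"))
  df <- data.frame(ppm = grid_axis(s$grid), intensity = s$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (sidecar) {
    meta <- list(n_points = s$grid$n_points, ppm_min = s$grid$ppm_min,
                 ppm_max = s$grid$ppm_max,
                 spectrometer_freq = s$grid$spectrometer_freq,
                 provenance = s$provenance, normalized = s$normalized)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_spectrum
#'
#' @param grid Grid to resample onto; by default the grid is reconstructed
#'   from the sidecar if present, else inferred from the file's own axis
#'   (assuming it is already uniform).
#' @param spectrometer_freq Used when no sidecar exists.
#' @return `read_spectrum`: an `mrs_spectrum`. A descending ppm column is
#'   accepted and canonicalized to ascending.
#' @export
read_spectrum <- function(path, grid = NULL, spectrometer_freq = 63.885) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "", comment.char = "#"),
    error = function(e) stop_invalid("cannot parse ", path, ": ",
                                     conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop_invalid(path, " must contain two numeric columns (ppm, intensity)")
  }
  axis <- suppressWarnings(as.numeric(raw[[1]]))
  values <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(axis)) || any(is.na(values))) {
    stop_invalid("non-numeric data in ", path)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  if (is.null(grid)) {
    grid <- if (!is.null(meta)) {
      make_grid(meta$n_points, meta$ppm_min, meta$ppm_max,
                meta$spectrometer_freq)
    } else {
      make_grid(length(axis), min(axis), max(axis), spectrometer_freq)
    }
  }
  out <- interpolate_to_grid(axis, values, grid)
  if (!is.null(meta)) {
    out$provenance <- meta$provenance
    out$normalized <- isTRUE(meta$normalized)
  }
  out
}

#' Save / load a paired dataset
#'
#' The matrices are stored as raw little-endian float64 arrays
#' (`clean.f64`, `noisy.f64`, row-major) next to a human-readable
#' `manifest.json` holding the dimensions, the noise configuration echo,
#' the per-pair draws and md5 checksums of both arrays. `load_dataset()`
#' verifies dimensions and checksums and aborts on any mismatch.
#'
#' @param data An `mrs_dataset` from [build_dataset()].
#' @param dir Directory to create/fill.
#' @return `save_dataset`: `dir`, invisibly. `load_dataset`: the restored
#'   `mrs_dataset` (bit-identical matrices).
#' @export
save_dataset <- function(data, dir) {
  stopifnot(inherits(data, "mrs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clean.f64", "noisy.f64"))
  writeBin(as.numeric(t(data$clean)), paths[1], size = 8, endian = "little")
  writeBin(as.numeric(t(data$noisy)), paths[2], size = 8, endian = "little")
  manifest <- list(
    n_pairs = nrow(data$clean),
    n_points = ncol(data$clean),
    checksums = list(clean = unname(tools::md5sum(paths[1])),
                     noisy = unname(tools::md5sum(paths[2]))),
    config = unclass(data$config),
    grid = unclass(data$grid),
    voigt = unclass(data$params),
    draws = data$manifest
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_invalid("missing manifest: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  paths <- file.path(dir, c("clean.f64", "noisy.f64"))
  if (!all(file.exists(paths))) stop_invalid("missing array file(s) in ", dir)
  sums <- c(unname(tools::md5sum(paths[1])), unname(tools::md5sum(paths[2])))
  if (!identical(sums[1], man$checksums$clean) ||
      !identical(sums[2], man$checksums$noisy)) {
    stop("dataset integrity error: checksum mismatch in ", dir, call. = FALSE)
  }
  n_pairs <- man$n_pairs
  n_points <- man$n_points
  expect_len <- n_pairs * n_points
  read_mat <- function(p) {
    v <- readBin(p, "double", n = expect_len + 1L, size = 8,
                 endian = "little")
    if (length(v) != expect_len) {
      stop("dataset integrity error: ", p, " has ", length(v),
           " values, expected ", expect_len, call. = FALSE)
    }
    matrix(v, n_pairs, n_points, byrow = TRUE)
  }
  cfg <- man$config
  config <- noise_config(target_snr_db = cfg$target_snr_db,
                         lb_range_hz = cfg$lb_range_hz,
                         pink_amplitude = cfg$pink_amplitude,
                         baseline_order = cfg$baseline_order,
                         baseline_amplitude = cfg$baseline_amplitude,
                         drift_amplitude = cfg$drift_amplitude,
                         drift_smoothing = cfg$drift_smoothing,
                         spike_count_range = cfg$spike_count_range,
                         spike_amplitude_range = cfg$spike_amplitude_range,
                         zero_fill_factor = cfg$zero_fill_factor,
                         seed = cfg$seed)
  grid <- make_grid(man$grid$n_points, man$grid$ppm_min, man$grid$ppm_max,
                    man$grid$spectrometer_freq)
  draws <- as.data.frame(man$draws)
  if (nrow(draws) != n_pairs) {
    stop("dataset integrity error: manifest rows (", nrow(draws),
         ") != n_pairs (", n_pairs, ")", call. = FALSE)
  }
  structure(list(clean = read_mat(paths[1]), noisy = read_mat(paths[2]),
                 manifest = draws, config = config, grid = grid,
                 params = voigt_params(man$voigt$gauss_width,
                                       man$voigt$lorentz_width)),
            class = "mrs_dataset")
}
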