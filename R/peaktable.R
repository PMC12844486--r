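#' Construct a peak table
#'
#' A peak table lists the resonances of one metabolite: integer peak labels,
#' chemical shifts in ppm and relative intensities (typically max-referenced
#' to 1000, as metabolite-database exports are).
#'
#' @param peak_id Integer vector of unique peak labels.
#' @param ppm Chemical shifts (ppm).
#' @param intensity Relative intensities (> 0).
#' @param source_label Free-text provenance label.
#' @param ... Further per-peak columns (e.g. assignments) carried along.
#' @return A data frame of class `mrs_peak_table` with attribute
#'   `source_label`.
#' @export
peak_table <- function(peak_id, ppm, intensity, source_label = "", ...) {
  peak_id <- as.integer(peak_id)
  if (anyDuplicated(peak_id)) stop_invalid("`peak_id` must be unique")
  if (length(ppm) != length(peak_id) || length(intensity) != length(peak_id)) {
    stop_invalid("`peak_id`, `ppm` and `intensity` must have equal length")
  }
  if (any(!is.finite(ppm)) || any(!is.finite(intensity))) {
    stop_invalid("`ppm` and `intensity` must be finite")
  }
  if (any(intensity <= 0)) stop_invalid("`intensity` must be positive")
  tab <- data.frame(peak_id = peak_id, ppm = as.numeric(ppm),
                    intensity = as.numeric(intensity), ...,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("mrs_peak_table", "data.frame"),
            source_label = source_label)
}

#' Read a peak table from a CSV/TSV export
#'
#' Expects a header with columns `peak_id`, `ppm`, `intensity` (extra
#' columns are kept). An optional `hz` column is accepted and checked for
#' consistency against `ppm * spectrometer_freq` (within 1%), then dropped.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param spectrometer_freq MHz, used only to validate an `hz` column.
#' @return An `mrs_peak_table`.
#' @export
load_peak_table <- function(path, sep = ",", spectrometer_freq = 63.885) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("peak_id", "ppm", "intensity")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_invalid("peak table ", path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      stop_invalid("non-numeric `", col, "` in row ", bad[1], " of ", path,
                   " (value: ", raw[[col]][bad[1]], ")")
    }
    raw[[col]] <- v
  }
  if (anyDuplicated(raw$peak_id)) {
    stop_invalid("duplicate peak_id in ", path, " (row ",
                 which(duplicated(raw$peak_id))[1], ")")
  }
  if ("hz" %in% names(raw)) {
    expect_hz <- raw$ppm * spectrometer_freq
    rel <- abs(raw$hz - expect_hz) / pmax(abs(expect_hz), 1e-12)
    if (any(rel > 0.01)) {
      stop_invalid("`hz` column inconsistent with ppm * ", spectrometer_freq,
                   " MHz in row ", which(rel > 0.01)[1], " of ", path)
    }
    raw$hz <- NULL
  }
  extra <- raw[setdiff(names(raw), need)]
  do.call(peak_table, c(list(peak_id = raw$peak_id, ppm = raw$ppm,
                             intensity = raw$intensity,
                             source_label = basename(path)),
                        as.list(extra)))
}

#' Bundled cholesterol reference peak table
#'
#' The 14 characteristic cholesterol 1H resonances (HMDB entry 2491),
#' spanning 0.678--5.35 ppm. Positions and intensities printed in the source
#' assignment summary are used verbatim (including the dominant aliphatic
#' envelope: peak 5, 1.007 ppm, intensity 1000; the hydroxyl-bearing methine:
#' peak 13, 3.5 ppm; and the olefinic marker: peak 14, 5.35 ppm); the
#' remaining entries are clearly flagged placeholders inside their stated
#' spectral regions -- see the `provenance` column.
#'
#' @return An `mrs_peak_table` with 14 rows and columns `peak_id`, `ppm`,
#'   `intensity`, `provenance`, `assignment`.
#' @export
cholesterol_reference <- function() {
  path <- system.file("extdata", "cholesterol_hmdb2491.csv",
                      package = "mrsdenoise", mustWork = TRUE)
  tab <- load_peak_table(path)
  attr(tab, "source_label") <- "cholesterol HMDB 2491"
  tab
}
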