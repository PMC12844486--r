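#' Detect peaks in a spectrum
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence` times the spectrum maximum, then refines each position
#' by 3-point parabolic interpolation through the apex and its neighbours.
#' Prominence is measured the standard way: the drop from the peak to the
#' higher of the two lowest points separating it from higher terrain (or
#' the signal edge).
#'
#' @param s An `mrs_spectrum`.
#' @param min_prominence Prominence threshold as a fraction of `max(s)`
#'   (default 0.01).
#' @return Data frame with columns `ppm` (refined position), `height` and
#'   `prominence`, sorted by ppm. Zero rows if nothing qualifies.
#' @export
detect_peaks <- function(s, min_prominence = 0.01) {
  stopifnot(inherits(s, "mrs_spectrum"))
  check_number(min_prominence, "min_prominence", lower = 0)
  v <- s$values
  n <- length(v)
  axis <- grid_axis(s$grid)
  empty <- data.frame(ppm = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L || max(v) <= min(v)) return(empty)
  apex <- which(diff(sign(diff(v))) < 0) + 1L # strict rise then fall/plateau
  if (!length(apex)) return(empty)
  prom <- vapply(apex, function(i) {
    h <- v[i]
    left <- if (i > 1L) {
      higher <- which(v[1:(i - 1L)] > h)
      lo <- if (length(higher)) (max(higher) + 1L):(i - 1L) else 1:(i - 1L)
      min(v[lo])
    } else h
    right <- if (i < n) {
      higher <- which(v[(i + 1L):n] > h)
      hi <- if (length(higher)) (i + 1L):(i + min(higher) - 1L) else (i + 1L):n
      min(v[hi])
    } else h
    h - max(left, right)
  }, 0)
  keep <- prom >= min_prominence * max(v)
  apex <- apex[keep]
  prom <- prom[keep]
  if (!length(apex)) return(empty)
  ppm <- vapply(apex, function(i) {
    if (i == 1L || i == n) return(axis[i])
    a <- v[i - 1L]; b <- v[i]; c <- v[i + 1L]
    denom <- a - 2 * b + c
    if (denom == 0) return(axis[i])
    delta <- 0.5 * (a - c) / denom
    axis[i] + delta * s$grid$spacing
  }, 0)
  data.frame(ppm = ppm, height = v[apex], prominence = prom)[order(ppm), ]
}

#' Match detected peaks to a reference table
#'
#' Greedy nearest-neighbour assignment on |delta ppm|: candidate pairs
#' within `tol_ppm` are accepted in order of increasing distance, each
#' detection and each reference peak used at most once; ties break toward
#' the smaller ppm. Monotone in the tolerance: shrinking `tol_ppm` never
#' increases the match count.
#'
#' @param detections Numeric vector of detected ppm positions, or the data
#'   frame returned by [detect_peaks()].
#' @param reference An `mrs_peak_table` (default the bundled 14-peak
#'   cholesterol reference).
#' @param tol_ppm Matching tolerance in ppm (default 0.05, about 5 grid
#'   bins on the canonical 1024-point axis).
#' @return An object of class `mrs_match_result`: list with data frame
#'   `matches` (`detected_ppm`, `peak_id`, `reference_ppm`, `delta_ppm`),
#'   vector `unmatched_detections` and data frame `unmatched_references`.
#' @export
match_to_reference <- function(detections, reference = cholesterol_reference(),
                               tol_ppm = 0.05) {
  if (is.data.frame(detections)) detections <- detections$ppm
  detections <- as.numeric(detections)
  stopifnot(inherits(reference, "mrs_peak_table"))
  check_number(tol_ppm, "tol_ppm", lower = 0, strict = TRUE)
  nd <- length(detections)
  nr <- nrow(reference)
  pairs <- expand.grid(d = seq_len(nd), r = seq_len(nr))
  pairs$dist <- abs(detections[pairs$d] - reference$ppm[pairs$r])
  pairs <- pairs[pairs$dist <= tol_ppm, ]
  pairs <- pairs[order(pairs$dist, detections[pairs$d]), ]
  used_d <- logical(nd)
  used_r <- logical(nr)
  keep <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$d[k]; r <- pairs$r[k]
    if (!used_d[d] && !used_r[r]) {
      used_d[d] <- TRUE
      used_r[r] <- TRUE
      keep <- c(keep, k)
    }
  }
  m <- pairs[keep, ]
  matches <- data.frame(detected_ppm = detections[m$d],
                        peak_id = reference$peak_id[m$r],
                        reference_ppm = reference$ppm[m$r],
                        delta_ppm = m$dist)
  matches <- matches[order(matches$reference_ppm), ]
  rownames(matches) <- NULL
  structure(list(matches = matches,
                 unmatched_detections = detections[!used_d],
                 unmatched_references =
                   as.data.frame(reference)[!used_r,
                                            c("peak_id", "ppm", "intensity")],
                 tol_ppm = tol_ppm),
            class = "mrs_match_result")
}

#' @export
print.mrs_match_result <- function(x, ...) {
  cat(sprintf("<mrs_match_result> %d matched / %d reference peaks (tol %.3g ppm), %d unassigned detections\n",
              nrow(x$matches), nrow(x$matches) + nrow(x$unmatched_references),
              x$tol_ppm, length(x$unmatched_detections)))
  if (nrow(x$matches)) print(format(x$matches, digits = 4), row.names = FALSE)
  invisible(x)
}
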