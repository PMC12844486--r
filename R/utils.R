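## Internal helpers: argument checks, seeded evaluation, logging.

stop_invalid <- function(...) {
  stop(structure(
    class = c("mrsdenoise_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop_invalid("`", name, "` = ", format(x), " is outside the allowed range [",
                 lower, ", ", upper, "]", if (strict) " (exclusive)")
  }
  invisible(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded helpers never perturb an enclosing
#' simulation. A `NULL` seed evaluates `code` with the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and indices
#'
#' MINSTD-style modular hash; the multiplier keeps every intermediate product
#' below 2^53 so the arithmetic is exact in doubles, and the result is always
#' in `[1, 2^31 - 2]` (a valid 32-bit R seed).
#'
#' @param master Integer master seed.
#' @param ... Non-negative integer indices (e.g. table index, variant index).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (k in c(1, as.numeric(c(...)))) {
    h <- (h * 48271 + k) %% m
  }
  h <- (h * 48271 + 11) %% m
  as.integer(if (h == 0) 1 else h)
}

msg_log <- function(...) {
  message("[mrsdenoise] ", ...)
}
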