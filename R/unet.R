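#' 1D U-Net architecture configuration
#'
#' The denoiser is a 1D encoder-decoder with `n_levels` downsampling stages
#' and a symmetric upsampling path. Each stage is two Conv1D + ReLU layers;
#' encoder stages end in a factor-2 max-pool, decoder stages start with a
#' factor-2 linear-interpolation upsample followed by a skip concatenation
#' with the matching encoder output, and a final kernel-1 linear convolution
#' projects back to one channel. Channel width doubles per level from
#' `base_channels`.
#'
#' @param n_levels Downsampling depth (default 3: 1024 -> 512 -> 256 -> 128).
#' @param base_channels Channels at the first level (default 16).
#' @param kernel_size Convolution width, odd (default 9).
#' @param pool_factor Down/upsampling factor; only 2 is supported.
#' @return An object of class `mrs_unet_config`.
#' @export
unet_config <- function(n_levels = 3L, base_channels = 16L, kernel_size = 9L,
                        pool_factor = 2L) {
  check_number(n_levels, "n_levels", lower = 1)
  check_number(base_channels, "base_channels", lower = 1)
  check_number(kernel_size, "kernel_size", lower = 1)
  if (pool_factor != 2L) stop_invalid("only `pool_factor = 2` is supported")
  if (kernel_size %% 2L != 1L) stop_invalid("`kernel_size` must be odd")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_factor = 2L),
            class = "mrs_unet_config")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 150).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param val_fraction Validation holdout share, in (0, 1) (default 0.15).
#' @param seed Seed controlling weight init, the train/validation split and
#'   epoch shuffling.
#' @return An object of class `mrs_train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 32L,
                         learning_rate = 1e-3, val_fraction = 0.15,
                         seed = 42L) {
  check_number(epochs, "epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 1,
               strict = TRUE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "mrs_train_config")
}

## Conv layer shapes implied by a config (must mirror the C++ layout).
unet_layout <- function(config) {
  n <- config$n_levels
  base <- config$base_channels
  k <- config$kernel_size
  lay <- list()
  c_in <- 1L
  for (i in seq_len(n)) {
    c <- base * 2L^(i - 1L)
    lay <- c(lay, list(c(c_in, c, k), c(c, c, k)))
    c_in <- c
  }
  cb <- base * 2L^n
  lay <- c(lay, list(c(c_in, cb, k), c(cb, cb, k)))
  c_in <- cb
  for (i in rev(seq_len(n))) {
    c <- base * 2L^(i - 1L)
    lay <- c(lay, list(c(c_in + c, c, k), c(c, c, k)))
    c_in <- c
  }
  c(lay, list(c(c_in, 1L, 1L)))
}

#' Build an (untrained) U-Net denoiser
#'
#' Initializes weights with He-scaled Gaussians (`sd = sqrt(2 / fan_in)`)
#' and zero biases, deterministically for a given seed.
#'
#' @param config An [unet_config()].
#' @param input_length Length of the spectra the model will see; must be
#'   divisible by `pool_factor^n_levels` (the default 1024 is).
#' @param seed Seed for weight initialization.
#' @return An object of class `mrs_denoiser` with fields `config`,
#'   `input_length`, `weights` (`W`, `b` lists), `history` (NULL until
#'   trained) and `trained`.
#' @export
build_model <- function(config = unet_config(), input_length = 1024L,
                        seed = 42L) {
  stopifnot(inherits(config, "mrs_unet_config"))
  input_length <- as.integer(input_length)
  if (input_length %% config$pool_factor^config$n_levels != 0L) {
    stop_invalid("`input_length` must be divisible by pool_factor^n_levels (",
                 config$pool_factor^config$n_levels, ")")
  }
  lay <- unet_layout(config)
  weights <- with_seed(seed, {
    W <- lapply(lay, function(sh) {
      fan_in <- sh[1] * sh[3]
      matrix(rnorm(sh[2] * fan_in, sd = sqrt(2 / fan_in)), sh[2], fan_in)
    })
    b <- lapply(lay, function(sh) numeric(sh[2]))
    list(W = W, b = b)
  })
  structure(list(config = config, input_length = input_length,
                 weights = weights, history = NULL, trained = FALSE,
                 best_epoch = NA_integer_, init_seed = as.integer(seed)),
            class = "mrs_denoiser")
}

#' @export
print.mrs_denoiser <- function(x, ...) {
  np <- sum(vapply(x$weights$W, length, 0)) +
    sum(vapply(x$weights$b, length, 0))
  cat(sprintf("<mrs_denoiser> %d-level 1D U-Net, base %d ch, kernel %d, %s (%d parameters)\n",
              x$config$n_levels, x$config$base_channels,
              x$config$kernel_size,
              if (x$trained) sprintf("trained (best epoch %d, val MSE %.3g)",
                                     x$best_epoch,
                                     min(x$history$val_mse))
              else "untrained", np))
  invisible(x)
}

#' Train the U-Net denoiser on a paired dataset
#'
#' Minimizes the mean squared error between the network output on noisy
#' spectra and the matching clean spectra with the Adam optimizer, tracking
#' MSE and MAE on both the training split and a held-out validation split
#' each epoch. The returned model carries the weights of the epoch with the
#' best validation MSE (not necessarily the last).
#'
#' @param model An [build_model()] denoiser.
#' @param data An `mrs_dataset` from [build_dataset()], values in [0, 1].
#' @param tc An [train_config()].
#' @return The trained `mrs_denoiser`; `$history` is a data frame with one
#'   row per epoch (`train_mse`, `train_mae`, `val_mse`, `val_mae`).
#' @export
train_denoiser <- function(model, data, tc = train_config()) {
  stopifnot(inherits(model, "mrs_denoiser"), inherits(tc, "mrs_train_config"))
  if (!is.list(data) || is.null(data$noisy) || is.null(data$clean)) {
    stop_invalid("`data` must be an mrs_dataset (or a list with clean/noisy matrices)")
  }
  n <- nrow(data$noisy)
  if (is.null(n) || n < 2L) stop_invalid("dataset must contain at least 2 pairs")
  if (ncol(data$noisy) != model$input_length) {
    stop_invalid("dataset spectra have length ", ncol(data$noisy),
                 " but the model expects ", model$input_length)
  }
  split <- with_seed(tc$seed, {
    idx <- sample.int(n)
    n_val <- min(max(1L, round(tc$val_fraction * n)), n - 1L)
    val <- sort(idx[seq_len(n_val)])
    train <- idx[(n_val + 1L):n]
    perms <- vapply(seq_len(tc$epochs), function(e) sample(train),
                    integer(length(train)))
    list(train = train, val = val, perms = perms)
  })
  fit <- cpp_unet_train(t(data$noisy), t(data$clean),
                        model$weights$W, model$weights$b,
                        model$config$n_levels, model$config$base_channels,
                        model$config$kernel_size,
                        split$train, split$val, split$perms,
                        tc$batch_size, tc$learning_rate, 0.9, 0.999, 1e-8)
  model$weights <- list(W = fit$W, b = fit$b)
  model$history <- data.frame(epoch = seq_len(tc$epochs),
                              train_mse = fit$history[, 1],
                              train_mae = fit$history[, 2],
                              val_mse = fit$history[, 3],
                              val_mae = fit$history[, 4])
  model$trained <- TRUE
  model$best_epoch <- fit$best_epoch
  model$train_config <- tc
  model
}

#' Denoise spectra with a U-Net model
#'
#' Deterministic inference. Accepts a single normalized `mrs_spectrum` (the
#' result keeps the grid and gets provenance `"denoised"`) or a numeric
#' matrix of row-spectra (a matrix of the same shape is returned).
#'
#' @param model A (typically trained) `mrs_denoiser`.
#' @param s An `mrs_spectrum` of length `input_length`, or an
#'   `n x input_length` matrix.
#' @return Denoised spectrum or matrix.
#' @export
denoise <- function(model, s) {
  stopifnot(inherits(model, "mrs_denoiser"))
  if (inherits(s, "mrs_spectrum")) {
    if (length(s$values) != model$input_length) {
      stop_invalid("spectrum length ", length(s$values),
                   " does not match model input length ", model$input_length)
    }
    pred <- cpp_unet_predict(matrix(s$values, ncol = 1),
                             model$weights$W, model$weights$b,
                             model$config$n_levels,
                             model$config$base_channels,
                             model$config$kernel_size)
    out <- s
    out$values <- as.numeric(pred)
    out$provenance <- "denoised"
    return(out)
  }
  if (!is.matrix(s)) stop_invalid("`s` must be an mrs_spectrum or a matrix")
  if (ncol(s) != model$input_length) {
    stop_invalid("matrix has ", ncol(s), " columns but the model expects ",
                 model$input_length)
  }
  t(cpp_unet_predict(t(s), model$weights$W, model$weights$b,
                     model$config$n_levels, model$config$base_channels,
                     model$config$kernel_size))
}
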