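test_that("model construction obeys shape contracts and seeding", {
  m <- build_model()
  expect_equal(length(m$weights$W), 4L * 3L + 3L)
  ## channel plan: 1 -> 16 -> 32 -> 64 -> 128 bottleneck, mirrored decoder
  expect_equal(nrow(m$weights$W[[1]]), 16L)
  expect_equal(dim(m$weights$W[[7]]), c(128L, 64L * 9L))
  expect_equal(dim(m$weights$W[[15]]), c(1L, 16L))

  m2 <- build_model(seed = m$init_seed)
  expect_identical(m$weights, m2$weights)
  m3 <- build_model(seed = m$init_seed + 1L)
  expect_false(identical(m$weights$W[[1]], m3$weights$W[[1]]))

  expect_error(build_model(unet_config(), input_length = 1020L),
               "divisible")
  expect_error(unet_config(kernel_size = 8), "odd")
})

test_that("an untrained model maps 1024-point input to finite 1024-point output", {
  m <- build_model(seed = 3)
  sp <- minmax_normalize(peaks_to_spectrum(cholesterol_reference(),
                                           default_grid()))
  out <- denoise(m, sp)
  expect_equal(length(out$values), 1024L)
  expect_true(all(is.finite(out$values)))
  expect_equal(out$provenance, "denoised")
  expect_error(denoise(m, new_spectrum(rep(0, 512),
                                       make_grid(512, 0, 10, 63.885))),
               "length")
})

test_that("inference is deterministic", {
  m <- build_model(seed = 3)
  x <- matrix(runif(2 * 1024), 2, 1024)
  expect_identical(denoise(m, x), denoise(m, x))
})

test_that("analytic gradients agree with finite differences on a tiny net", {
  ## With default-scale weights the loss surface is piecewise linear in any
  ## bias (every pre-activation sits near a ReLU kink), which makes central
  ## differences unreliable; so the check runs in a regime where all
  ## rectifiers are firmly active - weights scaled down, biases +0.5 - and
  ## the network is locally smooth. Weight gradients are additionally
  ## checked at the default initialization.
  set.seed(1)
  cfg <- unet_config(n_levels = 2, base_channels = 2, kernel_size = 3)
  m <- build_model(cfg, input_length = 16, seed = 5)
  X <- matrix(runif(16 * 3), 3, 16)
  Yt <- matrix(runif(16 * 3), 3, 16)
  loss_at <- function(W, b) {
    mrsdenoise:::cpp_unet_lossgrad(t(X), t(Yt), W, b, 2, 2, 3)$loss
  }
  h <- 1e-3

  ## (a) locally-linear regime: weights and biases, tight tolerance
  Ws <- lapply(m$weights$W, function(w) w * 0.1)
  bs <- lapply(m$weights$b, function(b) b + 0.5)
  lg <- mrsdenoise:::cpp_unet_lossgrad(t(X), t(Yt), Ws, bs, 2, 2, 3)
  for (li in seq_along(Ws)) {
    for (j in seq_len(min(3, length(Ws[[li]])))) {
      Wp <- Ws; Wp[[li]][j] <- Wp[[li]][j] + h
      Wm <- Ws; Wm[[li]][j] <- Wm[[li]][j] - h
      fd <- (loss_at(Wp, bs) - loss_at(Wm, bs)) / (2 * h)
      an <- lg$gW[[li]][j]
      expect_lt(abs(fd - an), 1e-4 + 0.02 * (abs(fd) + abs(an)))
    }
    bp <- bs; bp[[li]][1] <- bp[[li]][1] + h
    bm_ <- bs; bm_[[li]][1] <- bm_[[li]][1] - h
    fd <- (loss_at(Ws, bp) - loss_at(Ws, bm_)) / (2 * h)
    expect_lt(abs(fd - lg$gb[[li]][1]),
              1e-4 + 0.02 * (abs(fd) + abs(lg$gb[[li]][1])))
  }

  ## (b) default init: weight gradients only (kinks make bias FD noisy)
  lg2 <- mrsdenoise:::cpp_unet_lossgrad(t(X), t(Yt), m$weights$W,
                                        m$weights$b, 2, 2, 3)
  for (li in seq_along(m$weights$W)) {
    for (j in seq_len(min(3, length(m$weights$W[[li]])))) {
      Wp <- m$weights$W; Wp[[li]][j] <- Wp[[li]][j] + h
      Wm <- m$weights$W; Wm[[li]][j] <- Wm[[li]][j] - h
      fd <- (loss_at(Wp, m$weights$b) - loss_at(Wm, m$weights$b)) / (2 * h)
      an <- lg2$gW[[li]][j]
      expect_lt(abs(fd - an), 5e-4 + 0.05 * (abs(fd) + abs(an)))
    }
  }
})

test_that("training learns the identity task and records full history", {
  ## 200 identity pairs (noisy == clean), 20 epochs
  data <- build_dataset(cholesterol_reference(), 200, noise_config(seed = 6))
  iddata <- data
  iddata$noisy <- iddata$clean
  tc <- train_config(epochs = 20, seed = 2)
  fit <- train_denoiser(build_model(seed = 2), iddata, tc)
  expect_equal(nrow(fit$history), 20L)
  expect_true(fit$trained)
  expect_lt(min(fit$history$val_mse), 1e-4)
  ## loss collapses by orders of magnitude on this task
  expect_lt(fit$history$train_mse[20], fit$history$train_mse[1] / 10)
})

test_that("a briefly trained model denoises held-out spectra", {
  train_data <- build_dataset(cholesterol_reference(), 300,
                              noise_config(seed = 7))
  holdout <- build_dataset(cholesterol_reference(), 10,
                           noise_config(seed = 8))
  fit <- train_denoiser(build_model(seed = 4), train_data,
                        train_config(epochs = 6, seed = 4))
  den <- denoise(fit, holdout$noisy)
  mse_before <- rowMeans((holdout$noisy - holdout$clean)^2)
  mse_after <- rowMeans((den - holdout$clean)^2)
  expect_true(all(mse_after < mse_before))
})

test_that("training is reproducible under a fixed seed", {
  data <- build_dataset(cholesterol_reference(), 60, noise_config(seed = 9))
  f1 <- train_denoiser(build_model(seed = 5), data,
                       train_config(epochs = 2, seed = 5))
  f2 <- train_denoiser(build_model(seed = 5), data,
                       train_config(epochs = 2, seed = 5))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})
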