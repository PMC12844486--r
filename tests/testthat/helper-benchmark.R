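## The desk-scale benchmark (2000 training pairs, 50 holdout pairs, 30
## epochs) is expensive, so it is computed once per test run and shared by
## the acceptance-style tests that assert on it.

.benchmark_cache <- new.env(parent = emptyenv())

get_full_benchmark <- function() {
  if (!is.null(.benchmark_cache$result)) return(.benchmark_cache$result)
  master <- 1L
  train_data <- build_dataset(cholesterol_reference(), 2000,
                              noise_config(seed = derive_seed(master, 1)))
  holdout <- build_dataset(cholesterol_reference(), 50,
                           noise_config(seed = derive_seed(master, 2)))
  model <- train_denoiser(
    build_model(seed = derive_seed(master, 3)),
    train_data,
    train_config(epochs = 30, seed = derive_seed(master, 4))
  )
  bm <- benchmark_methods(holdout, model)
  noisy_in <- benchmark_methods(holdout, model = NULL, baselines = list(),
                                include_noisy = TRUE)
  .benchmark_cache$result <- list(
    model = model,
    holdout = holdout,
    benchmark = bm,
    ttests = paired_ttests(bm),
    input_metrics = noisy_in$per_spectrum$none
  )
  .benchmark_cache$result
}

bench_mean <- function(bm, meth, metr) {
  tab <- bm$table
  tab$mean[tab$method == meth & tab$metric == metr]
}
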