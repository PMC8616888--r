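# Desk-scale reference experiment shared by the acceptance-level tests:
# the 1D deconvolution benchmark at full signal length and dataset size with
# a shortened training schedule. Trained once per test run and cached.

.reference_cache <- new.env(parent = emptyenv())

reference_config <- function(seed = 1) {
  experiment_config(
    n = 512, nu = 8, sigma = 0.05, noise_mode = "measurement_and_signal",
    n_total = 2000, split_sizes = c(train = 1600, validation = 200,
                                    test = 200),
    n_layers = 10, channels = 24, kernel_size = 5, dropout_sites = c(3, 5, 7),
    epochs_base = 12, epochs_inn = 10, interval_layers = 6:10,
    batch_size = 32, beta = 2e-3, methods = "inn", seed = seed)
}

get_reference_bundle <- function() {
  if (is.null(.reference_cache$bundle)) {
    .reference_cache$bundle <- train_reference_models(reference_config())
  }
  .reference_cache$bundle
}
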