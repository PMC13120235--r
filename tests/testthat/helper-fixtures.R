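# small in-code fixtures shared across test files

# tiny spectra set with reproducible random absorbances
toy_spectra <- function(n = 5, p = 24, seed = 42, lo = 1000, step = 4) {
  set.seed(seed)
  spectra_set(seq(lo, by = step, length.out = p),
              matrix(runif(n * p), n, p),
              paste0("S", seq_len(n)))
}

# one-channel spectra set whose absorbance values are used directly as
# PLS-DA scores by fake_da_model()
score_spectra <- function(values, ids = paste0("U", seq_along(values))) {
  spectra_set(1000, matrix(values, ncol = 1), ids)
}

# hand-built PLS-DA model with identity coefficients and an identity
# pre-treatment, so predicted scores equal the (single-channel) absorbance
fake_da_model <- function(threshold = 0.5) {
  b <- 1
  attr(b, "intercept") <- 0
  core <- structure(
    list(n_lv = 1L, W = matrix(1), P = matrix(1), q = 1,
         x_mean = 0, y_mean = 0, coefficients = b, early_stop = FALSE),
    class = "pls_model"
  )
  structure(list(core = core, positive_label = "V", threshold = threshold),
            class = "da_model")
}

fake_identity_fitted <- function(grid = 1000) {
  structure(
    list(spec = pretreatment_spec("autoscale"), grid = grid,
         means = NULL, sds = NULL),
    class = "fitted_pretreatment"
  )
}

# noise-free generator settings for exact-recovery tests
noiseless_config <- function(seed = 7, mode = "NIR") {
  generator_config(mode = mode, scatter_sigma = 0, baseline_sigma = 0,
                   noise_sigma = 0, seed = seed)
}

# the full seed-1 synthetic NIR experiment is used by several test files;
# compute it once per test run
full_nir_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- paste0("seed", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- run_full_experiment(seed = seed)
    }
    cache[[key]]
  }
})
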