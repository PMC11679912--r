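# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# a small deterministic GT/sCT pair with known per-slice MAE targets
tiny_pair <- function(seed = 5, n_slices = 6, targets = NULL) {
  cfg <- phantom_config(shape = c(32, 32, n_slices), seed = seed)
  gt <- generate_gt(cfg)
  if (is.null(targets)) targets <- seq(10, 90, length.out = n_slices)
  sct <- corrupt_to_target_mae(gt, targets, cfg)
  list(pair = volume_pair(gt, sct, patient_id = sprintf("T%03d", seed),
                          modality = "CBCT"),
       targets = targets, config = cfg)
}

# quick training configuration for structural tests (not an accuracy recipe)
mini_cfg <- function(seed = 3, epochs = 25) {
  desk_train_config(seed = seed, max_epochs = epochs, max_translation_px = 1L,
                    min_regression_samples = 4L)
}

mini_dataset <- function(modality = "CBCT", n_patients = 5, seed = 21) {
  make_phantom_dataset(n_patients,
                       phantom_config(shape = c(32, 32, 8),
                                      modality_style = modality),
                       seed = seed)
}

# one small trained cascade shared by the cascade/evaluation tests
mini_model <- function() {
  memo("mini_model", {
    ds <- mini_dataset()
    scheme <- compute_classification_bins(build_corpus(ds$pairs)$mae_gt,
                                          saturation = 100)
    corpus <- build_corpus(ds$pairs, scheme = scheme)
    train_cascade(corpus, scheme = scheme, cfg = mini_cfg())
  })
}

mini_corpus <- function(seed = 77) {
  memo(paste0("mini_corpus_", seed), {
    ds <- mini_dataset(seed = seed)
    build_corpus(ds$pairs)
  })
}
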