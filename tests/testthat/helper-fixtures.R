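# Shared fixtures, all generated in code.

# small labelled dataset + trained stack, built once per test run
small_config <- function(seed = 11L)
  synthetic_config(n_positive_per_fold = 20L, n_negative = 40L,
                   length_range = c(200L, 350L), seed = seed)

.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(small_config())
  .fixture_env$ds
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- fixture_dataset()
    .fixture_env$model <- depo_train(
      ds$labeled,
      token_cfg = token_classifier_config(epochs = 15L, seed = 5L),
      head_cfg = binary_head_config(epochs = 15L, seed = 5L))
  }
  .fixture_env$model
}

random_background_record <- function(id, len) {
  protein_record(id, paste(sample(setdiff(aa_alphabet(), "X"), len,
                                  replace = TRUE), collapse = ""))
}

# deterministic sequence of given length (no RNG use)
flat_record <- function(id, len, annotation = NA_character_) {
  protein_record(id, paste(rep(c("A", "G", "S", "T", "L"),
                               length.out = len), collapse = ""),
                 annotation)
}
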