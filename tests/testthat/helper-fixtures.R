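# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Full-scale synthetic dataset: 20/20/15 plants per condition, both leaves.
full_dataset <- function() {
  fixture("full_dataset", function() {
    synthesize_dataset(swp_synthetic_config(seed = 10))
  })
}

leaf_traces <- function(leaf) {
  fixture(paste0("traces_leaf", leaf), function() {
    recs <- Filter(function(r) r$leaf == leaf, full_dataset()$recordings)
    preprocess_dataset(recs)
  })
}

condition_group <- function(leaf, condition) {
  Filter(function(t) t$condition == condition, leaf_traces(leaf))
}

# One fully trained AAE (200 epochs, seed 10) per (leaf, condition) group.
trained_aaes <- function() {
  fixture("trained_aaes", function() {
    models <- list()
    for (leaf in c(8L, 13L)) {
      for (cond in swp_conditions()) {
        models[[sprintf("leaf%d_%s", leaf, cond)]] <-
          train_aae(condition_group(leaf, cond), swp_aae_config())
      }
    }
    models
  })
}

# A small fast dataset for unit tests that only need plumbing, not scale.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    synthesize_dataset(swp_synthetic_config(
      n_per_condition = c(Normal = 3, SED = 3, LED = 2), seed = 7))
  })
}

tiny_traces <- function(leaf = 8) {
  fixture(paste0("tiny_traces_leaf", leaf), function() {
    recs <- Filter(function(r) r$leaf == leaf, tiny_dataset()$recordings)
    preprocess_dataset(recs)
  })
}

# A short fast AAE config for interface-level tests.
fast_aae_cfg <- function(epochs = 20, seed = 3) {
  swp_aae_config(epochs = epochs, seed = seed)
}

make_trace <- function(values, real_length = length(values), sample_id = "t",
                       leaf = 8, condition = "Normal") {
  structure(list(values = values, real_length = real_length,
                 sample_id = sample_id, leaf = leaf, condition = condition),
            class = "swp_trace")
}
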