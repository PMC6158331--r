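# Shared fixtures, built in code and memoized per test run. Durations are
# kept short: all duration-dependent metrics normalize by actual time.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# four small LVFA blocks, preprocessed and featurized
tiny_blocks <- function() {
  memo("tiny_blocks", function() {
    cfg <- synth_config(block_duration_s = 240, seizure_duration_s = 40,
                        seed = 42)
    recs <- synth_dataset(4, cfg, seed = 42)
    list(recs = recs, epochs = prepare_epochs(recs),
         blocks = prepare_blocks(recs))
  })
}

# small labeled feature matrix pooled over tiny_blocks channel 1
tiny_train <- function() {
  memo("tiny_train", function() {
    blocks <- tiny_blocks()$blocks
    tr <- do.call(rbind, lapply(blocks, function(blk) {
      use <- !blk$artifact_mask[, 1]
      cbind(blk$features[use, 1, , drop = TRUE], as.integer(blk$labels[use]))
    }))
    list(x = tr[, 1:10, drop = FALSE], y = tr[, 11])
  })
}

# a modest forest for serialization / voting tests
tiny_forest <- function(n_trees = 25) {
  memo(paste0("tiny_forest", n_trees), function() {
    tr <- tiny_train()
    rf_train(tr$x, tr$y, n_trees = n_trees, seed = 11)
  })
}
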