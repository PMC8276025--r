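# Trained desk-scale models are expensive (minutes); train each operating
# point at most once per test session and share it across test blocks.

.desk_cache <- new.env(parent = emptyenv())

desk_fit <- function(B, steps, seed = 1L) {
  key <- sprintf("B%d_s%d_seed%d", B, steps, seed)
  if (is.null(.desk_cache[[key]])) {
    config <- desk_train_config(B = B, seed = seed, steps = steps)
    data <- suppressWarnings(make_training_set(config))
    .desk_cache[[key]] <- suppressWarnings(train_decoder(config, data = data))
  }
  .desk_cache[[key]]
}
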