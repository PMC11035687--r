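# Shared fixtures built in code. Heavy objects (the benchmark splits and the
# trained reference models) are built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# full frozen benchmark: 10 classes, 1000 train / 200 test per class
acc_benchmark <- function() {
  cached("benchmark", function() synthetic_benchmark(1000L, 200L, seed = 42L))
}

acc_fit <- function(rf_size) {
  key <- paste0("fit_rf", rf_size)
  cached(key, function() {
    bench <- acc_benchmark()
    net <- satiation_network(rf_size = rf_size, seed = 1L)
    train_network(net, bench$train,
                  training_config(n_repeat = 4L, batch_size = 200L,
                                  max_epochs = 10L, seed = 1L))
  })
}

# same-stimulus traces of the 5x5 model on the test split (semantics kept)
acc_same_rf5 <- function() {
  cached("same_rf5", function() {
    run_same_stimulus(acc_fit(5L)$net, acc_benchmark()$test, t_max = 100L,
                      keep_semantics = TRUE)
  })
}

# small quick dataset for unit tests
tiny_glyphs <- function(n_per_class = 5L, seed = 9L) {
  cached(paste0("tiny", n_per_class, "_", seed),
         function() generate_glyphs(glyph_spec_default(), n_per_class,
                                    seed = seed))
}
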