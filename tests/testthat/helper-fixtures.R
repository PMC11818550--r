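# Shared small fixtures, built once per test run.

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_drugs = 6, n_proteins = 8,
                             seq_len_range = c(15L, 25L), seed = 11)
      cache <<- synthetic_dataset(spec)
    }
    cache
  }
})

# the seed-42 conformance fixture (20 drugs x 30 proteins), built once
conformance_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_dataset(synthetic_spec())
    cache
  }
})

tiny_config <- function(epochs = 2L, ...) {
  hetdta_config(profile = "desk", hetero_dim = 8L, graph_dim = 8L,
                ecfp_dim = 8L, fc_dims = c(16L, 8L, 1L), epochs = epochs, ...)
}
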