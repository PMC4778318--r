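# Shared small synthetic worlds. Sizes are kept modest so the default
# test run stays fast; the generator presets themselves default to the
# full study conditions.

small_oriented_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_world(oriented_world_config(n_genes = 800L,
                                                  n_samples = 120L,
                                                  seed = 301L))
    cache
  }
})

small_null_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_world(null_world_config(n_genes = 250L,
                                              n_samples = 40L,
                                              seed = 302L))
    cache
  }
})

# Tiny deterministic region set for unit examples.
toy_regions <- function(seqs) upstream_set(seqs)
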