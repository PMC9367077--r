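# Memoized full-pipeline runs on the planted fixture, shared between the
# acceptance suite and the module tests that need end-to-end results.

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(seed, dim = 20) {
  key <- sprintf("s%d_k%d", seed, dim)
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- synth_config(seed = seed)
    .pipeline_cache[[key]] <- run_fixture_pipeline(cfg, dim = dim, seed = seed)
  }
  .pipeline_cache[[key]]
}
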