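# the full 8-preset synthetic study is expensive enough to build once and
# share across the structural-invariant and qualitative-reproduction tests
.study_cache <- new.env(parent = emptyenv())

preset_study <- function() {
  if (is.null(.study_cache$sw)) {
    presets <- paper_preset(seed = 1)
    datasets <- generate_study(presets)
    sw <- suppressMessages(run_study(datasets, sweep_config(seed = 1)))
    .study_cache$presets <- presets
    .study_cache$datasets <- datasets
    .study_cache$sw <- sw
    .study_cache$sz <- suppressWarnings(standardize(sw))
  }
  as.list(.study_cache)
}
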