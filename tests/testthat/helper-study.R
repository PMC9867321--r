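# Memoised full-scale synthetic study shared by the acceptance checks: 200
# captures per category at the default 128 x 128 scene, generator seed 42,
# 70/30 stratified split with seed 7.
study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(study_cache$res)) {
    stream <- generate_dataset(200, seed = 42L)
    sm <- extract_matrix(stream)
    parts <- split_matrix(sm, split_spec(0.70, seed = 7L))
    study_cache$res <- list(sm = sm, parts = parts)
  }
  study_cache$res
}
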