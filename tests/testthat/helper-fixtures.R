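# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_consensus <- function() {
  if (is.null(.fixture_cache$cons))
    .fixture_cache$cons <- synthetic_consensus_set()
  .fixture_cache$cons
}

# A small cohort + pipeline result reused across test files.
fixture_result <- function() {
  if (is.null(.fixture_cache$res)) {
    .fixture_cache$res <- run_temr_pipeline(
      seed = 301, n_events = 24, background_length = 1.2e6, n_decoys = 30)
  }
  .fixture_cache$res
}

# One planted HR deletion on a tiny genome, with everything exposed.
fixture_hr_del <- function(mh = 15L, seed = 77L) {
  cons <- fixture_consensus()
  sp <- plant_spec("DEL", "HR", mh_length = mh)
  pl <- make_te_pair(cons$Alu, sp, seed = seed)
  ref <- build_reference(10000, pl, cons, seed = seed + 1L)
  truth <- plant_temr(ref, sp, seed = seed + 2L)
  list(cons = cons, spec = sp, ref = ref, truth = truth)
}
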