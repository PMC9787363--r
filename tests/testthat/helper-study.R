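# The replicate simulation study at the reference design is the most
# expensive ingredient of the recovery, precision and coverage tests; it is
# computed once per test run and shared.
.study_cache <- new.env(parent = emptyenv())

reference_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_simulation_study(
      10, seed = 1, models = c("integrated", "mr"),
      chains = 3, iter = 10000, burnin = 2000)
  }
  .study_cache$study
}
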